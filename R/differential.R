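#' Call differential reactivity between two conditions
#'
#' For each position determined in both conditions, computes the absolute
#' difference of mean reactivities `deltaR = |R1 - R2|`, the relative change
#' `deltaR / (R1 + R2)`, and a two-sided Welch t-test on the per-replicate
#' values. A position is called significant only when all three criteria
#' hold strictly: `deltaR > dr_thresh`, `rel_change > rel_thresh`, and
#' `p < alpha`. The two-criterion threshold excludes both small changes
#' between weakly reactive nucleotides and large but meaningless changes
#' between highly reactive ones.
#'
#' Positions undetermined in either condition are excluded. Degenerate cases
#' are flagged rather than dropped: fewer than two usable replicates on a
#' side leaves `p_value` undefined and the call not significant
#' (`flag = "insufficient_replicates"`); both sides constant gives `p = 0`
#' when means differ and `p = 1` otherwise (`flag = "degenerate_variance"`);
#' a non-positive mean sum leaves `rel_change` undefined and the call not
#' significant (`flag = "nonpositive_sum"`).
#'
#' @param a,b Long replicate tibbles for the two conditions (condition 1 and
#'   condition 2), as read by [read_reactivity_table()] and optionally
#'   filtered by [filter_outliers()].
#' @param dr_thresh Threshold on `deltaR` (default 0.2, strict).
#' @param rel_thresh Threshold on `rel_change` (default 0.2, strict).
#' @param alpha Significance level for the Welch test (default 0.05, strict).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   and applied before the `alpha` comparison. Default `"none"`, matching
#'   the per-position convention of differential SHAPE analysis;
#'   `"BH"` enables Benjamini-Hochberg.
#'
#' @return A tibble of class `shape_diff`, one row per shared determined
#'   position: `position`, `base`, `R1`, `R2`, `deltaR`, `rel_change`,
#'   `p_value`, `significant`, `direction` (`up_in_2` / `down_in_2` /
#'   `none`), `flag`.
#' @examples
#' a <- tibble::tibble(position = 1L, base = "G",
#'                     replicate = paste0("rep", 1:3),
#'                     reactivity = c(1.0, 1.1, 0.9))
#' b <- dplyr::mutate(a, reactivity = c(0.40, 0.50, 0.45))
#' compare_profiles(a, b)
#' @export
compare_profiles <- function(a, b, dr_thresh = 0.2, rel_thresh = 0.2,
                             alpha = 0.05, p_adjust = "none") {
  check_replicate_tbl(a, "a")
  check_replicate_tbl(b, "b")
  va <- split(a$reactivity[!is.na(a$reactivity)],
              a$position[!is.na(a$reactivity)])
  vb <- split(b$reactivity[!is.na(b$reactivity)],
              b$position[!is.na(b$reactivity)])
  shared <- intersect(names(va), names(vb))
  if (length(shared) == 0L) {
    warn("No shared determined positions; empty differential result.")
    return(empty_diff())
  }
  shared <- shared[order(as.integer(shared))]
  base_map <- setNames(a$base, as.character(a$position))

  rec <- purrr::map(shared, function(p) {
    x <- va[[p]]; y <- vb[[p]]
    R1 <- mean(x); R2 <- mean(y)
    dR <- abs(R1 - R2)
    flag <- NA_character_
    rel <- NA_real_
    if (R1 + R2 > 0) rel <- dR / (R1 + R2) else flag <- "nonpositive_sum"
    pval <- NA_real_
    if (length(x) < 2L || length(y) < 2L) {
      flag <- flag %|na|% "insufficient_replicates"
    } else if (sd(x) == 0 && sd(y) == 0) {
      pval <- if (R1 == R2) 1 else 0
      flag <- flag %|na|% "degenerate_variance"
    } else {
      pval <- t.test(x, y, var.equal = FALSE)$p.value
    }
    tibble(position = as.integer(p),
           base = unname(base_map[p]) %|na|% NA_character_,
           R1 = R1, R2 = R2, deltaR = dR, rel_change = rel,
           p_value = pval, flag = flag)
  })
  out <- dplyr::bind_rows(rec)
  p_cmp <- p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$rel_change) & !is.na(p_cmp) &
    out$deltaR > dr_thresh & out$rel_change > rel_thresh & p_cmp < alpha
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$R2 > out$R1, "up_in_2", "down_in_2"))
  out <- dplyr::relocate(out, "position", "base", "R1", "R2", "deltaR",
                         "rel_change", "p_value", "significant", "direction",
                         "flag")
  class(out) <- c("shape_diff", class(out))
  out
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

empty_diff <- function() {
  out <- tibble(position = integer(), base = character(), R1 = double(),
                R2 = double(), deltaR = double(), rel_change = double(),
                p_value = double(), significant = logical(),
                direction = character(), flag = character())
  class(out) <- c("shape_diff", class(out))
  out
}

#' Summarise differential calls by structural class
#'
#' Cross-tabulates differential records against a per-position structural
#' annotation (single strand, helix, pseudoknot strands, kissing loop,
#' tertiary, ...), counting compared and significant positions per class and
#' direction. Magnesium-removal probing predicts that positions protected by
#' the tertiary fold (pseudoknot, kissing loop, non-canonical contacts)
#' light up in the no-Mg condition; the attached recall measures how many
#' annotated tertiary positions the calls recover.
#'
#' @param records A `shape_diff` tibble from [compare_profiles()].
#' @param annotation Tibble with columns `position` and `class`; positions
#'   missing from it are counted as `"unannotated"`.
#' @param tertiary_classes Classes counted as tertiary-structure positions
#'   for the recall summary.
#' @return A tibble with one row per structural class: `class`,
#'   `n_compared`, `n_significant`, `n_up_in_2`, `n_down_in_2`. Attribute
#'   `tertiary_recall` holds the fraction of annotated tertiary positions
#'   called significant.
#' @export
mg_differential_report <- function(records, annotation,
                                   tertiary_classes = c("TERT", "PK5", "PK3",
                                                        "KL")) {
  if (!all(c("position", "class") %in% names(annotation))) {
    abort("`annotation` must have `position` and `class` columns.")
  }
  joined <- dplyr::left_join(
    records,
    dplyr::select(dplyr::mutate(annotation,
                                class = as.character(.data$class)),
                  "position", "class"),
    by = "position"
  )
  joined$class[is.na(joined$class)] <- "unannotated"
  out <- joined |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_compared = dplyr::n(),
      n_significant = sum(.data$significant),
      n_up_in_2 = sum(.data$direction == "up_in_2"),
      n_down_in_2 = sum(.data$direction == "down_in_2"),
      .groups = "drop"
    )
  tert <- dplyr::filter(joined, .data$class %in% tertiary_classes)
  attr(out, "tertiary_recall") <- if (nrow(tert)) {
    mean(tert$significant)
  } else {
    NA_real_
  }
  out
}

#' @method glance shape_diff
#' @export
glance.shape_diff <- function(x, ...) {
  tibble(n_positions = nrow(x),
         n_significant = sum(x$significant),
         n_up_in_2 = sum(x$direction == "up_in_2"),
         n_down_in_2 = sum(x$direction == "down_in_2"),
         n_flagged = sum(!is.na(x$flag)))
}

#' Plot a differential reactivity profile
#'
#' @param object A `shape_diff` tibble.
#' @param ... Unused.
#' @return A ggplot: signed reactivity change per position, significant
#'   calls highlighted.
#' @method autoplot shape_diff
#' @export
autoplot.shape_diff <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object), change = .data$R2 - .data$R1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$change)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey70"),
                               name = "significant") +
    ggplot2::labs(x = "position", y = "R2 - R1 (SHAPE units)",
                  title = "Differential SHAPE reactivity") +
    ggplot2::theme_minimal()
}
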