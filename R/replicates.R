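#' Discard outlier replicate measurements
#'
#' Within each position's replicate triplicate (or larger set), a value is an
#' outlier when it lies more than `window` reactivity units away from every
#' other measurement at that position; outliers are discarded (set to `NA`).
#' If all values at a position are mutually more than `window` apart there is
#' no agreeing majority and the position becomes undetermined. With fewer
#' than three usable values no outlier can be identified and both are kept.
#'
#' The rule is a single pass over the original values: a value kept because
#' it is close to some other value can never lose that neighbour (a discarded
#' value is by definition far from *all* others), so the filter is
#' idempotent.
#'
#' @param reps Long replicate tibble (see [read_reactivity_table()]).
#' @param window Agreement window in reactivity units (default 0.4).
#' @return `reps` with outlying `reactivity` entries set to `NA`. The number
#'   of discarded values is reported via a message and attached as attribute
#'   `n_discarded`.
#' @examples
#' reps <- tibble::tibble(
#'   position = 1L, base = "A", replicate = paste0("rep", 1:3),
#'   reactivity = c(0.10, 0.15, 0.90)
#' )
#' filter_outliers(reps) # 0.90 is discarded
#' @export
filter_outliers <- function(reps, window = 0.4) {
  check_replicate_tbl(reps)
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    abort("`window` must be a single positive number.")
  }
  n_before <- sum(!is.na(reps$reactivity))
  out <- reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("position", condition_cols(reps))
    ))) |>
    dplyr::mutate(reactivity = drop_lone_values(.data$reactivity, window)) |>
    dplyr::ungroup()
  n_discarded <- n_before - sum(!is.na(out$reactivity))
  if (n_discarded > 0) {
    inform(sprintf("filter_outliers: discarded %d replicate value(s).",
                   n_discarded))
  }
  attr(out, "n_discarded") <- n_discarded
  out
}

# NA out each value whose distance to every other non-NA value exceeds
# `window`. Applied only when >= 3 usable values exist.
drop_lone_values <- function(x, window) {
  idx <- which(!is.na(x))
  if (length(idx) < 3L) return(x)
  v <- x[idx]
  d <- abs(outer(v, v, "-"))
  diag(d) <- Inf
  lone <- apply(d, 1L, min) > window
  x[idx[lone]] <- NA_real_
  x
}

#' Aggregate replicate reactivities into a per-position profile
#'
#' Computes the per-position mean reactivity, sample standard deviation and
#' number of usable replicates. Positions with no usable value are flagged
#' undetermined. Outlier filtering ([filter_outliers()]) is normally applied
#' first.
#'
#' @param reps Long replicate tibble.
#' @return A tibble with one row per position: `position`, `base`,
#'   `reactivity` (mean), `sd` (`NA` when fewer than two values), `n_used`,
#'   `undetermined`, plus any condition columns carried through.
#' @export
aggregate_replicates <- function(reps) {
  check_replicate_tbl(reps)
  reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("position", "base", condition_cols(reps))
    ))) |>
    dplyr::summarise(
      n_used = sum(!is.na(.data$reactivity)),
      sd = ifelse(.data$n_used >= 2, sd(.data$reactivity, na.rm = TRUE),
                  NA_real_),
      reactivity = ifelse(.data$n_used >= 1,
                          mean(.data$reactivity, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(undetermined = .data$n_used == 0L) |>
    dplyr::relocate("position", "base", "reactivity", "sd", "n_used",
                    "undetermined") |>
    dplyr::arrange(.data$position)
}

#' Bin mean reactivities into low / moderate / high classes
#'
#' Uses the conventional display bins for normalized SHAPE reactivity:
#' below 0.4 is low (negative values clamp to low), 0.4 to 0.7 inclusive is
#' moderate, above 0.7 is high. Undetermined positions keep the class
#' `"undetermined"`.
#'
#' @param profile Aggregated profile from [aggregate_replicates()].
#' @param low Upper edge of the low bin (default 0.4).
#' @param high Values strictly above this are high (default 0.7).
#' @return `profile` with an added factor column `class` with levels
#'   `low`, `moderate`, `high`, `undetermined`.
#' @export
classify_reactivity <- function(profile, low = 0.4, high = 0.7) {
  if (!all(c("position", "reactivity") %in% names(profile))) {
    abort("`profile` must have `position` and `reactivity` columns.")
  }
  und <- if ("undetermined" %in% names(profile)) {
    profile$undetermined
  } else {
    is.na(profile$reactivity)
  }
  r <- profile$reactivity
  cls <- dplyr::case_when(
    und | is.na(r) ~ "undetermined",
    r < low ~ "low",
    r <= high ~ "moderate",
    TRUE ~ "high"
  )
  profile$class <- factor(cls, levels = c("low", "moderate", "high",
                                          "undetermined"))
  profile
}
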