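#' Boost-to-10 constraint strategy
#'
#' Builds a pseudo-reactivity profile for structure-prediction software in
#' which positions whose reactivity rises significantly between 37 degC and
#' a mildly elevated temperature are assigned the saturating value
#' `boost` (default 10), while all other nucleotides keep their 37 degC
#' reactivity. A reactivity of 10 makes pairing at those positions
#' prohibitively costly for pseudo-energy models, discouraging spurious
#' secondary structure through pseudoknot strands.
#'
#' @param profile37 Aggregated 37 degC profile ([aggregate_replicates()]).
#' @param diff Differential records ([compare_profiles()]) between 37 degC
#'   and the elevated temperature (condition order: 37 degC first).
#' @param boost Value assigned to significant positions (default 10).
#' @return A tibble of class `shape_constraints` with columns `position`,
#'   `value` (`NA` for undetermined positions, written as `-999` by
#'   [export_shape()]); attribute `strategy = "boost10"`.
#' @export
make_boost10 <- function(profile37, diff, boost = 10) {
  if (!all(c("position", "reactivity") %in% names(profile37))) {
    abort("`profile37` must have `position` and `reactivity` columns.")
  }
  sig <- diff$position[diff$significant]
  if (!all(sig %in% profile37$position)) {
    abort("Significant differential positions are missing from `profile37`.")
  }
  und <- if ("undetermined" %in% names(profile37)) {
    profile37$undetermined
  } else {
    is.na(profile37$reactivity)
  }
  value <- ifelse(und, NA_real_, profile37$reactivity)
  value[profile37$position %in% sig] <- boost
  new_constraints(profile37$position, value, "boost10")
}

#' Pseudoknot-mask constraint strategy
#'
#' Builds an artificial constraint file that *inverts* the usual reading of
#' reactivity: positions whose reactivity varies significantly between two
#' conditions (e.g. 37 vs 53 degC, or with/without Mg) — the candidate
#' tertiary/pseudoknot positions — are set to a pairing-favourable `low`
#' value (default -0.2), while every other determined position is set to a
#' strongly pairing-adverse `high` value (default 5). Feeding this file to
#' prediction software restricts base pairing to the candidate set, so any
#' helix it still predicts is formed among differential positions —
#' revealing pseudoknot pairings that standard prediction misses.
#'
#' @param diff Differential records from [compare_profiles()]; must be
#'   non-empty.
#' @param low Value for significant positions (default -0.2).
#' @param high Value for other determined positions (default 5).
#' @param all_positions Optional full position universe; positions absent
#'   from `diff` (undetermined in either condition) receive the missing
#'   sentinel (`NA`, exported as `-999`).
#' @return A tibble of class `shape_constraints` (`position`, `value`);
#'   attribute `strategy = "pk_mask"`.
#' @export
make_pk_mask <- function(diff, low = -0.2, high = 5, all_positions = NULL) {
  if (nrow(diff) == 0L) {
    abort("Empty differential input: cannot build a pseudoknot mask.")
  }
  value <- ifelse(diff$significant, low, high)
  pos <- diff$position
  if (!is.null(all_positions)) {
    missing_pos <- setdiff(all_positions, pos)
    pos <- c(pos, missing_pos)
    value <- c(value, rep(NA_real_, length(missing_pos)))
    o <- order(pos)
    pos <- pos[o]; value <- value[o]
  }
  new_constraints(pos, value, "pk_mask")
}

new_constraints <- function(position, value, strategy) {
  out <- tibble(position = as.integer(position), value = value)
  attr(out, "strategy") <- strategy
  class(out) <- c("shape_constraints", class(out))
  out
}

#' Find complementary helices within a candidate position set
#'
#' Enumerates all maximal antiparallel helices of at least `min_len` base
#' pairs whose paired positions all lie in `candidates` and are
#' Watson-Crick (or, optionally, GU wobble) complementary. Running this on
#' the positions singled out by a pseudoknot mask checks whether the masked
#' set can pair with itself — i.e. whether the differential positions alone
#' support a pseudoknot helix — without invoking external prediction
#' software.
#'
#' @param sequence RNA sequence as a single A/C/G/U string (T is accepted
#'   and read as U).
#' @param candidates Integer positions (1-based) allowed to pair.
#' @param min_len Minimum helix length in base pairs (default 3: 2-bp
#'   interactions are below the reliable detection limit).
#' @param allow_gu Allow GU wobble pairs (default TRUE).
#' @return Tibble of maximal helices sorted by length (decreasing) then 5'
#'   start: `i_start`, `j_start` (outermost pair), `length`, `pairs`
#'   (list-column of two-column matrices of paired positions, `j > i`
#'   throughout).
#' @export
find_complementary_helices <- function(sequence, candidates, min_len = 3,
                                       allow_gu = TRUE) {
  seq_chars <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1]]
  n <- length(seq_chars)
  if (!all(seq_chars %in% c("A", "C", "G", "U"))) {
    abort("`sequence` must contain only A/C/G/U (or T).")
  }
  candidates <- as.integer(candidates)
  if (length(candidates) && (min(candidates) < 1L || max(candidates) > n)) {
    abort("`candidates` must lie within the sequence.")
  }
  if (min_len < 1) abort("`min_len` must be >= 1.")
  in_cand <- logical(n)
  in_cand[candidates] <- TRUE

  ok_pair <- function(i, j) {
    in_cand[i] && in_cand[j] &&
      can_pair(seq_chars[i], seq_chars[j], allow_gu)
  }

  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || !ok_pair(i, j)) next
      # only start a helix at an outer-extendable-no-further pair
      if (i > 1L && j < n && ok_pair(i - 1L, j + 1L)) next
      len <- 0L
      while (i + len < j - len && ok_pair(i + len, j - len)) len <- len + 1L
      if (len >= min_len) {
        res[[length(res) + 1L]] <- list(
          i_start = i, j_start = j, length = len,
          pairs = cbind(i = i + 0:(len - 1L), j = j - 0:(len - 1L))
        )
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble(i_start = integer(), j_start = integer(),
                  length = integer(), pairs = list()))
  }
  out <- tibble(
    i_start = vapply(res, `[[`, integer(1), "i_start"),
    j_start = vapply(res, `[[`, integer(1), "j_start"),
    length = vapply(res, `[[`, integer(1), "length"),
    pairs = lapply(res, `[[`, "pairs")
  )
  dplyr::arrange(out, dplyr::desc(.data$length), .data$i_start)
}

can_pair <- function(x, y, allow_gu = TRUE) {
  wc <- (x == "A" & y == "U") | (x == "U" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  gu <- (x == "G" & y == "U") | (x == "U" & y == "G")
  wc | (allow_gu & gu)
}
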