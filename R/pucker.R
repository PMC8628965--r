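PUCKER_FAMILIES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                     "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                     "C1'-endo", "C2'-exo")

A_LIKE <- c("C1'-endo", "C2'-exo", "C3'-endo", "C4'-exo")
B_LIKE <- c("C1'-exo", "C2'-endo", "C3'-exo", "C4'-endo")

#' Pseudorotation phase and amplitude from ring dihedrals
#'
#' Describes each five-membered sugar ring conformation by its
#' pseudorotation amplitude (degree of puckering, degrees) and phase (which
#' atoms are most displaced from the mean ring plane), computed from the
#' five ring dihedrals v1 (C1'-C2'-C3'-C4') through v5 (O4'-C1'-C2'-C3')
#' via the Fourier components
#' \deqn{a = 0.4 \sum_i v_i \cos(0.8\pi(i-1)), \quad
#'       b = -0.4 \sum_i v_i \sin(0.8\pi(i-1))}
#' with amplitude \eqn{\sqrt{a^2+b^2}} and phase \eqn{\mathrm{atan2}(b, a)}
#' mapped to `[0, 360)`. All five dihedrals enter symmetrically. The cosine
#' projection `pha_cos = a / amp` (the quantity often printed as "Pha") is
#' also returned, but classification uses the full angle, which the cosine
#' alone cannot resolve over the whole pucker wheel.
#'
#' @param dihedrals Tibble with numeric columns `v1`..`v5` (degrees, in
#'   `(-180, 180]`); other columns (e.g. `frame`, `residue`) are preserved.
#' @param planar_tol Amplitude below which the ring is treated as planar
#'   and phase is undefined (default 1e-6 degrees).
#' @return `dihedrals` with added columns `a`, `b`, `amp`, `phase_deg`
#'   (`[0, 360)`, `NA` when planar), `pha_cos`, `planar`.
#' @examples
#' pseudorotation(inverse_pseudorotation(38.6, 18))
#' @export
pseudorotation <- function(dihedrals, planar_tol = 1e-6) {
  vcols <- paste0("v", 1:5)
  if (!all(vcols %in% names(dihedrals))) {
    abort("`dihedrals` must have columns v1..v5 (degrees).")
  }
  v <- as.matrix(dihedrals[, vcols])
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    abort("Ring dihedrals must be finite numbers (no NA/NaN).")
  }
  theta <- 0.8 * pi * (0:4)
  a <- 0.4 * as.vector(v %*% cos(theta))
  b <- -0.4 * as.vector(v %*% sin(theta))
  amp <- sqrt(a^2 + b^2)
  planar <- amp < planar_tol
  phase <- (atan2(b, a) * 180 / pi) %% 360
  phase[planar] <- NA_real_
  out <- as_tibble(dihedrals)
  out$a <- a
  out$b <- b
  out$amp <- amp
  out$phase_deg <- phase
  out$pha_cos <- ifelse(planar, NA_real_, a / amp)
  out$planar <- planar
  out
}

#' Build ring dihedrals from amplitude and phase
#'
#' Inverse of [pseudorotation()]: constructs the five ring dihedrals
#' \eqn{v_i = A \cos(P + 0.8\pi(i-1))} realising a given pucker amplitude
#' and phase. Used by the synthetic trajectory generator and as the
#' round-trip check on the forward transform.
#'
#' @param amp Amplitude(s) in degrees.
#' @param phase_deg Phase(s) in degrees.
#' @return Tibble with columns `v1`..`v5` (vectorised over inputs).
#' @export
inverse_pseudorotation <- function(amp, phase_deg) {
  n <- max(length(amp), length(phase_deg))
  amp <- rep_len(amp, n)
  p <- rep_len(phase_deg, n) * pi / 180
  v <- vapply(0:4, function(i) amp * cos(p + 0.8 * pi * i), numeric(n))
  out <- as_tibble(matrix(v, nrow = n,
                          dimnames = list(NULL, paste0("v", 1:5))))
  out
}

#' Assign pucker family and A-like/B-like group
#'
#' The pseudorotation wheel is divided into ten 36-degree families named by
#' the atom most displaced from the mean ring plane and the displacement
#' direction (endo towards C5', exo away): C3'-endo is centred at 18
#' degrees, then C4'-exo, O4'-endo, C1'-exo, C2'-endo, C3'-exo, C4'-endo,
#' O4'-exo, C1'-endo, C2'-exo around the circle. Families group into the
#' A-like set (C1'-endo, C2'-exo, C3'-endo, C4'-exo — the A-form helix
#' region) and the B-like set (C1'-exo, C2'-endo, C3'-exo, C4'-endo); the
#' two O4' families belong to neither and are grouped `other`.
#'
#' @param states Output of [pseudorotation()]; must contain no planar rows.
#' @return `states` with added columns `family` (factor over the ten
#'   families) and `group` (`A_like` / `B_like` / `other`).
#' @export
classify_pucker <- function(states) {
  if (!all(c("phase_deg", "planar") %in% names(states))) {
    abort("`states` must come from pseudorotation().")
  }
  if (any(states$planar)) {
    abort("Planar ring(s) present: phase and family are undefined.")
  }
  idx <- floor((states$phase_deg %% 360) / 36) + 1L
  fam <- PUCKER_FAMILIES[idx]
  states$family <- factor(fam, levels = PUCKER_FAMILIES)
  states$group <- dplyr::case_when(
    fam %in% A_LIKE ~ "A_like",
    fam %in% B_LIKE ~ "B_like",
    TRUE ~ "other"
  )
  states
}

#' Per-nucleotide pucker family occupancies over a trajectory
#'
#' For every nucleotide, counts the fraction of trajectory frames spent in
#' each of the ten pucker families (plus an `undefined` bucket for planar
#' frames) and in the A-like/B-like/other groups.
#'
#' @param frames Tibble of per-frame ring dihedrals: columns `residue`,
#'   `v1`..`v5`, optionally `frame` and `chain`.
#' @return A tibble with one row per residue x family actually observed:
#'   `residue`, `family`, `group`, `n_frames`, `pct`. Percentages sum to
#'   100 per residue.
#' @export
pucker_occupancy <- function(frames) {
  if (!"residue" %in% names(frames)) {
    abort("`frames` must have a `residue` column.")
  }
  if (nrow(frames) == 0L) abort("Empty trajectory.")
  st <- pseudorotation(frames)
  ok <- !st$planar
  fam <- rep("undefined", nrow(st))
  grp <- rep("undefined", nrow(st))
  if (any(ok)) {
    cls <- classify_pucker(st[ok, , drop = FALSE])
    fam[ok] <- as.character(cls$family)
    grp[ok] <- cls$group
  }
  tibble(residue = st$residue, family = fam, group = grp) |>
    dplyr::count(.data$residue, .data$family, .data$group,
                 name = "n_frames") |>
    dplyr::group_by(.data$residue) |>
    dplyr::mutate(pct = 100 * .data$n_frames / sum(.data$n_frames)) |>
    dplyr::ungroup()
}

#' Summarise group occupancies from family occupancies
#'
#' @param occupancy Output of [pucker_occupancy()].
#' @return Tibble `residue`, `group`, `pct` (summing to 100 per residue).
#' @export
group_occupancy <- function(occupancy) {
  occupancy |>
    dplyr::group_by(.data$residue, .data$group) |>
    dplyr::summarise(pct = sum(.data$pct), .groups = "drop")
}

#' Mean and standard deviation of per-frame scalar quantities
#'
#' Summarises flexibility descriptors computed along a trajectory
#' (distances, valence angles, dihedrals, ...) as mean plus sample standard
#' deviation per quantity.
#'
#' @param series Tibble with columns `quantity` (name) and `value` (one row
#'   per frame).
#' @return Tibble `quantity`, `mean`, `sd`, `n_frames` (`sd` is `NA` with a
#'   single frame).
#' @export
summarize_quantity <- function(series) {
  if (!all(c("quantity", "value") %in% names(series))) {
    abort("`series` needs columns `quantity` and `value`.")
  }
  if (nrow(series) == 0L) abort("Empty series.")
  series |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() >= 2, sd(.data$value), NA_real_),
                     n_frames = dplyr::n(), .groups = "drop")
}

#' Read a per-frame ring dihedral table
#'
#' @param path CSV with header columns `frame`, `residue`, `v1`..`v5`
#'   (an optional `chain` column is preserved). Dihedral extraction from MD
#'   trajectory formats is left to external tooling; this package consumes
#'   the exported table.
#' @return A tibble of per-frame dihedrals.
#' @export
read_dihedral_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Dihedral table not found: '%s'", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "residue", paste0("v", 1:5))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("'%s' lacks column(s): %s.", path,
                  paste(miss, collapse = ", ")))
  }
  df
}

#' Plot per-nucleotide pucker occupancies
#'
#' @param occupancy Output of [pucker_occupancy()].
#' @return A stacked-bar ggplot of family occupancy per residue.
#' @export
plot_pucker_occupancy <- function(occupancy) {
  ggplot2::ggplot(occupancy,
                  ggplot2::aes(x = factor(.data$residue), y = .data$pct,
                               fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue", y = "occupancy (%)", fill = "pucker family",
                  title = "Sugar pucker occupancy") +
    ggplot2::theme_minimal()
}
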