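#' Min-max normalize melting fluorescence curves
#'
#' Scales each replicate curve to `[0, 1]` so that peak-prominence
#' thresholds are comparable across runs and instruments. Curves are
#' grouped by `replicate` (and by `mg_mM` when present).
#'
#' @param curve Tibble with columns `temperature_C`, `rfu`, and optionally
#'   `replicate` and `mg_mM`.
#' @return The same tibble with `rfu` rescaled to `[0, 1]` per curve.
#' @export
normalize_melt <- function(curve) {
  check_melt_tbl(curve)
  grp <- intersect(c("replicate", "mg_mM"), names(curve))
  curve |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(rfu = minmax_scale(.data$rfu, .data$temperature_C)) |>
    dplyr::ungroup()
}

minmax_scale <- function(x, temp) {
  if (length(x) < 10L) {
    abort("A melt curve needs at least 10 points to normalize.")
  }
  rng <- range(x)
  if (diff(rng) == 0) {
    abort("Constant fluorescence curve: no dynamic range to normalize.")
  }
  (x - rng[1L]) / diff(rng)
}

#' Negative temperature derivative of a melt curve
#'
#' Computes `-dRFU/dT` by central differences on interior points and
#' one-sided differences at the ends, per curve. Maxima of this derivative
#' mark melting transitions.
#'
#' @param curve A (normalized) melt tibble: `temperature_C`, `rfu`, optional
#'   `replicate` / `mg_mM` grouping columns.
#' @return Tibble with `temperature_C`, `d_rfu` (`-dRFU/dT`, RFU per degC)
#'   and the grouping columns.
#' @export
melt_derivative <- function(curve) {
  check_melt_tbl(curve)
  grp <- intersect(c("replicate", "mg_mM"), names(curve))
  curve |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::reframe(
      temperature_C = .data$temperature_C,
      d_rfu = -finite_diff(.data$temperature_C, .data$rfu)
    )
}

# dy/dx with central differences inside, one-sided at the two ends.
finite_diff <- function(x, y) {
  n <- length(x)
  if (n < 3L) abort("Need at least 3 points to differentiate.")
  if (any(diff(x) <= 0)) {
    abort("Temperature grid must be strictly increasing.")
  }
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  d
}

#' Average replicate derivative curves and smooth
#'
#' Pointwise mean of the replicate derivatives on their common temperature
#' grid, followed by a centered moving average whose window is specified in
#' degrees (grid-independent) rather than points. `window_C = 0` averages
#' without smoothing.
#'
#' @param derivs Derivative tibble from [melt_derivative()] with a
#'   `replicate` column (and optionally `mg_mM`, preserved as grouping).
#' @param window_C Full width of the smoothing window in degC (default 1.5).
#' @return Tibble with `temperature_C`, `d_rfu` per remaining group.
#' @export
average_and_smooth <- function(derivs, window_C = 1.5) {
  if (!all(c("temperature_C", "d_rfu") %in% names(derivs))) {
    abort("`derivs` needs columns temperature_C and d_rfu.")
  }
  if (window_C < 0) abort("`window_C` must be non-negative.")
  grp <- intersect("mg_mM", names(derivs))
  if ("replicate" %in% names(derivs)) {
    grids <- derivs |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "replicate")))) |>
      dplyr::summarise(g = paste(signif(sort(.data$temperature_C), 12),
                                 collapse = ","), .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(n_grids = dplyr::n_distinct(.data$g),
                       .groups = "drop")
    if (any(grids$n_grids > 1L)) {
      abort("Replicate curves are not on a common temperature grid.")
    }
  }
  derivs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "temperature_C")))) |>
    dplyr::summarise(d_rfu = mean(.data$d_rfu), .groups = "drop_last") |>
    dplyr::arrange(.data$temperature_C, .by_group = TRUE) |>
    dplyr::mutate(d_rfu = moving_average(.data$temperature_C, .data$d_rfu,
                                         window_C)) |>
    dplyr::ungroup()
}

# Centered moving average over a temperature window of full width `width`.
moving_average <- function(x, y, width) {
  if (width == 0) return(y)
  half <- width / 2
  vapply(seq_along(x), function(i) {
    mean(y[abs(x - x[i]) <= half + 1e-9])
  }, numeric(1))
}

#' Detect melting transitions from a derivative curve
#'
#' Finds local maxima of the smoothed `-dRFU/dT` curve; each maximum marks a
#' melting temperature (Tm). Peaks are kept when their topographic
#' prominence is at least `min_prominence` times the curve's dynamic range,
#' which suppresses noise bumps. Tm is reported at the grid point of the
#' maximum.
#'
#' @param deriv Averaged/smoothed derivative tibble (`temperature_C`,
#'   `d_rfu`); if grouping columns remain, transitions are detected per
#'   group.
#' @param min_prominence Minimum peak prominence relative to
#'   `max(d_rfu) - min(d_rfu)` (default 0.05).
#' @return A tibble of class `melt_transitions`, sorted by `tm` within
#'   group: columns `tm` (degC), `height`, `prominence`, plus grouping
#'   columns. May be empty.
#' @export
find_transitions <- function(deriv, min_prominence = 0.05) {
  if (!all(c("temperature_C", "d_rfu") %in% names(deriv))) {
    abort("`deriv` needs columns temperature_C and d_rfu.")
  }
  grp <- intersect(c("mg_mM", "replicate"), names(deriv))
  out <- deriv |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::reframe(peak_table(.data$temperature_C, .data$d_rfu,
                              min_prominence))
  class(out) <- c("melt_transitions", class(out))
  out
}

peak_table <- function(x, y, min_prominence) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(y)
  rng <- diff(range(y))
  if (n < 3L || rng == 0) {
    return(tibble(tm = double(), height = double(), prominence = double()))
  }
  # Collapse flat runs so a plateau counts as one candidate (its midpoint).
  runs <- rle(y)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  mids <- floor((starts + ends) / 2L)
  v <- runs$values
  m <- length(v)
  peaks_r <- if (m < 3L) integer(0) else {
    which(v[2:(m - 1L)] > v[1:(m - 2L)] & v[2:(m - 1L)] > v[3:m]) + 1L
  }
  is_peak <- mids[peaks_r]
  prom <- vapply(is_peak, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence * rng
  tibble(tm = x[is_peak][keep], height = y[is_peak][keep],
         prominence = prom[keep]) |>
    dplyr::arrange(.data$tm)
}

# Topographic prominence: drop from the peak to the highest of the two
# key saddles (minimum between the peak and the nearest higher ground on
# each side; curve end counts as unbounded higher ground at -Inf floor).
peak_prominence <- function(y, i) {
  left <- y[seq_len(i - 1L)]
  right <- y[seq(i + 1L, length(y))]
  saddle <- function(v) {
    higher <- which(v > y[i])
    if (length(higher) == 0L) return(min(v))
    min(v[seq(from = length(v), to = max(higher))])
  }
  lmin <- saddle(rev(left))
  rmin <- saddle(right)
  y[i] - max(lmin, rmin)
}

#' Compare melting transitions across a magnesium titration
#'
#' Lines up detected transitions across MgCl2 conditions by peak rank (in
#' ascending Tm) and reports Tm shifts and peak-height changes relative to
#' the previous Mg concentration, e.g. to track the growth of the
#' tertiary-structure transition with increasing Mg.
#'
#' @param transitions A `melt_transitions` tibble with an `mg_mM` column, or
#'   a named list of transition tibbles keyed by Mg concentration (mM).
#' @return A tibble: `mg_mM`, `peak_rank`, `tm`, `height`, `prominence`,
#'   `tm_shift`, `height_change` (shifts vs the previous Mg concentration;
#'   `NA` for the first or when the rank is absent there).
#' @export
compare_titration <- function(transitions) {
  if (is.list(transitions) && !is.data.frame(transitions)) {
    if (is.null(names(transitions))) {
      abort("A list of transition sets must be named by Mg concentration.")
    }
    transitions <- dplyr::bind_rows(
      purrr::imap(transitions, function(x, key) {
        x <- as_tibble(x)
        if (nrow(x) == 0L) {
          # keep conditions with no detected transition as blank rows
          x <- tibble(tm = NA_real_, height = NA_real_,
                      prominence = NA_real_)
        }
        dplyr::mutate(x, mg_mM = as.numeric(key))
      })
    )
  }
  if (!"mg_mM" %in% names(transitions)) {
    abort("`transitions` must carry an `mg_mM` column (>= 2 conditions).")
  }
  if (length(unique(transitions$mg_mM)) < 2L) {
    abort("Need at least two Mg conditions to compare.")
  }
  df <- transitions |>
    as_tibble() |>
    dplyr::group_by(.data$mg_mM) |>
    dplyr::arrange(.data$tm, .by_group = TRUE) |>
    dplyr::mutate(peak_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$mg_mM)
  mgs <- sort(unique(df$mg_mM))
  df$tm_shift <- NA_real_
  df$height_change <- NA_real_
  for (j in seq_along(mgs)[-1]) {
    cur <- which(df$mg_mM == mgs[j])
    prev <- df[df$mg_mM == mgs[j - 1L], ]
    m <- match(df$peak_rank[cur], prev$peak_rank)
    df$tm_shift[cur] <- df$tm[cur] - prev$tm[m]
    df$height_change[cur] <- df$height[cur] - prev$height[m]
  }
  dplyr::relocate(df, "mg_mM", "peak_rank", "tm", "height", "prominence",
                  "tm_shift", "height_change")
}

#' Plot a melt derivative curve with detected transitions
#'
#' @param deriv Averaged/smoothed derivative tibble.
#' @param transitions Optional `melt_transitions` tibble to mark.
#' @return A ggplot of `-dRFU/dT` against temperature.
#' @export
plot_melt_derivative <- function(deriv, transitions = NULL) {
  p <- ggplot2::ggplot(deriv, ggplot2::aes(x = .data$temperature_C,
                                           y = .data$d_rfu)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (degC)", y = "-dRFU/dT",
                  title = "Melt derivative") +
    ggplot2::theme_minimal()
  if ("mg_mM" %in% names(deriv)) {
    p <- p + ggplot2::aes(colour = factor(.data$mg_mM)) +
      ggplot2::labs(colour = "MgCl2 (mM)")
  }
  if (!is.null(transitions) && nrow(transitions)) {
    p <- p + ggplot2::geom_vline(data = as_tibble(transitions),
                                 ggplot2::aes(xintercept = .data$tm),
                                 linetype = "dashed", colour = "#c0392b")
  }
  p
}

check_melt_tbl <- function(curve) {
  if (!all(c("temperature_C", "rfu") %in% names(curve))) {
    abort("A melt curve needs columns `temperature_C` and `rfu`.")
  }
  invisible(curve)
}
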