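#' Build a nucleotide x temperature reactivity matrix
#'
#' Assembles per-temperature aggregated profiles into the matrix clustered
#' by [cluster_nucleotides()]. A nucleotide enters the matrix only if its
#' reactivity is determined at every temperature; positions with any
#' undetermined (or missing) value are dropped and listed.
#'
#' @param profiles A tibble of aggregated profiles covering several
#'   temperatures: columns `position`, `temperature_C`, `reactivity`, and
#'   optionally `undetermined`. Typically `dplyr::bind_rows()` of
#'   [aggregate_replicates()] outputs.
#' @return An object of class `temperature_matrix`: a list with `matrix`
#'   (rows = kept positions, columns = temperatures), `temperatures`
#'   (increasing), `positions`, `dropped_positions`, and a `transformed`
#'   flag (`FALSE` here).
#' @export
build_temperature_matrix <- function(profiles) {
  need <- c("position", "temperature_C", "reactivity")
  if (!all(need %in% names(profiles))) {
    abort("`profiles` needs columns position, temperature_C, reactivity.")
  }
  temps <- sort(unique(profiles$temperature_C))
  if (length(temps) < 2L) {
    abort("At least two temperatures are required to build the matrix.")
  }
  df <- profiles
  if ("undetermined" %in% names(df)) {
    df$reactivity[df$undetermined] <- NA_real_
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(df, "position", "temperature_C", "reactivity"),
    names_from = "temperature_C", values_from = "reactivity"
  )
  wide <- dplyr::arrange(wide, .data$position)
  m <- as.matrix(wide[, as.character(temps), drop = FALSE])
  complete <- stats::complete.cases(m)
  structure(
    list(
      matrix = m[complete, , drop = FALSE],
      temperatures = temps,
      positions = wide$position[complete],
      dropped_positions = wide$position[!complete],
      transformed = FALSE
    ),
    class = "temperature_matrix"
  )
}

#' @export
print.temperature_matrix <- function(x, ...) {
  cat(sprintf(
    "<temperature_matrix> %d nucleotides x %d temperatures (%s degC)%s\n",
    nrow(x$matrix), length(x$temperatures),
    paste(x$temperatures, collapse = ", "),
    if (x$transformed) ", transformed" else ", raw"
  ))
  if (length(x$dropped_positions)) {
    cat(sprintf("  dropped (undetermined): %d position(s)\n",
                length(x$dropped_positions)))
  }
  invisible(x)
}

#' Log-transform and doubly standardize a temperature matrix
#'
#' Prepares reactivities for clustering: values below `floor` are floored
#' (normalized SHAPE values can be zero or negative, which log2 cannot
#' take), log2-transformed, then standardized nucleotide-wise (each row to
#' mean 0 / sd 1) and temperature-wise (each column to mean 0 / sd 1), in
#' that order. A zero-variance row or column is centered but not scaled and
#' is recorded in the `flat_rows` / `flat_cols` attributes.
#'
#' The double standardization makes clustering respond to the *shape* of a
#' nucleotide's thermal response rather than its absolute reactivity, and is
#' invariant to uniform positive rescaling of the input.
#'
#' @param tm A raw `temperature_matrix` from [build_temperature_matrix()].
#' @param floor Lower clamp applied before log2 (default 0.01).
#' @return A transformed `temperature_matrix`.
#' @export
transform_reactivity <- function(tm, floor = 0.01) {
  stopifnot(inherits(tm, "temperature_matrix"))
  if (tm$transformed) abort("Matrix is already transformed.")
  if (floor <= 0) abort("`floor` must be positive.")
  m <- log2(pmax(tm$matrix, floor))

  scale_dim <- function(m, margin) {
    mu <- apply(m, margin, mean)
    s <- apply(m, margin, sd)
    flat <- which(s == 0 | is.na(s))
    s[s == 0 | is.na(s)] <- 1  # center only; no divide for flat slices
    m <- sweep(m, margin, mu, "-")
    list(m = sweep(m, margin, s, "/"), flat = flat)
  }
  rows <- scale_dim(m, 1L)
  cols <- scale_dim(rows$m, 2L)
  out <- tm
  out$matrix <- cols$m
  out$transformed <- TRUE
  attr(out, "flat_rows") <- unname(rows$flat)
  attr(out, "flat_cols") <- unname(cols$flat)
  out
}

#' Cluster nucleotides by their thermal reactivity profile
#'
#' k-means clustering of the (transformed) nucleotide x temperature matrix,
#' with a best-of-restarts protocol under a fixed seed so results are
#' reproducible. Distortion is the within-cluster sum of squared errors.
#'
#' @param tm A `temperature_matrix`, normally transformed with
#'   [transform_reactivity()].
#' @param k Number of clusters, `1 <= k <=` number of nucleotides.
#' @param seed RNG seed (default 42).
#' @param n_restarts Random restarts; the lowest-distortion solution is kept
#'   (default 50).
#' @return An object of class `shape_clusters`: list with `k`, `labels`
#'   (tibble `position`, `cluster`), `centroids` (k x temperatures, in the
#'   clustered space), `distortion`, `seed`, `temperatures`, and an
#'   `archetype` slot filled by [label_archetypes()].
#' @export
cluster_nucleotides <- function(tm, k, seed = 42, n_restarts = 50) {
  stopifnot(inherits(tm, "temperature_matrix"))
  n <- nrow(tm$matrix)
  if (k < 1 || k > n) {
    abort(sprintf("`k` must be between 1 and %d (number of nucleotides).", n))
  }
  key <- apply(tm$matrix, 1L, paste, collapse = "\r")
  ukey <- unique(key)
  if (k >= length(ukey)) {
    # at least as many centres as distinct profiles: zero distortion, each
    # distinct profile its own cluster (Hartigan-Wong refuses this case)
    cl <- match(key, ukey)
    fit <- list(cluster = cl,
                centers = tm$matrix[match(ukey, key), , drop = FALSE],
                tot.withinss = 0)
  } else {
    fit <- with_seed(seed, suppressWarnings(
      kmeans(tm$matrix, centers = k, nstart = n_restarts, iter.max = 100L)
    ))
  }
  structure(
    list(
      k = as.integer(k),
      labels = tibble(position = tm$positions,
                      cluster = as.integer(fit$cluster)),
      centroids = fit$centers,
      distortion = fit$tot.withinss,
      seed = seed,
      temperatures = tm$temperatures,
      archetype = NULL
    ),
    class = "shape_clusters"
  )
}

#' @export
print.shape_clusters <- function(x, ...) {
  cat(sprintf("<shape_clusters> k = %d, %d nucleotides, distortion = %.4g\n",
              x$k, nrow(x$labels), x$distortion))
  if (!is.null(x$archetype)) {
    cat("  archetypes:", paste(sprintf("%d=%s", seq_along(x$archetype),
                                       x$archetype), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Distortion curve and elbow-based choice of k
#'
#' Runs [cluster_nucleotides()] for `k = 1..k_max` and records the
#' distortion (within-cluster sum of squared errors). The knee is chosen
#' automatically as the k whose curve point lies farthest (perpendicular
#' distance) from the chord joining the first and last points — a
#' deterministic stand-in for reading the elbow off the plot. The full curve
#' is always returned so the choice can be overridden.
#'
#' @inheritParams cluster_nucleotides
#' @param k_max Largest k to evaluate (default 10, capped at the number of
#'   nucleotides).
#' @return An object of class `elbow_curve`: list with `curve` (tibble `k`,
#'   `distortion`) and `chosen_k`.
#' @export
elbow_k <- function(tm, k_max = 10, seed = 42, n_restarts = 50) {
  stopifnot(inherits(tm, "temperature_matrix"))
  k_max <- min(k_max, nrow(tm$matrix))
  ks <- seq_len(k_max)
  d <- vapply(ks, function(k) {
    cluster_nucleotides(tm, k, seed = seed, n_restarts = n_restarts)$distortion
  }, numeric(1))
  if (any(diff(d) > 1e-8)) {
    warn("Distortion curve is not monotone non-increasing; consider more restarts.")
  }
  chosen <- if (k_max == 1L) 1L else ks[which.max(chord_distance(ks, d))]
  structure(list(curve = tibble(k = ks, distortion = d),
                 chosen_k = as.integer(chosen)),
            class = "elbow_curve")
}

# Perpendicular distance of each (k, d) point from the chord joining the
# first and last points of the curve.
chord_distance <- function(k, d) {
  x1 <- k[1]; y1 <- d[1]
  x2 <- k[length(k)]; y2 <- d[length(d)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len == 0) return(rep(0, length(k)))
  abs((y2 - y1) * k - (x2 - x1) * d + x2 * y1 - y2 * x1) / len
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("<elbow_curve> k = 1..%d, chosen k = %d\n",
              max(x$curve$k), x$chosen_k))
  invisible(x)
}

#' Label clusters with thermal-unfolding archetypes
#'
#' Four recurring thermal behaviours are expected for a folded RNA probed
#' along a denaturation series: nucleotides already very reactive at 37 degC
#' that stay reactive (single strands); nucleotides that light up just above
#' 37 degC (tertiary contacts melting first); nucleotides that open with the
#' bulk of the secondary structure from ~65 degC; and nucleotides of
#' especially stable helices that open only towards 85 degC. Each cluster is
#' labelled from its *raw* (untransformed) mean profile: a high mean
#' reactivity at the lowest temperature gives `always_reactive`; otherwise
#' the temperature interval with the largest centroid increase decides —
#' first interval `tertiary_37_53`, last interval `stable_85`, any middle
#' interval `secondary_65`.
#'
#' @param clusters A `shape_clusters` object (meaningful for `k = 4`).
#' @param tm_raw The *raw* `temperature_matrix` the clustering was derived
#'   from (before [transform_reactivity()]).
#' @param high_thresh Raw mean reactivity at the lowest temperature above
#'   which a cluster is `always_reactive` (default 0.7, the high-reactivity
#'   bin edge).
#' @return `clusters` with the `archetype` slot filled: one label per
#'   cluster from `always_reactive`, `tertiary_37_53`, `secondary_65`,
#'   `stable_85`, or `unassigned` (ties, or `k != 4`).
#' @export
label_archetypes <- function(clusters, tm_raw, high_thresh = 0.7) {
  stopifnot(inherits(clusters, "shape_clusters"),
            inherits(tm_raw, "temperature_matrix"))
  if (tm_raw$transformed) {
    abort("`tm_raw` must be the raw (untransformed) matrix.")
  }
  if (clusters$k != 4L) {
    warn("Archetype labels are defined for k = 4; labelling all clusters 'unassigned'.")
    clusters$archetype <- rep("unassigned", clusters$k)
    return(clusters)
  }
  idx <- match(clusters$labels$position, tm_raw$positions)
  if (anyNA(idx)) abort("`tm_raw` does not cover the clustered positions.")
  n_int <- length(tm_raw$temperatures) - 1L
  labels <- vapply(seq_len(clusters$k), function(cl) {
    rows <- idx[clusters$labels$cluster == cl]
    prof <- colMeans(tm_raw$matrix[rows, , drop = FALSE])
    if (prof[1L] > high_thresh) return("always_reactive")
    inc <- diff(prof)
    top <- which(inc == max(inc))
    if (length(top) > 1L) return("unassigned")
    if (top == 1L) "tertiary_37_53"
    else if (top == n_int) "stable_85"
    else "secondary_65"
  }, character(1))
  clusters$archetype <- labels
  clusters
}

#' @method tidy shape_clusters
#' @export
tidy.shape_clusters <- function(x, ...) {
  out <- x$labels
  if (!is.null(x$archetype)) {
    out$archetype <- x$archetype[out$cluster]
  }
  out
}

#' @method glance shape_clusters
#' @export
glance.shape_clusters <- function(x, ...) {
  tibble(k = x$k, n_nucleotides = nrow(x$labels),
         distortion = x$distortion, seed = x$seed)
}

#' @method tidy elbow_curve
#' @export
tidy.elbow_curve <- function(x, ...) x$curve

#' @method glance elbow_curve
#' @export
glance.elbow_curve <- function(x, ...) {
  tibble(chosen_k = x$chosen_k, k_max = max(x$curve$k))
}

#' Plot an elbow (distortion) curve
#'
#' @param object An `elbow_curve` from [elbow_k()].
#' @param ... Unused.
#' @return A ggplot of distortion against k with the chosen k marked.
#' @method autoplot elbow_curve
#' @export
autoplot.elbow_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$k, y = .data$distortion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed",
                        colour = "#c0392b") +
    ggplot2::scale_x_continuous(breaks = object$curve$k) +
    ggplot2::labs(x = "number of clusters k",
                  y = "distortion (within-cluster SSE)",
                  title = sprintf("Elbow curve (chosen k = %d)",
                                  object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Plot cluster mean thermal profiles
#'
#' @param object A `shape_clusters` object.
#' @param tm_raw Optional raw `temperature_matrix`; when supplied, raw mean
#'   reactivity profiles are drawn instead of transformed centroids.
#' @param ... Unused.
#' @return A ggplot of per-cluster mean reactivity against temperature.
#' @method autoplot shape_clusters
#' @export
autoplot.shape_clusters <- function(object, tm_raw = NULL, ...) {
  if (!is.null(tm_raw)) {
    idx <- match(object$labels$position, tm_raw$positions)
    prof <- t(vapply(seq_len(object$k), function(cl) {
      colMeans(tm_raw$matrix[idx[object$labels$cluster == cl], ,
                             drop = FALSE])
    }, numeric(length(tm_raw$temperatures))))
    ylab <- "mean raw reactivity"
  } else {
    prof <- object$centroids
    ylab <- "centroid (transformed units)"
  }
  df <- tibble(
    cluster = factor(rep(seq_len(object$k),
                         each = length(object$temperatures))),
    temperature_C = rep(object$temperatures, times = object$k),
    value = as.vector(t(prof))
  )
  if (!is.null(object$archetype)) {
    df$cluster <- factor(
      sprintf("%s (%s)", df$cluster, object$archetype[as.integer(df$cluster)])
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature_C, y = .data$value,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "temperature (degC)", y = ylab,
                  title = "Cluster thermal profiles") +
    ggplot2::theme_minimal()
}
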