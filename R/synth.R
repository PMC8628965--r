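#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the generator in one list so that identical
#' configurations give bit-identical data. Defaults emulate a
#' magnesium-dependent, pseudoknotted RNA probed along a thermal
#' denaturation series:
#'
#' * `class_means` — 37 degC mean reactivity per structural class, aligned
#'   with the conventional display bins (single strands high ~0.9, paired
#'   nucleotides low ~0.1, tertiary contacts moderate ~0.5).
#' * `plateau` — reactivity every class approaches once denatured (0.9).
#' * `midpoints_C` / `width_C` — logistic temperature-response midpoint per
#'   class and common width (degC). Tertiary contacts, pseudoknot and
#'   kissing-loop strands open first (midpoint 45 degC), regular helices
#'   with the bulk of the secondary structure (66 degC, where the melting
#'   data place the onset of secondary-structure unfolding), the stable
#'   helix only towards the top of the range (90 degC). Single strands have no
#'   transition; their apparent reactivity drifts down by `ss_drift` across
#'   the range, mimicking the effect of per-profile normalization as
#'   everything else becomes reactive.
#' * `mg_effect` — reactivity added to a class when magnesium is absent.
#'   Only tertiary-dependent classes respond, and of the two pseudoknot
#'   strands only the 3' strand: the 5' strand is modelled as adopting an
#'   alternative pairing without Mg, leaving its reactivity unchanged — the
#'   asymmetry that makes the pseudoknot hard to see one-sided.
#' * `noise_sd` — replicate Gaussian noise, in normalized SHAPE units.
#' * `undetermined_frac` — fraction of positions with no usable signal.
#' * `melt_*` — fluorescence melt model: linear dye-decay baseline minus
#'   one sigmoidal fluorescence drop per transition (so `-dRFU/dT` peaks at
#'   each Tm), on a 37-95 degC grid.
#' * `amp_mean`, `amp_sd`, `phase_sd` — pucker jitter for trajectory
#'   simulation (degrees).
#'
#' @param seed Integer seed; every generator draw derives from it.
#' @param ... Named overrides of any default listed above.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 42, ...) {
  cfg <- list(
    seed = as.integer(seed),
    class_means = c(SS = 0.90, HELIX = 0.10, STABLE_HELIX = 0.08,
                    TERT = 0.50, PK5 = 0.15, PK3 = 0.15, KL = 0.45),
    plateau = 0.90,
    midpoints_C = c(SS = NA, HELIX = 66, STABLE_HELIX = 90,
                    TERT = 45, PK5 = 45, PK3 = 45, KL = 45),
    width_C = 4,
    ss_drift = 0.2,
    mg_effect = c(SS = 0, HELIX = 0, STABLE_HELIX = 0,
                  TERT = 0.4, PK5 = 0, PK3 = 0.4, KL = 0.4),
    noise_sd = 0.04,
    undetermined_frac = 0.006,
    n_replicates = 3L,
    melt_transitions = tibble(tm = c(57, 80), height = c(150, 250)),
    melt_width_C = 1.5,
    melt_baseline = 900,
    melt_decay = 3,
    melt_noise_sd = 0.5,
    melt_grid = seq(37, 95, by = 0.5),
    pucker_mixtures = tibble(
      residue = c(10L, 83L, 83L, 161L, 161L),
      family = c("C3'-endo", "C2'-endo", "C3'-endo", "C3'-endo", "C2'-exo"),
      weight = c(1, 0.4, 0.6, 0.7, 0.3)
    ),
    amp_mean = 38.6,
    amp_sd = 3,
    phase_sd = 5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown generator option(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (cfg$noise_sd < 0 || cfg$melt_noise_sd < 0 || cfg$amp_sd < 0 ||
      cfg$phase_sd < 0) {
    abort("Noise standard deviations must be non-negative.")
  }
  if (cfg$undetermined_frac < 0 || cfg$undetermined_frac > 1) {
    abort("`undetermined_frac` must be in [0, 1].")
  }
  structure(cfg, class = "generator_config")
}

STRUCT_CLASSES <- c("SS", "HELIX", "STABLE_HELIX", "TERT", "PK5", "PK3", "KL")

#' Generate a synthetic structure annotation
#'
#' Lays out a pseudoknotted RNA of the requested length containing every
#' structural class the reactivity model distinguishes: single strands
#' (SS), three regular helices (HELIX), one stable helix (STABLE_HELIX),
#' tertiary-contact stretches (TERT), an H-type pseudoknot whose 5' strand
#' sits in a hairpin loop and pairs with a downstream 3' strand
#' (PK5/PK3, complementary), and a kissing-loop pair between two hairpin
#' loops (KL, complementary). The dot-bracket string carries the secondary
#' helices as parentheses and the pseudoknot as one bracket layer; the
#' kissing interaction, being tertiary, is left unpaired there.
#'
#' @param seed Integer seed for the random sequence.
#' @param length Total length in nucleotides (>= 60).
#' @return A list of class `structure_annotation`: `annotation` (tibble
#'   `position`, `base`, `class`), `sequence`, `dotbracket`, `segments`
#'   (tibble `name`, `class`, `start`, `end`).
#' @export
make_structure <- function(seed = 42, length = 188) {
  if (length < 60) abort("`length` must be at least 60 to host all motifs.")
  base_len <- c(
    ss1 = 3, h1_5 = 3, ssa = 1, pk5 = 4, ssb = 1, h1_3 = 3,
    ss2 = 3, sh_5 = 3, tert1 = 4, sh_3 = 3, ss3 = 2, pk3 = 4,
    ss4 = 2, h2_5 = 3, kl1 = 4, h2_3 = 3, ss5 = 2, h3_5 = 3,
    kl2 = 4, h3_3 = 3, tert2 = 2
  )
  stopifnot(sum(base_len) == 60)
  # Deterministic round-robin growth: stems/pseudoknot/kissing strands grow
  # on both sides at once to keep complementarity.
  slots <- list(
    list(segs = "ss2", cost = 1), list(segs = c("h1_5", "h1_3"), cost = 2),
    list(segs = "tert1", cost = 1), list(segs = c("sh_5", "sh_3"), cost = 2),
    list(segs = "ss4", cost = 1), list(segs = c("h2_5", "h2_3"), cost = 2),
    list(segs = "tert2", cost = 1), list(segs = c("h3_5", "h3_3"), cost = 2),
    list(segs = "ss1", cost = 1), list(segs = c("pk5", "pk3"), cost = 2),
    list(segs = c("kl1", "kl2"), cost = 2), list(segs = "ss5", cost = 1)
  )
  extra <- length - 60L
  i <- 1L
  while (extra > 0L) {
    slot <- slots[[(i - 1L) %% length(slots) + 1L]]
    if (slot$cost <= extra) {
      base_len[slot$segs] <- base_len[slot$segs] + 1L
      extra <- extra - slot$cost
    }
    i <- i + 1L
  }
  seg_class <- c(
    ss1 = "SS", h1_5 = "HELIX", ssa = "SS", pk5 = "PK5", ssb = "SS",
    h1_3 = "HELIX", ss2 = "SS", sh_5 = "STABLE_HELIX", tert1 = "TERT",
    sh_3 = "STABLE_HELIX", ss3 = "SS", pk3 = "PK3", ss4 = "SS",
    h2_5 = "HELIX", kl1 = "KL", h2_3 = "HELIX", ss5 = "SS",
    h3_5 = "HELIX", kl2 = "KL", h3_3 = "HELIX", tert2 = "TERT"
  )
  ends <- cumsum(base_len)
  starts <- ends - base_len + 1L
  segments <- tibble(name = names(base_len),
                     class = unname(seg_class[names(base_len)]),
                     start = unname(starts), end = unname(ends))

  seqs <- with_seed(seed, {
    draw <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)
    s <- lapply(base_len, draw)
    s$h1_3 <- revcomp(s$h1_5)
    s$sh_3 <- revcomp(s$sh_5)
    s$h2_3 <- revcomp(s$h2_5)
    s$h3_3 <- revcomp(s$h3_5)
    s$pk3 <- revcomp(s$pk5)
    s$kl2 <- revcomp(s$kl1)
    s
  })
  sequence <- unlist(seqs[names(base_len)], use.names = FALSE)

  db <- rep(".", length)
  brk <- function(seg, ch) {
    db[starts[seg]:ends[seg]] <<- ch
  }
  brk("h1_5", "("); brk("h1_3", ")")
  brk("sh_5", "("); brk("sh_3", ")")
  brk("h2_5", "("); brk("h2_3", ")")
  brk("h3_5", "("); brk("h3_3", ")")
  brk("pk5", "["); brk("pk3", "]")

  annotation <- tibble(
    position = seq_len(length),
    base = sequence,
    class = rep(segments$class, base_len)
  )
  structure(list(annotation = annotation,
                 sequence = paste(sequence, collapse = ""),
                 dotbracket = paste(db, collapse = ""),
                 segments = segments),
            class = "structure_annotation")
}

revcomp <- function(x) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  rev(unname(comp[x]))
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(sprintf("<structure_annotation> %d nt\n", nrow(x$annotation)))
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n")
  invisible(x)
}

# Expected (noise-free) reactivity of each class at one condition.
class_mean_reactivity <- function(class, temperature_C, mg_mM, cfg) {
  base <- cfg$class_means[class]
  mid <- cfg$midpoints_C[class]
  resp <- ifelse(
    is.na(mid),
    # single strands: slight apparent drift down with temperature,
    # anchored on the 37-85 degC probing range
    -cfg$ss_drift * (temperature_C - 37) / 48,
    (cfg$plateau - base) * plogis((temperature_C - mid) / cfg$width_C)
  )
  mg <- if (mg_mM == 0) cfg$mg_effect[class] else 0
  unname(base + resp + mg)
}

#' Simulate a replicate reactivity table for one condition
#'
#' Draws a triplicate (by default) reactivity table for the annotated
#' structure under one probing condition. The per-position mean is the
#' class baseline plus a logistic temperature response (archetype midpoints
#' per class, see [generator_config()]) plus a magnesium term when the
#' condition lacks Mg; replicates add Gaussian noise, and a configured
#' fraction of positions is made undetermined. Deterministic given the
#' configuration seed and the condition.
#'
#' @param ann A `structure_annotation` from [make_structure()].
#' @param condition One-row condition tibble from [shape_condition()].
#' @param cfg A [generator_config()].
#' @return Long replicate tibble (`position`, `base`, `replicate`,
#'   `reactivity`, condition columns) with attribute `truth`: tibble
#'   `position`, `class`, `true_mean`.
#' @export
simulate_reactivities <- function(ann, condition, cfg = generator_config()) {
  stopifnot(inherits(ann, "structure_annotation"))
  an <- ann$annotation
  if (!all(an$class %in% STRUCT_CLASSES)) {
    abort("Unknown structural class in annotation.")
  }
  mu <- class_mean_reactivity(an$class, condition$temperature_C,
                              condition$mg_mM, cfg)
  n <- nrow(an)
  k <- cfg$n_replicates
  seed_i <- derive_seed(cfg$seed, round(condition$temperature_C * 100),
                        round(condition$mg_mM * 100),
                        match(condition$probe, c("1M7", "NMIA", "BzCN")))
  out <- with_seed(seed_i, {
    vals <- rep(mu, each = k) + rnorm(n * k, sd = cfg$noise_sd)
    und <- runif(n) < cfg$undetermined_frac
    vals[rep(und, each = k)] <- NA_real_
    tibble(
      position = rep(an$position, each = k),
      base = rep(an$base, each = k),
      replicate = rep(paste0("rep", seq_len(k)), times = n),
      reactivity = vals
    )
  })
  out <- dplyr::bind_cols(out, condition[rep(1L, nrow(out)), , drop = FALSE])
  attr(out, "truth") <- tibble(position = an$position, class = an$class,
                               true_mean = mu)
  out
}

# Fold auxiliary integers into one 32-bit-safe seed.
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483629
  for (k in list(...)) {
    x <- (x * 69069 + as.double(k) + 1) %% 2147483629
  }
  as.integer(x)
}

#' Simulate replicate fluorescence melt curves
#'
#' Models the dye-based melt experiment: a linearly decaying fluorescence
#' baseline (dye binding weakens with temperature) minus one sigmoidal
#' fluorescence drop per melting transition, plus Gaussian noise, in
#' triplicate. With this sign convention `-dRFU/dT` has a maximum at each
#' planted Tm, as expected for derivative melt analysis.
#'
#' @param cfg A [generator_config()]; `melt_transitions` (tibble `tm`,
#'   `height`) plants the transitions — an empty tibble gives pure decay.
#' @param mg_mM Optional Mg concentration attached as a column.
#' @return Tibble `temperature_C`, `rfu`, `replicate` (+ `mg_mM`), with
#'   attribute `truth` holding the transition table.
#' @export
simulate_melt <- function(cfg = generator_config(), mg_mM = NULL) {
  tr <- cfg$melt_transitions
  grid <- cfg$melt_grid
  base <- cfg$melt_baseline - cfg$melt_decay * (grid - grid[1])
  if (nrow(tr)) {
    for (j in seq_len(nrow(tr))) {
      base <- base - tr$height[j] * plogis((grid - tr$tm[j]) / cfg$melt_width_C)
    }
  }
  seed_i <- derive_seed(cfg$seed, 77L, round((mg_mM %||% -1) * 100))
  out <- with_seed(seed_i, {
    purrr::map_dfr(seq_len(cfg$n_replicates), function(r) {
      tibble(temperature_C = grid,
             rfu = base + rnorm(length(grid), sd = cfg$melt_noise_sd),
             replicate = paste0("rep", r))
    })
  })
  if (!is.null(mg_mM)) out$mg_mM <- mg_mM
  attr(out, "truth") <- tr
  out
}

#' Simulate a per-frame ring-dihedral trajectory
#'
#' Draws, for each configured nucleotide and frame, a pucker family from
#' its mixture weights, then builds the five ring dihedrals by inverse
#' pseudorotation at the family's centre phase with Gaussian jitter on
#' amplitude and phase.
#'
#' @param cfg A [generator_config()]; `pucker_mixtures` (tibble `residue`,
#'   `family`, `weight`, weights summing to 1 per residue) defines the
#'   conformational ensemble.
#' @param n_frames Number of trajectory frames.
#' @return Tibble `frame`, `residue`, `v1`..`v5` with attribute `truth`
#'   holding the mixture table.
#' @export
simulate_dihedrals <- function(cfg = generator_config(), n_frames = 500) {
  mix <- cfg$pucker_mixtures
  if (!all(c("residue", "family", "weight") %in% names(mix))) {
    abort("`pucker_mixtures` needs columns residue, family, weight.")
  }
  if (!all(mix$family %in% PUCKER_FAMILIES)) {
    abort("Unknown pucker family in `pucker_mixtures`.")
  }
  sums <- tapply(mix$weight, mix$residue, sum)
  if (any(abs(sums - 1) > 1e-8) || any(mix$weight < 0)) {
    abort("Mixture weights must be non-negative and sum to 1 per residue.")
  }
  centers <- (match(mix$family, PUCKER_FAMILIES) - 1L) * 36 + 18
  out <- with_seed(derive_seed(cfg$seed, 131L, n_frames), {
    purrr::map_dfr(unique(mix$residue), function(res) {
      sel <- mix$residue == res
      fam_idx <- sample(which(sel), n_frames, replace = TRUE,
                        prob = mix$weight[sel])
      amp <- cfg$amp_mean + rnorm(n_frames, sd = cfg$amp_sd)
      phase <- centers[fam_idx] + rnorm(n_frames, sd = cfg$phase_sd)
      v <- inverse_pseudorotation(amp, phase)
      dplyr::bind_cols(tibble(frame = seq_len(n_frames), residue = res), v)
    })
  })
  attr(out, "truth") <- mix
  out
}

#' Simulate the full temperature series and its planted truth
#'
#' Convenience wrapper: simulates replicate tables at each requested
#' temperature (fixed probe and Mg), aggregates them, and returns both the
#' profiles and the planted thermal-archetype truth used by clustering
#' tests.
#'
#' @param ann A `structure_annotation`.
#' @param cfg A [generator_config()].
#' @param temperatures Probing temperatures (degC).
#' @param probe,mg_mM Fixed probe and Mg concentration for the series.
#' @param filter Apply [filter_outliers()] before aggregation (default
#'   TRUE).
#' @return A list: `profiles` (long aggregated tibble across temperatures),
#'   `replicates` (list of replicate tibbles keyed by temperature),
#'   `truth` (tibble `position`, `class`, `archetype`).
#' @export
simulate_temperature_series <- function(ann, cfg = generator_config(),
                                        temperatures = c(37, 53, 65, 74, 85),
                                        probe = "1M7", mg_mM = 5,
                                        filter = TRUE) {
  reps <- lapply(temperatures, function(tc) {
    r <- simulate_reactivities(
      ann, shape_condition(probe, mg_mM = mg_mM, temperature_C = tc), cfg
    )
    if (filter) r <- suppressMessages(filter_outliers(r))
    r
  })
  names(reps) <- as.character(temperatures)
  profiles <- dplyr::bind_rows(lapply(reps, aggregate_replicates))
  archetype_map <- c(SS = "always_reactive", TERT = "tertiary_37_53",
                     PK5 = "tertiary_37_53", PK3 = "tertiary_37_53",
                     KL = "tertiary_37_53", HELIX = "secondary_65",
                     STABLE_HELIX = "stable_85")
  truth <- dplyr::mutate(ann$annotation,
                         archetype = unname(archetype_map[.data$class]))
  list(profiles = profiles, replicates = reps, truth = truth)
}
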