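# Independent oracles and small builders shared across tests.
# These deliberately re-derive results from first principles (explicit
# formulas, exhaustive enumeration) rather than calling the package's own
# code paths.

# Build a long replicate tibble from a named list position -> replicate values.
make_reps <- function(values_by_pos, base = "A") {
  dplyr::bind_rows(lapply(names(values_by_pos), function(p) {
    v <- values_by_pos[[p]]
    tibble::tibble(
      position = as.integer(p),
      base = base,
      replicate = paste0("rep", seq_along(v)),
      reactivity = v
    )
  }))
}

# Welch two-sample two-sided t-test from the defining formulas.
welch_p_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Brute-force evaluation of the three-criterion differential rule.
sig_oracle <- function(x, y, dr = 0.2, rel = 0.2, alpha = 0.05) {
  R1 <- mean(x); R2 <- mean(y)
  dR <- abs(R1 - R2)
  if (R1 + R2 <= 0) return(FALSE)
  relc <- dR / (R1 + R2)
  p <- welch_p_oracle(x, y)
  dR > dr && relc > rel && p < alpha
}

# Exhaustive helix enumeration: every (i, j, L) substring pair is tested
# directly for candidate membership, complementarity, strand separation and
# maximality.
helix_oracle <- function(sequence, candidates, min_len = 3, allow_gu = TRUE) {
  s <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1]]
  n <- length(s)
  cand <- logical(n); cand[candidates] <- TRUE
  pair_ok <- function(i, j) {
    if (i < 1 || j > n || j <= i) return(FALSE)
    if (!cand[i] || !cand[j]) return(FALSE)
    x <- s[i]; y <- s[j]
    wc <- (x == "A" && y == "U") || (x == "U" && y == "A") ||
      (x == "G" && y == "C") || (x == "C" && y == "G")
    gu <- (x == "G" && y == "U") || (x == "U" && y == "G")
    wc || (allow_gu && gu)
  }
  found <- list()
  for (i in 1:n) for (j in seq_len(n)[-seq_len(i)]) {
   maxL <- floor((j - i + 1) / 2)
   if (maxL < min_len) next
   for (L in min_len:maxL) {
    ok <- TRUE
    for (k in 0:(L - 1)) {
      if (!(i + k < j - k) || !pair_ok(i + k, j - k)) { ok <- FALSE; break }
    }
    if (!ok) next
    # maximal: no valid pair outside or inside the stretch
    if (pair_ok(i - 1, j + 1)) next
    if (i + L < j - L && pair_ok(i + L, j - L)) next
    found[[length(found) + 1]] <- c(i = i, j = j, L = L)
   }
  }
  if (!length(found)) {
    return(tibble::tibble(i_start = integer(), j_start = integer(),
                          length = integer()))
  }
  out <- tibble::as_tibble(do.call(rbind, found))
  names(out) <- c("i_start", "j_start", "length")
  dplyr::arrange(dplyr::distinct(out), dplyr::desc(length), i_start)
}
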