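profiles_from_matrix <- function(m, temps) {
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m, .name_repair = ~ as.character(temps)),
                  position = seq_len(nrow(m))),
    -position, names_to = "temperature_C", values_to = "reactivity",
    names_transform = as.numeric
  )
}

test_that("positions with any undetermined value are dropped from the matrix", {
  m <- matrix(runif(20, 0.1, 1), nrow = 4)
  prof <- profiles_from_matrix(m, c(37, 53, 65, 74, 85))
  prof$reactivity[prof$position == 2 & prof$temperature_C == 65] <- NA
  tm <- build_temperature_matrix(prof)
  expect_equal(nrow(tm$matrix), 3)
  expect_equal(tm$dropped_positions, 2)
  # complete data: nothing dropped
  tm_full <- build_temperature_matrix(profiles_from_matrix(m, c(37, 53, 65, 74, 85)))
  expect_equal(nrow(tm_full$matrix), 4)
  # a position absent from one profile counts as undetermined
  prof_miss <- dplyr::filter(prof, !(position == 3 & temperature_C == 85))
  expect_equal(sort(build_temperature_matrix(prof_miss)$dropped_positions),
               c(2, 3))
})

test_that("fewer than two temperatures is an error", {
  prof <- tibble::tibble(position = 1:4, temperature_C = 37,
                         reactivity = runif(4))
  expect_error(build_temperature_matrix(prof), "two temperatures")
})

test_that("transform floors, logs and doubly standardizes", {
  set.seed(601)
  m <- matrix(runif(50, 0.05, 1.2), nrow = 10)
  tm <- build_temperature_matrix(profiles_from_matrix(m, c(37, 53, 65, 74, 85)))
  tr <- transform_reactivity(tm)
  expect_true(tr$transformed)
  expect_equal(unname(colMeans(tr$matrix)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(tr$matrix, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # zero value gets floored, not -Inf
  m0 <- m; m0[1, 1] <- 0
  tr0 <- transform_reactivity(
    build_temperature_matrix(profiles_from_matrix(m0, c(37, 53, 65, 74, 85))))
  expect_true(all(is.finite(tr0$matrix)))
  # constant row: centered, scaling skipped, flagged
  mc <- m; mc[3, ] <- 0.5
  trc <- transform_reactivity(
    build_temperature_matrix(profiles_from_matrix(mc, c(37, 53, 65, 74, 85))))
  expect_true(3 %in% attr(trc, "flat_rows"))
  expect_true(all(is.finite(trc$matrix)))
})

test_that("transform is invariant to uniform positive rescaling", {
  set.seed(602)
  m <- matrix(runif(60, 0.05, 1.5), nrow = 12)
  temps <- c(37, 53, 65, 74, 85)
  t1 <- transform_reactivity(build_temperature_matrix(profiles_from_matrix(m, temps)))
  # rescale by 3x; floor scaled too so the clamp acts identically
  t3 <- transform_reactivity(
    build_temperature_matrix(profiles_from_matrix(3 * m, temps)), floor = 0.03)
  expect_equal(t1$matrix, t3$matrix, tolerance = 1e-10)
})

test_that("k-means distortion has its closed forms at k = 1 and k = n", {
  set.seed(603)
  m <- matrix(rnorm(40), nrow = 8)
  tm <- build_temperature_matrix(profiles_from_matrix(abs(m) + 0.1,
                                                      c(37, 53, 65, 74, 85)))
  tr <- transform_reactivity(tm)
  k1 <- cluster_nucleotides(tr, 1)
  expect_equal(k1$distortion,
               sum(sweep(tr$matrix, 2, colMeans(tr$matrix))^2),
               tolerance = 1e-10)
  kn <- cluster_nucleotides(tr, nrow(tr$matrix))
  expect_equal(kn$distortion, 0, tolerance = 1e-10)
  expect_error(cluster_nucleotides(tr, nrow(tr$matrix) + 1), "between 1 and")
})

test_that("clustering is reproducible and distortion non-increasing in k", {
  ann <- make_structure(7, 120)
  series <- simulate_temperature_series(ann, generator_config(seed = 7))
  tr <- transform_reactivity(build_temperature_matrix(series$profiles))
  a <- cluster_nucleotides(tr, 4, seed = 123, n_restarts = 10)
  b <- cluster_nucleotides(tr, 4, seed = 123, n_restarts = 10)
  expect_identical(a$labels, b$labels)
  expect_identical(a$distortion, b$distortion)
  eb <- suppressWarnings(elbow_k(tr, k_max = 8, seed = 123, n_restarts = 20))
  expect_true(all(diff(eb$curve$distortion) <= 1e-6))
})

test_that("duplicated vectors force a zero-distortion elbow at their count", {
  base <- matrix(c(0.1, 0.2, 0.9, 0.4, 0.6,
                   0.8, 0.1, 0.2, 0.9, 0.3,
                   0.5, 0.9, 0.1, 0.2, 0.7), nrow = 3, byrow = TRUE)
  m <- base[rep(1:3, each = 6), ]
  tm <- build_temperature_matrix(profiles_from_matrix(m, c(37, 53, 65, 74, 85)))
  tr <- transform_reactivity(tm)
  eb <- suppressWarnings(elbow_k(tr, k_max = 6, seed = 1))
  expect_equal(eb$curve$distortion[3], 0, tolerance = 1e-10)
  expect_equal(eb$chosen_k, 3L)
  # trivial curve
  eb1 <- elbow_k(tr, k_max = 1, seed = 1)
  expect_equal(eb1$chosen_k, 1L)
})

test_that("planted thermal archetypes are recovered and labelled", {
  ann <- make_structure(42, 188)
  series <- simulate_temperature_series(ann, generator_config(seed = 42))
  tm_raw <- build_temperature_matrix(series$profiles)
  tr <- transform_reactivity(tm_raw)
  cl <- label_archetypes(cluster_nucleotides(tr, 4, seed = 42), tm_raw)
  expect_setequal(cl$archetype,
                  c("always_reactive", "tertiary_37_53", "secondary_65",
                    "stable_85"))
  truth <- series$truth$archetype[match(cl$labels$position,
                                        series$truth$position)]
  recovered <- cl$archetype[cl$labels$cluster]
  expect_gt(mean(recovered == truth), 0.95)
  td <- tidy(cl)
  expect_named(td, c("position", "cluster", "archetype"))
  expect_equal(glance(cl)$k, 4L)
})

test_that("archetype labelling follows the raw centroid rise", {
  temps <- c(37, 53, 65, 74, 85)
  raw <- rbind(
    matrix(rep(c(0.9, 0.88, 0.85, 0.8, 0.78), each = 3), nrow = 3),   # flat high
    matrix(rep(c(0.1, 0.1, 0.1, 0.12, 0.5), each = 3), nrow = 3)      # late riser
  )
  raw <- raw + matrix(rnorm(30, 0, 1e-3), nrow = 6)
  tm <- build_temperature_matrix(profiles_from_matrix(raw, temps))
  tr <- transform_reactivity(tm)
  cl <- cluster_nucleotides(tr, 2, seed = 5)
  expect_warning(l2 <- label_archetypes(cl, tm), "k = 4")
  expect_true(all(l2$archetype == "unassigned"))
  # with k = 4 on four planted shapes, each label is forced by its rise
  raw4 <- rbind(
    matrix(rep(c(0.90, 0.85, 0.80, 0.78, 0.75), each = 4), nrow = 4),
    matrix(rep(c(0.20, 0.80, 0.85, 0.88, 0.90), each = 4), nrow = 4),
    matrix(rep(c(0.10, 0.12, 0.30, 0.80, 0.88), each = 4), nrow = 4),
    matrix(rep(c(0.08, 0.08, 0.09, 0.10, 0.40), each = 4), nrow = 4)
  ) + matrix(rnorm(80, 0, 1e-3), nrow = 16)
  tm4 <- build_temperature_matrix(profiles_from_matrix(raw4, temps))
  cl4 <- label_archetypes(cluster_nucleotides(transform_reactivity(tm4), 4,
                                              seed = 5), tm4)
  lab <- cl4$archetype[cl4$labels$cluster]
  expect_equal(lab[1], "always_reactive")
  expect_equal(lab[5], "tertiary_37_53")
  expect_equal(lab[9], "secondary_65")
  expect_equal(lab[13], "stable_85")
})
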