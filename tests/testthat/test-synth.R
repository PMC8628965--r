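test_that("the structure layout is deterministic and hosts every motif", {
  ann <- make_structure(42, 188)
  expect_equal(nrow(ann$annotation), 188)
  expect_setequal(unique(ann$annotation$class),
                  c("SS", "HELIX", "STABLE_HELIX", "TERT", "PK5", "PK3", "KL"))
  expect_identical(make_structure(42, 188)$sequence, ann$sequence)
  expect_false(identical(make_structure(43, 188)$sequence, ann$sequence))
  # minimal length still contains all classes
  small <- make_structure(1, 60)
  expect_setequal(unique(small$annotation$class),
                  c("SS", "HELIX", "STABLE_HELIX", "TERT", "PK5", "PK3", "KL"))
  expect_error(make_structure(1, 59), "at least 60")
})

test_that("pseudoknot and kissing-loop strands are complementary", {
  ann <- make_structure(42, 188)
  seg <- ann$segments
  span <- function(nm) {
    r <- seg[seg$name == nm, ]
    strsplit(ann$sequence, "")[[1]][r$start:r$end]
  }
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  expect_identical(span("pk3"), rev(unname(comp[span("pk5")])))
  expect_identical(span("kl2"), rev(unname(comp[span("kl1")])))
  # dot-bracket layers balance
  db <- strsplit(ann$dotbracket, "")[[1]]
  expect_equal(sum(db == "("), sum(db == ")"))
  expect_equal(sum(db == "["), sum(db == "]"))
  expect_gt(sum(db == "["), 0)
  # the pseudoknot crosses a secondary helix: some "(" lies between [ and ]
  expect_true(any(db[which(db == "[")[1]:which(db == "]")[1]] == ")"))
})

test_that("zero-noise simulation reproduces the class means exactly", {
  ann <- make_structure(5, 80)
  cfg <- generator_config(seed = 5, noise_sd = 0, undetermined_frac = 0)
  reps <- simulate_reactivities(ann, shape_condition("1M7", 5, 37), cfg)
  truth <- attr(reps, "truth")
  prof <- aggregate_replicates(reps)
  expect_equal(prof$reactivity, truth$true_mean, tolerance = 1e-12)
  expect_equal(prof$sd, rep(0, nrow(prof)))
  # same seed, same condition: bit-identical
  reps2 <- simulate_reactivities(ann, shape_condition("1M7", 5, 37), cfg)
  expect_identical(reps$reactivity, reps2$reactivity)
})

test_that("magnesium removal raises only Mg-dependent classes", {
  ann <- make_structure(5, 120)
  cfg <- generator_config(seed = 5, noise_sd = 0, undetermined_frac = 0)
  with_mg <- attr(simulate_reactivities(ann, shape_condition("1M7", 5, 37), cfg),
                  "truth")
  no_mg <- attr(simulate_reactivities(ann, shape_condition("1M7", 0, 37), cfg),
                "truth")
  delta <- no_mg$true_mean - with_mg$true_mean
  expect_true(all(delta[with_mg$class %in% c("TERT", "KL", "PK3")] == 0.4))
  expect_true(all(delta[with_mg$class %in% c("PK5", "SS", "HELIX",
                                             "STABLE_HELIX")] == 0))
})

test_that("temperature responses follow the planted archetypes", {
  ann <- make_structure(5, 120)
  cfg <- generator_config(seed = 5, noise_sd = 0, undetermined_frac = 0)
  mean_at <- function(tc) {
    attr(simulate_reactivities(ann, shape_condition("1M7", 5, tc), cfg),
         "truth")$true_mean
  }
  cls <- ann$annotation$class
  m37 <- mean_at(37); m53 <- mean_at(53); m74 <- mean_at(74); m85 <- mean_at(85)
  tert <- cls %in% c("TERT", "PK5", "PK3", "KL")
  expect_true(all(m53[tert] - m37[tert] > 0.2))      # early melters rise first
  helix <- cls == "HELIX"
  expect_true(all(m53[helix] - m37[helix] < 0.05))   # helices hold at 53
  expect_true(all(m74[helix] > 0.6))                 # and open by 74
  stable <- cls == "STABLE_HELIX"
  expect_true(all(m74[stable] < 0.2))                # stable helix holds at 74
  ss <- cls == "SS"
  expect_true(all(m37[ss] > 0.7))                    # single strands reactive
  expect_true(all(m85[ss] < m37[ss]))                # with the apparent drift
})

test_that("melt simulation is deterministic with a truth attribute", {
  cfg <- generator_config(seed = 9)
  a <- simulate_melt(cfg, mg_mM = 5)
  b <- simulate_melt(cfg, mg_mM = 5)
  expect_identical(a$rfu, b$rfu)
  expect_equal(attr(a, "truth")$tm, c(57, 80))
  # no transitions, no noise: strictly decreasing dye decay
  flat <- simulate_melt(generator_config(
    seed = 9, melt_noise_sd = 0,
    melt_transitions = tibble::tibble(tm = double(), height = double())
  ))
  one <- dplyr::filter(flat, replicate == "rep1")
  expect_true(all(diff(one$rfu) < 0))
})

test_that("dihedral simulation respects mixtures and jitter settings", {
  # zero jitter: every frame sits exactly on its family centre phase
  cfg0 <- generator_config(seed = 3, amp_sd = 0, phase_sd = 0,
                           pucker_mixtures = tibble::tibble(
                             residue = 1L, family = "C2'-endo", weight = 1))
  fr <- simulate_dihedrals(cfg0, n_frames = 25)
  st <- pseudorotation(fr)
  expect_equal(st$phase_deg, rep(162, 25), tolerance = 1e-9)
  expect_equal(st$amp, rep(38.6, 25), tolerance = 1e-9)
  # invalid weights are rejected
  badcfg <- generator_config(seed = 3, pucker_mixtures = tibble::tibble(
    residue = 1L, family = c("C2'-endo", "C3'-endo"), weight = c(0.5, 0.4)))
  expect_error(simulate_dihedrals(badcfg, 10), "sum to 1")
  # determinism
  cfg <- generator_config(seed = 4)
  expect_identical(simulate_dihedrals(cfg, 50), simulate_dihedrals(cfg, 50))
})

test_that("generator configuration validates its inputs", {
  expect_error(generator_config(seed = 1, not_a_knob = 2), "Unknown generator")
  expect_error(generator_config(seed = 1, noise_sd = -0.1), "non-negative")
  expect_error(generator_config(seed = 1, undetermined_frac = 1.5), "0, 1")
})
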