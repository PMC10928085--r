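# Synthetic data generator: profile separation, labeling kinetics,
# reporter spillover composition, determinism, planted-event plumbing.

ISO_AREA_COLS_TEST <- paste0("area_", c("m0", "m8", "m10", "m16", "m18",
                                        "m20"))

test_that("compartment profiles are separated simplex vectors", {
  p <- simulate_compartment_profiles(12, 10, concentration = 5, seed = 1,
                                     min_distance = 0.05)
  expect_equal(unname(rowSums(p)), rep(1, 12), tolerance = 1e-12)
  expect_gte(attr(p, "min_pairwise_distance"), 0.05)
  p2 <- simulate_compartment_profiles(12, 10, concentration = 5, seed = 1,
                                      min_distance = 0.05)
  expect_identical(p, p2)                     # seed determinism
  # near-delta concentration on 2 fractions: profiles approach extremes
  d <- simulate_compartment_profiles(2, 2, concentration = 0.02, seed = 2,
                                     min_distance = 1)
  expect_true(all(apply(d, 1, max) > 0.95))
  expect_error(
    simulate_compartment_profiles(40, 2, concentration = 1, seed = 1,
                                  min_distance = 0.9, max_tries = 20),
    "retry budget exhausted")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_fractions = 1), "n_fractions")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(sim_config(dl_fraction = 0.7, partition_fraction = 0.5),
               "dl_fraction")
  expect_error(sim_config(conditions = c("a", "a")), "unique")
  expect_error(sim_config(rate_range = c(0.5, 0.1)), "rate_range")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("noiseless labeling obeys first-order fractional synthesis exactly", {
  cfg <- sim_config(n_compartments = 3, n_proteins = 10,
                    markers_per_compartment = 6, noise_cv = 0,
                    junk_q_fraction = 0, conditions = "ctl", seed = 5)
  sim <- simulate_dataset(cfg)
  light <- sim$psm[sim$psm$species == "L", ]
  heavy_area <- rowSums(light[, setdiff(ISO_AREA_COLS_TEST, "area_m0")])
  fs_obs <- heavy_area / (heavy_area + light$area_m0)
  k <- sim$truth$k_ctl[match(light$accessions, sim$truth$accession)]
  expect_equal(unname(fs_obs), 1 - exp(-k * 16), tolerance = 1e-12)
})

test_that("total light+heavy abundance is independent of the rates", {
  base <- list(n_compartments = 3, n_proteins = 8,
               markers_per_compartment = 6, noise_cv = 0,
               junk_q_fraction = 0, conditions = "ctl", seed = 11)
  slow <- simulate_dataset(do.call(sim_config,
                                   c(base, list(rate_range = c(0.001, 0.01)))))
  fast <- simulate_dataset(do.call(sim_config,
                                   c(base, list(rate_range = c(0.1, 0.5)))))
  tot <- function(s) {
    l <- s$psm[s$psm$species == "L", ]
    rowSums(l[, ISO_AREA_COLS_TEST])
  }
  expect_equal(tot(slow), tot(fast), tolerance = 1e-9)
})

test_that("identity impurity and zero noise give uncorrupted channels", {
  cfg <- sim_config(n_compartments = 3, n_proteins = 6,
                    markers_per_compartment = 6, noise_cv = 0,
                    junk_q_fraction = 0, conditions = "ctl",
                    identity_impurity = TRUE, seed = 7)
  sim <- simulate_dataset(cfg)
  ch_cols <- grep("^intensity_", names(sim$psm), value = TRUE)
  row <- sim$psm[sim$psm$species == "L", ][1, ]
  des <- sim$design[sim$design$replicate == row$replicate, ]
  tot <- sum(row[, ISO_AREA_COLS_TEST])  # light + heavy envelope
  lightab <- row$area_m0
  prof <- sim$profiles[sim$truth$compartment[
    sim$truth$accession == row$accessions], ]
  expected <- lightab * prof[match(des$fraction, colnames(sim$profiles))]
  got <- as.numeric(row[, paste0("intensity_", des$channel)])
  expect_equal(got, unname(expected), tolerance = 1e-9)
})

test_that("spillover composes with the design so NNLS recovers truth", {
  cfg <- sim_config(n_compartments = 3, n_proteins = 6,
                    markers_per_compartment = 6, noise_cv = 0,
                    junk_q_fraction = 0, conditions = "ctl", seed = 9)
  sim <- simulate_dataset(cfg)
  ch_cols <- grep("^intensity_", names(sim$psm), value = TRUE)
  obs <- as.matrix(sim$psm[, ch_cols])
  rec <- correct_impurities(obs, sim$impurity)
  # recovered channel intensities match species abundance x profile
  light <- sim$psm$species == "L"
  des1 <- sim$design[sim$design$replicate == 1, ]
  sel <- which(light & sim$psm$replicate == 1)
  comp <- sim$truth$compartment[match(sim$psm$accessions[sel],
                                      sim$truth$accession)]
  prof <- sim$profiles[comp, , drop = FALSE]
  truth <- sim$psm$area_m0[sel] *
    prof[, match(des1$fraction, colnames(sim$profiles)), drop = FALSE]
  expect_equal(unname(rec[sel, ]), unname(truth), tolerance = 1e-8 *
                 max(truth))
})

test_that("datasets are deterministic given the seed and plant events", {
  s1 <- small_sim(seed = 3)
  s2 <- small_sim(seed = 3)
  expect_identical(s1$psm, s2$psm)
  expect_identical(s1$truth, s2$truth)
  tr <- s1$truth
  expect_equal(sum(tr$event == "DL"), 4L)          # 0.1 * 40
  expect_equal(sum(tr$event == "partition"), 2L)   # 0.05 * 40
  expect_true(all(tr$event[tr$is_marker] == "none"))
  # DL moves both species, partition only the heavy one
  dl <- tr[tr$event == "DL", ]
  expect_true(all(dl$comp_stress_L != dl$compartment))
  expect_true(all(dl$comp_stress_L == dl$comp_stress_H))
  pt <- tr[tr$event == "partition", ]
  expect_true(all(pt$comp_stress_L == pt$compartment))
  expect_true(all(pt$comp_stress_H != pt$compartment))
  # heavy rows carry SILAC modification masses
  h <- s1$psm[s1$psm$species == "H", ]
  expect_true(all(grepl("8\\.0142|10\\.0083", h$modifications)))
  expect_false(any(grepl("8\\.0142|10\\.0083",
                         s1$psm$modifications[s1$psm$species == "L"])))
})

test_that("written datasets round-trip through the readers", {
  sim <- simulate_dataset(sim_config(n_compartments = 3, n_proteins = 5,
                                     markers_per_compartment = 6,
                                     seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  psm <- read_psm_table(paths["psm"])
  expect_true(all(psm$q_value <= 0.01))
  expect_setequal(unique(psm$species), c("L", "H"))
  des <- read_design(paths["design"])
  expect_equal(nrow(des), nrow(sim$design))
  imp <- read_impurity_matrix(paths["impurity"])
  expect_equal(unclass(imp), unclass(sim$impurity), tolerance = 1e-12)
  mk <- read_markers(paths["markers"])
  expect_equal(mk$accession, sim$markers$accession)
})
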