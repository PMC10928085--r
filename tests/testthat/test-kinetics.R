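# Turnover kinetics: isotopomer integration, fractional synthesis,
# rate fitting, protein summaries and condition comparisons.

test_that("applicable isotopomer sets follow the K/R composition", {
  expect_equal(applicable_offsets(1, 0), c("m0", "m8"))
  expect_equal(applicable_offsets(0, 1), c("m0", "m10"))
  expect_equal(applicable_offsets(2, 0), c("m0", "m8", "m16"))
  expect_equal(applicable_offsets(1, 1), c("m0", "m8", "m10", "m18"))
  expect_equal(applicable_offsets(0, 2), c("m0", "m10", "m20"))
})

test_that("fractional synthesis matches the m0-over-sum definition", {
  expect_equal(fractional_synthesis(c(m0 = 300, m8 = 100), n_K = 1, n_R = 0),
               0.25)
  expect_equal(fractional_synthesis(c(m0 = 500, m8 = 0), n_K = 1, n_R = 0), 0)
  # two-lysine peptide: mixed-label m8 counts in the denominator
  expect_equal(fractional_synthesis(c(m0 = 50, m8 = 30, m16 = 20),
                                    n_K = 2, n_R = 0), 0.5)
  # areas at offsets outside the applicable set are ignored
  expect_equal(fractional_synthesis(c(m0 = 300, m8 = 100, m20 = 999),
                                    n_K = 1, n_R = 0), 0.25)
  expect_true(is.na(fractional_synthesis(c(m0 = 0, m8 = 0),
                                         n_K = 1, n_R = 0)))
  expect_error(fractional_synthesis(c(m0 = -1, m8 = 1), n_K = 1, n_R = 0),
               "negative")
})

test_that("fractional synthesis is invariant to uniform area scaling", {
  set.seed(11)
  for (i in 1:20) {
    a <- c(m0 = runif(1, 1, 100), m8 = runif(1, 0, 100),
           m16 = runif(1, 0, 50))
    s <- runif(1, 1e-3, 1e4)
    expect_equal(fractional_synthesis(a, 2, 0),
                 fractional_synthesis(a * s, 2, 0), tolerance = 1e-12)
  }
})

make_scan <- function(rt, mz, intensity, ms_level = 1L) {
  list(rt = rt, ms_level = ms_level, mz = mz, intensity = intensity)
}

test_that("isotopomer integration follows the trapezoid convention", {
  q <- list(mz = 500, charge = 2, n_K = 1, n_R = 0,
            first_ms2_rt = 100, last_ms2_rt = 110)
  # single scan: unit-width degenerate trapezoid
  env1 <- integrate_isotopomers(list(make_scan(100, 500, 100)), q)
  expect_equal(unname(env1$areas["m0"]), 100)
  # two scans 10 s apart: (100 + 200)/2 * 10 = 1500 intensity*s
  env2 <- integrate_isotopomers(list(make_scan(100, 500, 100),
                                     make_scan(110, 500, 200)), q)
  expect_equal(unname(env2$areas["m0"]), 1500)
  # heavy partner integrated at mz + 8.0142/z
  env3 <- integrate_isotopomers(list(
    make_scan(100, c(500, 500 + 8.0142 / 2), c(100, 40)),
    make_scan(110, c(500, 500 + 8.0142 / 2), c(200, 60))), q)
  expect_equal(unname(env3$areas["m8"]), 500)
})

test_that("integration respects ppm tolerance and window contracts", {
  q <- list(mz = 500, charge = 2, n_K = 1, n_R = 0,
            first_ms2_rt = 100, last_ms2_rt = 110)
  # peak displaced by 30 ppm contributes nothing at 25 ppm tolerance
  off <- integrate_isotopomers(list(make_scan(100, 500 * (1 + 30e-6), 100)),
                               q, ppm_tol = 25)
  expect_equal(unname(off$areas["m0"]), 0)
  # ... but is picked up when inside tolerance
  on <- integrate_isotopomers(list(make_scan(100, 500 * (1 + 20e-6), 100)),
                              q, ppm_tol = 25)
  expect_equal(unname(on$areas["m0"]), 100)
  # MS2 scans are never integrated
  ms2 <- integrate_isotopomers(list(make_scan(100, 500, 100),
                                    make_scan(105, 500, 999, ms_level = 2L)),
                               q)
  expect_equal(unname(ms2$areas["m0"]), 100)
  expect_error(integrate_isotopomers(list(), q), "empty")
  expect_warning(
    none <- integrate_isotopomers(list(make_scan(500, 500, 100)), q),
    "no MS1 scan")
  expect_true(all(none$areas == 0) && none$empty_window)
})

test_that("rate fitting recovers noiseless rates to 1e-6 relative", {
  # single observation: closed-form inversion
  for (k_true in c(0.048, 0.027, 0.005, 0.2)) {
    fs <- 1 - exp(-k_true * 16)
    fit <- fit_turnover_rate(16, fs)
    expect_equal(fit$k, k_true, tolerance = 1e-6)
  }
  # multi-timepoint round trip across the k*t range
  for (kt in c(0.01, 0.05, 0.5, 2, 4)) {
    k_true <- kt / 16
    t <- c(4, 8, 16)
    fit <- fit_turnover_rate(t, 1 - exp(-k_true * t),
                             weights = c(3, 2, 1) * 1e5)
    expect_equal(fit$k, k_true, tolerance = 1e-6)
    expect_equal(fit$half_life_h * fit$k, log(2), tolerance = 1e-9)
  }
})

test_that("rate fitting handles degenerate inputs per contract", {
  expect_equal(fit_turnover_rate(16, 0)$k, 0)
  expect_equal(fit_turnover_rate(c(4, 16), c(0, 0))$k, 0)
  expect_warning(f <- fit_turnover_rate(16, 1.2), "clipped")
  expect_lte(f$k, 10)
  expect_error(fit_turnover_rate(numeric(), numeric()), "no non-missing")
  expect_error(fit_turnover_rate(0, 0.5), "> 0")
  # weighting pulls the estimate toward the heavy observation
  t <- c(8, 8); fs <- 1 - exp(-c(0.05, 0.2) * t)
  k_lo <- fit_turnover_rate(t, fs, weights = c(100, 1))$k
  k_hi <- fit_turnover_rate(t, fs, weights = c(1, 100))$k
  expect_lt(k_lo, k_hi)
})

test_that("half-life follows the first-order relation", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.01), 69.31, tolerance = 1e-3)
  expect_identical(half_life(0), Inf)
  expect_error(half_life(-0.1), "non-negative")
})

test_that("protein summaries use median and raw MAD of peptide rates", {
  f <- data.frame(accession = rep("P1", 3), k = c(0.1, 0.1, 0.1))
  s <- protein_rate_summary(f)
  expect_equal(s$median_k, 0.1)
  expect_equal(s$mad_k, 0)
  s2 <- protein_rate_summary(data.frame(accession = "P2",
                                        k = c(0.1, 0.2, 0.4)))
  expect_equal(s2$median_k, 0.2)
  expect_equal(s2$mad_k, 0.1)     # raw MAD, no 1.4826 consistency factor
  s3 <- protein_rate_summary(data.frame(accession = "P3", k = 0.07))
  expect_equal(s3$median_k, 0.07)
  expect_equal(s3$mad_k, 0)
  expect_equal(s3$peptide_count, 1L)
  # quality gate removes low-R2 peptides but keeps NA (single-timepoint)
  f4 <- data.frame(accession = rep("P4", 3), k = c(0.1, 0.2, 9),
                   r_squared = c(0.99, NA, 0.1))
  expect_equal(protein_rate_summary(f4, r2_floor = 0.5)$median_k, 0.15)
})

test_that("condition comparison reports median ratio and rank-sum p", {
  a <- data.frame(peptide = c("x", "y", "z"), k = c(1, 2, 3), intensity = 1)
  b <- data.frame(peptide = c("x", "y", "z"), k = c(10, 20, 30),
                  intensity = 1)
  cmp <- compare_turnover(a, b)
  expect_equal(cmp$ratio, 10)
  expect_equal(cmp$p, 0.1)                       # exact rank-sum, 20 splits
  expect_equal(cmp$p, wilcox_oracle(a$k, b$k))
  same <- compare_turnover(a, a)
  expect_equal(same$ratio, 1)
  expect_equal(same$p, 1)
  # replicate averaging happens before ranking
  a2 <- data.frame(peptide = rep(c("x", "y"), each = 2),
                   k = c(1, 3, 2, 4), intensity = 1)
  cmp2 <- compare_turnover(a2, a2)
  expect_equal(cmp2$n_a, 2L)
  # < 2 peptides: ratio still reported, p missing
  one <- compare_turnover(data.frame(peptide = "x", k = 2, intensity = 1),
                          data.frame(peptide = "x", k = 4, intensity = 1))
  expect_equal(one$ratio, 2)
  expect_true(is.na(one$p))
})

test_that("rank-sum p-values match the enumeration oracle for small groups", {
  set.seed(7)
  for (i in 1:12) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- data.frame(peptide = paste0("a", 1:na), k = rnorm(na, 1, 0.3),
                    intensity = 1)
    b <- data.frame(peptide = paste0("b", 1:nb), k = rnorm(nb, 1.5, 0.3),
                    intensity = 1)
    expect_equal(compare_turnover(a, b)$p, wilcox_oracle(a$k, b$k),
                 tolerance = 1e-12)
  }
})

test_that("multiple-testing adjustment follows the BH ladder", {
  # four proteins engineered to give a known raw p-vector
  fits <- do.call(rbind, lapply(1:4, function(i) {
    rbind(data.frame(accession = paste0("P", i), condition = "A",
                     peptide = paste0("p", 1:3), k = c(1, 2, 3) * i,
                     intensity = 1),
          data.frame(accession = paste0("P", i), condition = "B",
                     peptide = paste0("p", 1:3), k = c(10, 20, 30) * i,
                     intensity = 1))
  }))
  tab <- compare_turnover_table(fits, "A", "B")
  expect_equal(tab$p_adj, p.adjust(tab$p, "BH"))
  # frozen BH ladder example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # top-10 intensity cap
  big <- data.frame(peptide = paste0("q", 1:15), k = 1:15,
                    intensity = 15:1)
  capped <- compare_turnover(big, big)
  expect_equal(capped$n_a, 10L)
})
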