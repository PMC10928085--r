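# TMT quantification: impurity matrix construction, reporter extraction,
# NNLS correction, isoform-aware rollup, design mapping, normalization.

test_that("impurity matrices encode column-spills-into-row orientation", {
  spills <- data.frame(channel = c("A", "B", "C"), minus2 = 0,
                       minus1 = c(3, 1, 2), plus1 = c(5, 4, 0), plus2 = 0)
  M <- impurity_matrix(spills, lot = "L1")
  expect_equal(dim(unclass(M)), c(3L, 3L))
  expect_equal(M["B", "A"], 0.05)     # A spills +1 into B
  expect_equal(M["A", "B"], 0.01)     # B spills -1 into A
  expect_equal(diag(unclass(M)), c(A = 0.92, B = 0.95, C = 0.98))
  expect_true(all(colSums(unclass(M)) <= 1 + 1e-12))
  expect_equal(attr(M, "lot"), "L1")
  expect_error(impurity_matrix(spills[c(1, 1, 2), ]), "duplicate")
  # A's -1 spill falls off the plex edge: lost mass, not wrapped
  expect_equal(sum(unclass(M)[, 1]), 0.97)
})

test_that("reporter extraction takes the max peak within tolerance", {
  mzs <- unname(TMT10_REPORTER_MZ)
  v <- extract_reporters(mzs, rep(1, 10))
  expect_equal(unname(v), rep(1, 10))
  expect_equal(unname(extract_reporters(c(400, 500), c(5, 5))), rep(0, 10))
  two <- extract_reporters(c(mzs[1] - 0.001, mzs[1] + 0.001), c(5, 9))
  expect_equal(unname(two[1]), 9)
  expect_error(extract_reporters(mzs, rep(1, 10),
                                 channel_mz = c(a = 126.1, b = 126.1)),
               "duplicate")
})

test_that("impurity correction inverts the spill exactly when feasible", {
  v <- c(10, 20, 30)
  expect_equal(unname(correct_impurities(v, diag(3))), v,
               ignore_attr = TRUE)
  M <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  x <- correct_impurities(as.numeric(M %*% c(100, 0)), M)
  expect_equal(unname(x), c(100, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(x), nnls_oracle(M, as.numeric(M %*% c(100, 0))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("constrained corrections stay non-negative and match brute force", {
  # observation forcing a negative unconstrained solution
  M <- matrix(c(0.9, 0.1, 0, 0.1, 0.8, 0.1, 0, 0.1, 0.9), 3, 3)
  b <- c(0, 100, 0)
  unconstrained <- solve(M, b)
  expect_true(any(unconstrained < 0))
  x <- correct_impurities(b, M)
  expect_true(all(x >= 0))
  expect_equal(unname(x), nnls_oracle(M, b), tolerance = 1e-6,
               ignore_attr = TRUE)
  # property: perfect recovery of random non-negative truth
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    Mi <- random_impurity(n)
    truth <- runif(n, 0, 1000) * rbinom(n, 1, 0.8)
    rec <- correct_impurities(as.numeric(Mi %*% truth), Mi)
    expect_equal(unname(rec), truth, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("matrix-form correction matches vector-form row by row", {
  set.seed(9)
  M <- random_impurity(4)
  obs <- matrix(runif(20, 0, 100), 5, 4)
  obs[1, ] <- as.numeric(M %*% c(50, 0, 0, 50))
  got <- correct_impurities(obs, M)
  for (i in 1:5)
    expect_equal(unname(got[i, ]), unname(correct_impurities(obs[i, ], M)),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

make_psm_rows <- function(accessions, species = "L", intens = 1,
                          sequence = NULL) {
  n <- length(accessions)
  if (is.null(sequence)) sequence <- paste0("PEPTIDE", seq_len(n), "K")
  data.frame(accessions = accessions, species = species,
             sequence = sequence, i1 = intens, i2 = intens)
}

test_that("rollup applies the conservative isoform inference rules", {
  psm <- rbind(
    make_psm_rows("P1;P2", sequence = "AAAK"),          # rule 1: discard
    make_psm_rows("P1;P1-2", sequence = "BBBK"),        # rule 3 -> P1
    make_psm_rows("P1", sequence = "CCCK"),
    make_psm_rows("P3;P3-2", sequence = "DDDK"),        # rule 2: discard
    make_psm_rows("P3-2", sequence = "EEEK"),           # isoform-unique
    make_psm_rows("P3", sequence = "FFFK")
  )
  r <- rollup_peptides(psm, c("i1", "i2"))
  expect_setequal(rownames(r$intensity), c("P1", "P3", "P3-2"))
  expect_equal(r$n_discarded_multi, 1L)
  expect_equal(unname(r$support["P1"]), 2L)   # BBBK (rule 3) + CCCK
  expect_equal(unname(r$support["P3"]), 1L)   # shared DDDK discarded
  expect_true(r$below_threshold[["P3"]])
})

test_that("rollup sums intensities per species and is order invariant", {
  psm <- rbind(
    make_psm_rows(rep("P1", 3), species = "H", intens = 0,
                  sequence = c("AK", "BK", "CK")),
    make_psm_rows("P1", species = "L", intens = 7, sequence = "DK"))
  psm$i1 <- c(10, 20, 30, 7)
  r <- rollup_peptides(psm, c("i1", "i2"))
  expect_equal(r$intensity["P1_H", "i1"], 60)
  expect_equal(r$intensity["P1", "i1"], 7)
  shuf <- psm[c(3, 1, 4, 2), ]
  expect_equal(rollup_peptides(shuf, c("i1", "i2"))$intensity, r$intensity)
})

test_that("design mapping reorders channels to fraction order", {
  m <- matrix(1:6, 2, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  iden <- data.frame(channel = c("c1", "c2", "c3"),
                     fraction = c("F1", "F2", "F3"))
  expect_equal(unname(apply_design(m, iden)), unname(m))
  rev_d <- data.frame(channel = c("c1", "c2", "c3"),
                      fraction = c("F3", "F2", "F1"))
  expect_equal(unname(apply_design(m, rev_d)), unname(m[, 3:1]))
  expect_error(apply_design(m, iden[1:2, ]), "missing channel")
  bad <- data.frame(channel = c("c1", "c2", "c3"),
                    fraction = c("F1", "F1", "F2"))
  expect_error(apply_design(m, bad), "bijectively")
})

test_that("profile normalization is column-then-row with simplex output", {
  m <- matrix(c(2, 2, 2, 2), 2, 2)
  expect_equal(unname(normalize_profiles(m)), matrix(0.5, 2, 2))
  one <- matrix(c(3, 1, 4, 2), 1, 4)
  expect_equal(sum(normalize_profiles(one)), 1)
  # invariance to per-column scaling (fraction loading cancels)
  set.seed(2)
  m2 <- matrix(runif(20, 1, 10), 4, 5)
  scaled <- sweep(m2, 2, c(10, 1, 0.5, 2, 7), "*")
  expect_equal(normalize_profiles(m2), normalize_profiles(scaled),
               tolerance = 1e-12)
  withz <- rbind(m2, 0)
  expect_message(nz <- normalize_profiles(withz), "dropped")
  expect_equal(nrow(nz), 4L)
  expect_error(normalize_profiles(matrix(-1, 1, 2)), "negative")
})

test_that("the purity gate filters rows below threshold", {
  psm <- data.frame(purity = c(0.95, 0.50), x = 1:2)
  expect_equal(nrow(spectral_purity_gate(psm, 0.9)), 1L)
  expect_equal(attr(spectral_purity_gate(psm, 0.9), "n_removed"), 1L)
  expect_equal(nrow(spectral_purity_gate(psm, 0)), 2L)
  expect_error(spectral_purity_gate(data.frame(x = 1), 0.5), "absent")
})
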