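# Dynamic SILAC turnover kinetics: MS1 isotopomer integration, fractional
# synthesis, first-order rate fitting, protein-level summaries and
# between-condition comparisons.

#' Applicable isotopomer offsets for a peptide
#'
#' Enumerates the mass-isotopomer labels that can arise for a peptide with
#' `n_K` lysines and `n_R` arginines under heavy lysine (+8.0142 Da) and
#' heavy arginine (+10.0083 Da) labeling. Up to two labeled residues are
#' tracked (m0, m8, m10, m16, m18, m20); peptides with more than two K/R
#' are truncated to the two-residue envelope.
#'
#' @param n_K,n_R Number of lysine / arginine residues in the peptide.
#' @return Character vector of applicable offset labels (always includes
#'   `"m0"`), a subset of `c("m0","m8","m10","m16","m18","m20")`.
#' @export
#' @examples
#' applicable_offsets(1, 0)  # "m0" "m8"
#' applicable_offsets(1, 1)  # "m0" "m8" "m10" "m18"
applicable_offsets <- function(n_K, n_R) {
  n_K <- min(as.integer(n_K), 2L)
  n_R <- min(as.integer(n_R), 2L)
  if (n_K < 0 || n_R < 0) stop("residue counts must be non-negative")
  labs <- "m0"
  if (n_K >= 1) labs <- c(labs, "m8")
  if (n_R >= 1) labs <- c(labs, "m10")
  if (n_K >= 2) labs <- c(labs, "m16")
  if (n_K >= 1 && n_R >= 1) labs <- c(labs, "m18")
  if (n_R >= 2) labs <- c(labs, "m20")
  labs
}

#' Integrate MS1 isotopomer areas for a peptide
#'
#' Sums, per MS1 scan, all peak intensities within a ppm tolerance of each
#' expected isotopomer m/z (precursor m/z + offset mass / charge), then
#' integrates the per-scan intensity over retention time by the trapezoid
#' rule. The retention-time window spans the first to last MS2
#' identification of the peptide, padded on both sides.
#'
#' @param spectra Spectrum stream: a list of scans, each a list with
#'   elements `rt` (seconds), `ms_level`, `mz`, `intensity` (see
#'   [read_spectra()]).
#' @param query List with `mz` (light precursor m/z), `charge`, `n_K`,
#'   `n_R`, `first_ms2_rt`, `last_ms2_rt` (seconds).
#' @param ppm_tol Mass tolerance in parts per million (default 25).
#' @param rt_pad_s Retention-time pad in seconds on each side (default 20).
#' @return Object of class `isotopomer_envelope`: list with `areas` (named
#'   numeric over applicable offsets), `n_K`, `n_R`, `total_intensity`,
#'   `rt_window_s`, and logical `empty_window`.
#' @export
integrate_isotopomers <- function(spectra, query, ppm_tol = 25, rt_pad_s = 20) {
  if (length(spectra) == 0L) stop("empty spectrum stream")
  stopifnot_scalar(ppm_tol, "ppm_tol", lower = 1e-12)
  labs <- applicable_offsets(query$n_K, query$n_R)
  exp_mz <- query$mz + ISO_OFFSET_MASS[labs] / query$charge
  lo <- query$first_ms2_rt - rt_pad_s
  hi <- query$last_ms2_rt + rt_pad_s

  ms1 <- Filter(function(s) (s$ms_level %||% 1L) == 1L, spectra)
  rts <- vapply(ms1, function(s) s$rt, numeric(1))
  keep <- which(rts >= lo & rts <= hi)
  empty <- length(keep) == 0L
  if (empty)
    warning("no MS1 scan in retention-time window; all areas set to 0")

  areas <- stats::setNames(numeric(length(labs)), labs)
  if (!empty) {
    keep <- keep[order(rts[keep])]
    rt_k <- rts[keep]
    # per-scan summed intensity within tolerance of each expected m/z
    ints <- vapply(ms1[keep], function(s) {
      vapply(exp_mz, function(m) {
        tol <- m * ppm_tol * 1e-6
        sum(s$intensity[abs(s$mz - m) <= tol])
      }, numeric(1))
    }, numeric(length(labs)))
    ints <- matrix(ints, nrow = length(labs))
    if (length(keep) == 1L) {
      areas[] <- ints[, 1L]       # degenerate trapezoid: unit 1 s width
    } else {
      dt <- diff(rt_k)
      for (i in seq_along(labs))
        areas[i] <- sum((ints[i, -1L] + ints[i, -length(rt_k)]) / 2 * dt)
    }
  }
  structure(list(
    areas = areas, n_K = query$n_K, n_R = query$n_R,
    total_intensity = sum(areas), rt_window_s = c(lo, hi),
    empty_window = empty
  ), class = "isotopomer_envelope")
}

#' Fractional synthesis from an isotopomer envelope
#'
#' Fraction of the peptide pool synthesized after labeling onset:
#' `fs = 1 - m0 / sum(applicable isotopomer areas)`. The applicable set is
#' determined by the peptide's K/R composition ([applicable_offsets()]);
#' mixed partial-label isotopomers count in the denominator as
#' heavy-containing evidence of post-labeling synthesis.
#'
#' @param envelope An `isotopomer_envelope`, or a named numeric vector of
#'   areas (names among `m0`..`m20`), in which case `n_K`/`n_R` are
#'   required.
#' @param n_K,n_R Residue counts (ignored when `envelope` is an
#'   `isotopomer_envelope`).
#' @return Fractional synthesis in `[0, 1]`, or `NA` when all applicable
#'   areas are zero.
#' @export
#' @examples
#' fractional_synthesis(c(m0 = 300, m8 = 100), n_K = 1, n_R = 0)  # 0.25
fractional_synthesis <- function(envelope, n_K = NULL, n_R = NULL) {
  if (inherits(envelope, "isotopomer_envelope")) {
    areas <- envelope$areas; n_K <- envelope$n_K; n_R <- envelope$n_R
  } else {
    areas <- envelope
    if (is.null(n_K) || is.null(n_R))
      stop("n_K and n_R required when passing a bare area vector")
  }
  if (any(areas < 0, na.rm = TRUE)) stop("negative isotopomer area")
  labs <- applicable_offsets(n_K, n_R)
  a <- stats::setNames(numeric(length(labs)), labs)
  shared <- intersect(names(areas), labs)
  a[shared] <- ifelse(is.na(areas[shared]), 0, areas[shared])
  denom <- sum(a)
  if (denom <= 0) return(NA_real_)
  1 - a[["m0"]] / denom
}

#' Fit a first-order turnover rate to fractional-synthesis observations
#'
#' Intensity-weighted least-squares fit of the exponential rise model
#' `fs(t) = 1 - exp(-k t)` with plateau fixed at 1, minimizing
#' `sum(w * (fs - (1 - exp(-k t)))^2)` over `k >= 0`. With a single
#' observation the fit reduces to the closed form `k = -log(1 - fs) / t`.
#' The standard error comes from the Gauss-Newton curvature at the
#' optimum; fs values outside `[0, 1]` are clipped with a warning.
#'
#' @param t_h Chase times in hours (all `> 0`).
#' @param fs Fractional-synthesis observations.
#' @param weights Non-negative weights, typically total envelope
#'   intensity. Default: equal weights.
#' @param k_max Upper bound on the rate (per hour) used when fs
#'   approaches 1 (default 10).
#' @return Object of class `turnover_fit` with elements `k`, `se_k`,
#'   `half_life_h`, `n_obs`, `r_squared`.
#' @seealso [half_life()], [protein_rate_summary()]
#' @export
#' @examples
#' fit <- fit_turnover_rate(c(4, 8, 16), 1 - exp(-0.1 * c(4, 8, 16)))
#' coef(fit)
fit_turnover_rate <- function(t_h, fs, weights = NULL, k_max = 10) {
  keep <- !is.na(fs) & !is.na(t_h)
  t_h <- t_h[keep]; fs <- fs[keep]
  if (length(fs) == 0L) stop("no non-missing fractional-synthesis observations")
  if (any(t_h <= 0)) stop("all chase times must be > 0")
  weights <- if (is.null(weights)) rep(1, length(fs)) else weights[keep]
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(fs < 0 | fs > 1)) {
    warning("fractional synthesis outside [0, 1] clipped")
  }
  fs <- pmin(pmax(fs, 0), 1 - 1e-9)

  n <- length(fs)
  # per-observation closed-form inversions bracket the weighted optimum:
  # the residual of each observation is monotone in k, so the weighted
  # least-squares solution lies within their range (the objective is
  # numerically flat for large k, so an unbracketed search can fail)
  k_obs <- pmin(-log(1 - fs) / t_h, k_max)
  if (n == 1L || diff(range(k_obs)) == 0) {
    k <- k_obs[1L]
  } else {
    sse <- function(k) sum(weights * (fs - (1 - exp(-k * t_h)))^2)
    opt <- stats::optimize(sse, interval = range(k_obs),
                           tol = min(1e-10, 1e-9 * max(k_obs)))
    k <- opt$minimum
  }
  res <- fs - (1 - exp(-k * t_h))
  J <- t_h * exp(-k * t_h)                      # d fs_hat / d k
  se <- if (n > 1L && sum(weights * J^2) > 0) {
    s2 <- sum(weights * res^2) / (n - 1L)
    sqrt(s2 / sum(weights * J^2))
  } else NA_real_
  wmean <- sum(weights * fs) / sum(weights)
  tss <- sum(weights * (fs - wmean)^2)
  r2 <- if (tss > 0) 1 - sum(weights * res^2) / tss else NA_real_
  structure(list(k = k, se_k = se, half_life_h = half_life(k),
                 n_obs = n, r_squared = r2,
                 data = data.frame(t_h = t_h, fs = fs, weight = weights)),
            class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat("First-order turnover fit (plateau = 1)\n")
  cat(sprintf("  k         = %.6g /h%s\n", x$k,
              if (is.na(x$se_k)) "" else sprintf(" (se %.3g)", x$se_k)))
  cat(sprintf("  half-life = %.4g h\n", x$half_life_h))
  cat(sprintf("  n = %d, R^2 = %s\n", x$n_obs,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

#' @export
coef.turnover_fit <- function(object, ...) c(k = object$k)

#' @export
predict.turnover_fit <- function(object, t_h, ...) {
  if (missing(t_h)) t_h <- object$data$t_h
  1 - exp(-object$k * t_h)
}

#' Half-life from a first-order rate constant
#'
#' @param k Rate constant (per hour), `>= 0`.
#' @return `log(2) / k` in hours; `Inf` when `k` is 0.
#' @export
#' @examples
#' half_life(log(2))  # 1
half_life <- function(k) {
  if (any(k < 0)) stop("rate constant must be non-negative")
  ifelse(k == 0, Inf, log(2) / k)
}

#' Protein-level turnover summary
#'
#' Summarizes peptide-level rate fits per protein as the median of peptide
#' rates +/- the raw median absolute deviation (no consistency factor).
#' Peptides failing an optional R-squared floor are excluded; fits whose
#' R-squared is undefined (single-timepoint designs) always pass.
#'
#' @param fits Data frame with columns `accession`, `k`, and optionally
#'   `r_squared`.
#' @param r2_floor Minimum fit R-squared (default 0: keep all).
#' @return Data frame with `accession`, `median_k`, `mad_k`,
#'   `half_life_h`, `peptide_count`.
#' @export
protein_rate_summary <- function(fits, r2_floor = 0) {
  stopifnot(all(c("accession", "k") %in% names(fits)))
  if ("r_squared" %in% names(fits) && r2_floor > 0) {
    fits <- fits[is.na(fits$r_squared) | fits$r_squared >= r2_floor, ,
                 drop = FALSE]
  }
  if (nrow(fits) == 0L) stop("no peptide fits pass the quality gate")
  sp <- split(fits$k, fits$accession)
  data.frame(
    accession = names(sp),
    median_k = vapply(sp, stats::median, numeric(1)),
    mad_k = vapply(sp, function(x) stats::mad(x, constant = 1), numeric(1)),
    half_life_h = half_life(vapply(sp, stats::median, numeric(1))),
    peptide_count = lengths(sp),
    row.names = NULL
  )
}

#' Compare turnover rates of one protein between two conditions
#'
#' Per-peptide rates are first averaged over replicate experiments, then
#' restricted to the top `max_peptides` most intense peptides per
#' condition. The reported ratio is the median of per-peptide B/A ratios
#' over peptides observed in both conditions, with dispersion MAD/median;
#' the p-value is a two-sided Wilcoxon rank-sum test on the two
#' peptide-rate samples. Benjamini-Hochberg adjustment across proteins is
#' applied by [compare_turnover_table()].
#'
#' @param pep_a,pep_b Data frames for conditions A and B with columns
#'   `peptide`, `k`, `intensity` (one row per peptide x replicate).
#' @param max_peptides Peptide cap per condition (default 10).
#' @return List with `ratio` (median B/A), `dispersion` (MAD/median),
#'   `p` (raw Wilcoxon p; `NA` when either condition has < 2 peptides),
#'   `n_a`, `n_b`.
#' @export
compare_turnover <- function(pep_a, pep_b, max_peptides = 10) {
  summarise <- function(d) {
    if (nrow(d) == 0L) stop("each condition needs at least one peptide rate")
    k <- tapply(d$k, d$peptide, mean)
    inten <- tapply(d$intensity, d$peptide, mean)
    ord <- order(inten, decreasing = TRUE)
    top <- utils::head(ord, max_peptides)
    data.frame(peptide = names(k)[top], k = as.numeric(k[top]))
  }
  a <- summarise(pep_a); b <- summarise(pep_b)
  shared <- intersect(a$peptide, b$peptide)
  ratio <- dispersion <- NA_real_
  if (length(shared) > 0L) {
    r <- b$k[match(shared, b$peptide)] / a$k[match(shared, a$peptide)]
    r <- r[is.finite(r)]
    if (length(r) > 0L) {
      ratio <- stats::median(r)
      dispersion <- stats::mad(r, constant = 1) / ratio
    }
  }
  p <- if (nrow(a) >= 2L && nrow(b) >= 2L) {
    suppressWarnings(stats::wilcox.test(a$k, b$k, exact = NULL)$p.value)
  } else NA_real_
  list(ratio = ratio, dispersion = dispersion, p = p,
       n_a = nrow(a), n_b = nrow(b))
}

#' Compare turnover across all proteins with multiple-testing correction
#'
#' Runs [compare_turnover()] per protein and applies Benjamini-Hochberg
#' adjustment over the comparison set.
#'
#' @param fits Data frame of peptide fits with columns `accession`,
#'   `condition`, `peptide`, `k`, `intensity`.
#' @param cond_a,cond_b Condition labels to compare (B over A).
#' @param max_peptides Peptide cap per condition per protein.
#' @return Data frame with `accession`, `ratio`, `dispersion`, `p`,
#'   `p_adj`, `n_a`, `n_b`.
#' @export
compare_turnover_table <- function(fits, cond_a, cond_b, max_peptides = 10) {
  accs <- intersect(unique(fits$accession[fits$condition == cond_a]),
                    unique(fits$accession[fits$condition == cond_b]))
  rows <- lapply(accs, function(acc) {
    a <- fits[fits$accession == acc & fits$condition == cond_a, ]
    b <- fits[fits$accession == acc & fits$condition == cond_b, ]
    cmp <- compare_turnover(a, b, max_peptides)
    data.frame(accession = acc, ratio = cmp$ratio,
               dispersion = cmp$dispersion, p = cmp$p,
               n_a = cmp$n_a, n_b = cmp$n_b)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(accession = character(), ratio = numeric(),
                      dispersion = numeric(), p = numeric(),
                      p_adj = numeric(), n_a = integer(), n_b = integer()))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("accession", "ratio", "dispersion", "p", "p_adj", "n_a", "n_b")]
}
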