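# Localization dynamics between conditions: heavy-light spatial
# distances with a light-light null, drift-normalized distance changes,
# and bootstrap differential-localization probabilities.

#' Replicate-scaled Euclidean distance between fraction profiles
#'
#' Euclidean norm of the difference between two concatenated
#' multi-replicate profiles, divided by the number of replicates.
#'
#' @param a,b Numeric profile vectors of equal length (replicate-wise
#'   row-normalized, concatenated over replicates).
#' @param n_replicates Number of replicate segments in the vectors.
#' @return Non-negative distance.
#' @export
#' @examples
#' pair_distance(c(1, 0), c(0, 1), 1)  # sqrt(2)
pair_distance <- function(a, b, n_replicates = 1) {
  if (length(a) != length(b)) stop("profile dimension mismatch")
  stopifnot_scalar(n_replicates, "n_replicates", lower = 1)
  sqrt(sum((a - b)^2)) / n_replicates
}

#' Null distribution of distances between random light-protein pairs
#'
#' Samples distances between distinct, randomly paired light proteins to
#' calibrate the scale of heavy-light distances.
#'
#' @param light Matrix of light-protein profiles (proteins x features).
#' @param n_pairs Number of pairs to sample.
#' @param n_replicates Replicate count (distance scaling).
#' @param seed Integer seed.
#' @return Numeric vector of `n_pairs` distances. When `n_pairs` exceeds
#'   the number of distinct pairs, sampling is with replacement and the
#'   attribute `"with_replacement"` is `TRUE`.
#' @export
null_distance_sample <- function(light, n_pairs, n_replicates = 1, seed = 1) {
  n <- nrow(light)
  if (n < 2L) stop("need at least 2 light proteins")
  max_pairs <- n * (n - 1) / 2
  replace <- n_pairs > max_pairs
  with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)   # distinct partner
    if (!replace) {
      # reject duplicate unordered pairs by resampling
      key <- paste(pmin(i, j), pmax(i, j))
      while (anyDuplicated(key)) {
        dup <- which(duplicated(key))
        i[dup] <- sample.int(n, length(dup), replace = TRUE)
        j[dup] <- sample.int(n - 1L, length(dup), replace = TRUE)
        j[dup] <- ifelse(j[dup] >= i[dup], j[dup] + 1L, j[dup])
        key <- paste(pmin(i, j), pmax(i, j))
      }
    }
    d <- sqrt(rowSums((light[i, , drop = FALSE] -
                         light[j, , drop = FALSE])^2)) / n_replicates
    structure(d, with_replacement = replace)
  })
}

#' Drift-normalized change in heavy-light spatial distance
#'
#' For each protein with light and heavy profiles in both conditions,
#' computes the change in heavy-light distance `delta = d_B - d_A`,
#' subtracts the reference drift (the mean change, between the same two
#' conditions, of the distance between the protein's light profile and
#' `n_ref` sampled light partner proteins), and standardizes the
#' normalized changes into Z scores across all proteins.
#'
#' @param light_a,heavy_a,light_b,heavy_b Profile matrices for conditions
#'   A and B (rownames = accessions; heavy rownames may carry the `_H`
#'   suffix, which is stripped for pairing).
#' @param n_replicates Replicate count (distance scaling).
#' @param n_ref Number of light reference partners (default 250); when
#'   fewer light proteins are shared between conditions, all available
#'   are used and the result is flagged.
#' @param seed Integer seed for partner sampling.
#' @return Data frame with `accession`, `d_a`, `d_b`, `delta`, `drift`,
#'   `delta_norm`, `z`; attribute `"n_ref_used"` records the partner
#'   count.
#' @export
normalized_pair_change <- function(light_a, heavy_a, light_b, heavy_b,
                                   n_replicates = 1, n_ref = 250, seed = 1) {
  strip <- function(x) sub("_H$", "", x)
  rownames(heavy_a) <- strip(rownames(heavy_a))
  rownames(heavy_b) <- strip(rownames(heavy_b))
  accs <- Reduce(intersect, list(rownames(light_a), rownames(heavy_a),
                                 rownames(light_b), rownames(heavy_b)))
  if (length(accs) == 0L) stop("no protein has both species in both conditions")
  light_shared <- intersect(rownames(light_a), rownames(light_b))
  n_use <- min(n_ref, length(light_shared) - 1L)
  flagged <- n_use < n_ref

  d_a <- vapply(accs, function(a)
    pair_distance(light_a[a, ], heavy_a[a, ], n_replicates), numeric(1))
  d_b <- vapply(accs, function(a)
    pair_distance(light_b[a, ], heavy_b[a, ], n_replicates), numeric(1))
  delta <- d_b - d_a

  drift <- with_seed(seed, vapply(accs, function(a) {
    pool <- setdiff(light_shared, a)
    partners <- sample(pool, n_use, replace = FALSE)
    dA <- sqrt(rowSums(sweep(light_a[partners, , drop = FALSE], 2L,
                             light_a[a, ])^2)) / n_replicates
    dB <- sqrt(rowSums(sweep(light_b[partners, , drop = FALSE], 2L,
                             light_b[a, ])^2)) / n_replicates
    mean(dB - dA)
  }, numeric(1)))

  delta_norm <- delta - drift
  s <- stats::sd(delta_norm)
  z <- if (is.na(s) || s == 0) rep(0, length(delta_norm))
       else (delta_norm - mean(delta_norm)) / s
  structure(data.frame(accession = accs, d_a = d_a, d_b = d_b,
                       delta = delta, drift = drift,
                       delta_norm = delta_norm, z = z, row.names = NULL),
            n_ref_used = n_use, n_ref_flagged = flagged)
}

# Re-derive a protein profile from peptide-level fraction intensities:
# sum selected peptide rows per replicate, row-normalize each replicate
# segment, concatenate. `mats` is a list over replicates of
# peptide x fraction matrices with aligned rows.
profile_from_peptides <- function(mats, idx = NULL) {
  segs <- lapply(mats, function(m) {
    v <- colSums(m[idx %||% seq_len(nrow(m)), , drop = FALSE])
    s <- sum(v)
    if (s > 0) v / s else rep(NA_real_, length(v))
  })
  unlist(segs, use.names = FALSE)
}

#' Bootstrap differential-localization probability for one protein species
#'
#' Resamples peptides with replacement within each condition, re-derives
#' and re-normalizes the protein profile from the resampled peptides,
#' allocates it under each condition's compartment model, and reports the
#' fraction of resamples in which the top compartments differ between
#' conditions. The peptide is the resampling unit because typical
#' replicate counts (2-3) are too small to bootstrap.
#'
#' @param peptides_a,peptides_b Lists over replicates of peptide x
#'   fraction intensity matrices (rows aligned to the same peptide set
#'   within a condition; impurity-corrected, design-mapped, and scaled by
#'   the experiment's column-normalization factors).
#' @param model_a,model_b [fit_compartment_model()] objects for the two
#'   conditions.
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @return List with `dl_prob`, `source` and `destination` (modal top
#'   compartments in A and B), and `n_boot`.
#' @export
bootstrap_dl_probability <- function(peptides_a, peptides_b,
                                     model_a, model_b,
                                     n_boot = 200, seed = 1) {
  n_pep_a <- nrow(peptides_a[[1]])
  n_pep_b <- nrow(peptides_b[[1]])
  if (n_pep_a < 2L || n_pep_b < 2L)
    stop("bootstrap requires at least 2 peptides per condition")
  with_seed(seed, {
    boot_profiles <- function(mats, n_pep) {
      t(vapply(seq_len(n_boot), function(b) {
        profile_from_peptides(mats, sample.int(n_pep, n_pep, replace = TRUE))
      }, numeric(length(mats) * ncol(mats[[1]]))))
    }
    pa <- boot_profiles(peptides_a, n_pep_a)
    pb <- boot_profiles(peptides_b, n_pep_b)
    ok <- stats::complete.cases(pa) & stats::complete.cases(pb)
    top_a <- allocate(model_a, pa[ok, , drop = FALSE])$compartment
    top_b <- allocate(model_b, pb[ok, , drop = FALSE])$compartment
    modal <- function(x) names(which.max(table(x)))
    list(dl_prob = mean(top_a != top_b),
         source = modal(top_a), destination = modal(top_b),
         n_boot = sum(ok))
  })
}

#' Filter differential-localization records to light-heavy pairs
#'
#' Restricts DL calls to proteins for which both the light feature
#' (`accession`) and the heavy feature (`accession_H`) pass the DL
#' probability threshold.
#'
#' @param records Data frame with columns `id` (species-suffixed
#'   accession) and `dl_prob`.
#' @param threshold DL probability threshold (default 0.95).
#' @return Character vector of base accessions passing as pairs.
#' @export
paired_dl_filter <- function(records, threshold = 0.95) {
  if (nrow(records) == 0L) return(character())
  heavy <- grepl("_H$", records$id)
  base <- sub("_H$", "", records$id)
  pass <- records$dl_prob > threshold
  light_pass <- unique(base[pass & !heavy])
  heavy_pass <- unique(base[pass & heavy])
  sort(intersect(light_pass, heavy_pass))
}
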