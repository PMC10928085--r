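# TMT reporter quantification: reporter extraction, isotope-impurity
# correction by NNLS, isoform-aware protein rollup split by SILAC
# species, design mapping and profile normalization.

#' Build a TMT isotope-impurity matrix from a vendor spill sheet
#'
#' Vendor lot sheets list, per reagent, the percentage of its signal
#' observed two channels below (`minus2`), one below (`minus1`), one above
#' (`plus1`) and two above (`plus2`) its own position. This constructs the
#' square matrix `M` with the fixed orientation M[i, j] = fraction of
#' channel j's true signal observed in channel i, so observed = M %*% true.
#' Spill that falls outside the plex is lost; the diagonal is
#' 1 - (sum of all four stated percentages)/100.
#'
#' @param spills Data frame with columns `channel`, `minus2`, `minus1`,
#'   `plus1`, `plus2` (percentages), in channel order.
#' @param lot Lot identifier string.
#' @return Object of class `impurity_matrix`: the matrix with attributes
#'   `channels` and `lot`.
#' @export
impurity_matrix <- function(spills, lot = "unspecified") {
  need <- c("channel", "minus2", "minus1", "plus1", "plus2")
  if (!all(need %in% names(spills)))
    stop("spill sheet must have columns: ", paste(need, collapse = ", "))
  n <- nrow(spills)
  if (anyDuplicated(spills$channel)) stop("duplicate channel in spill sheet")
  M <- matrix(0, n, n, dimnames = list(spills$channel, spills$channel))
  off <- c(minus2 = -2L, minus1 = -1L, plus1 = 1L, plus2 = 2L)
  for (j in seq_len(n)) {
    spilled <- 0
    for (nm in names(off)) {
      pct <- spills[[nm]][j]
      if (is.na(pct)) pct <- 0
      spilled <- spilled + pct
      i <- j + off[[nm]]
      if (i >= 1L && i <= n) M[i, j] <- pct / 100
    }
    M[j, j] <- 1 - spilled / 100
  }
  if (any(M < 0)) stop("spill percentages exceed 100% for some channel")
  if (any(diag(M) <= apply(M - diag(diag(M)), 2, max)))
    warning("impurity matrix is not diagonally dominant")
  structure(M, channels = spills$channel, lot = lot,
            class = c("impurity_matrix", "matrix"))
}

#' Read an impurity spill sheet CSV
#'
#' @param path CSV with columns `channel`, `minus2`, `minus1`, `plus1`,
#'   `plus2` (percentages) and optionally `lot`.
#' @return An [impurity_matrix()].
#' @export
read_impurity_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(channel = "character"))
  lot <- if ("lot" %in% names(d)) as.character(d$lot[1]) else "unspecified"
  impurity_matrix(d, lot = lot)
}

#' Extract TMT reporter intensities from an MS2 peak list
#'
#' For each reporter channel, takes the most intense peak within an
#' absolute m/z tolerance of the reporter mass; channels with no matching
#' peak get 0.
#'
#' @param mz,intensity MS2 peak list vectors.
#' @param channel_mz Named numeric of reporter m/z values (default the
#'   10-plex table).
#' @param tol Absolute m/z tolerance (default 0.003 for high-resolution
#'   MS2).
#' @return Named numeric vector of per-channel intensities.
#' @export
extract_reporters <- function(mz, intensity, channel_mz = TMT10_REPORTER_MZ,
                              tol = 0.003) {
  stopifnot_scalar(tol, "tol", lower = 1e-12)
  if (anyDuplicated(round(channel_mz, 6)))
    stop("duplicate reporter m/z entries in channel table")
  vapply(channel_mz, function(m) {
    hit <- abs(mz - m) <= tol
    if (any(hit)) max(intensity[hit]) else 0
  }, numeric(1))
}

#' Correct TMT reporter intensities for isotope impurities
#'
#' Solves the non-negative least-squares problem
#' `argmin_{x >= 0} || M x - observed ||^2` for the true channel
#' intensities, where `M` is the impurity matrix (observed = M %*% true).
#' When the unconstrained solve is already non-negative it is returned
#' exactly. Matrices are corrected row-wise with a vectorized fast path.
#'
#' @param observed Numeric vector of observed channel intensities, or a
#'   matrix with one spectrum per row.
#' @param M Impurity matrix ([impurity_matrix()] or plain square matrix).
#' @return Corrected intensities (same shape as `observed`), all `>= 0`.
#'   A `residual` attribute carries the NNLS residual norm(s).
#' @export
correct_impurities <- function(observed, M) {
  M <- unclass(M)
  n <- ncol(M)
  if (nrow(M) != n) stop("impurity matrix must be square")
  if (is.matrix(observed)) {
    if (ncol(observed) != n)
      stop("observed has ", ncol(observed), " channels but matrix expects ", n)
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    out <- if (is.null(Minv)) matrix(-1, nrow(observed), n)
           else observed %*% t(Minv)
    bad <- which(apply(out, 1L, function(r) any(r < 0)))
    for (i in bad) out[i, ] <- pracma::lsqnonneg(M, observed[i, ])$x
    dimnames(out) <- dimnames(observed)
    resid <- sqrt(rowSums((observed - out %*% t(M))^2))
    return(structure(out, residual = resid))
  }
  if (length(observed) != n)
    stop("observed has ", length(observed), " channels but matrix expects ", n)
  x <- tryCatch(solve(M, observed), error = function(e) NULL)
  if (is.null(x) || any(x < 0)) x <- pracma::lsqnonneg(M, observed)$x
  names(x) <- colnames(M)
  structure(x, residual = sqrt(sum((M %*% x - observed)^2)))
}

# Strip an isoform suffix: "P12345-2" -> "P12345"
top_level_accession <- function(acc) sub("-.*$", "", acc)

# Row-level accession resolution under the conservative inference rules
# documented in rollup_peptides(). Returns NA for discarded rows.
resolve_psm_accessions <- function(accessions) {
  acc_list <- strsplit(as.character(accessions), ";", fixed = TRUE)
  acc_list <- lapply(acc_list, function(a) unique(trimws(a[nzchar(trimws(a))])))
  empty <- lengths(acc_list) == 0L
  top <- lapply(acc_list, top_level_accession)
  multi <- vapply(top, function(t) length(unique(t)) > 1L, logical(1))
  keep <- !empty & !multi
  unique_acc <- unique(unlist(acc_list[keep & lengths(acc_list) == 1L]))
  resolved <- rep(NA_character_, length(acc_list))
  for (i in which(keep)) {
    accs <- acc_list[[i]]
    if (length(accs) == 1L) { resolved[i] <- accs; next }
    canonical <- accs[!grepl("-", accs, fixed = TRUE)]
    isoforms <- setdiff(accs, canonical)
    if (any(isoforms %in% unique_acc)) next  # rule 2: shared row discarded
    if (length(canonical) == 1L) resolved[i] <- canonical  # rule 3
  }
  structure(resolved, n_multi = sum(multi & !empty), n_empty = sum(empty))
}

#' Isoform-aware peptide-to-protein rollup split by SILAC species
#'
#' Sums peptide channel intensities into protein species
#' (`accession` for light, `accession_H` for heavy) under conservative
#' inference rules that protect spatial profiles from razor peptides:
#' \enumerate{
#'   \item PSMs mapping to two or more distinct top-level accessions are
#'     discarded.
#'   \item Within one top-level accession, if any non-canonical isoform
#'     has at least one isoform-unique peptide, peptides shared between
#'     isoforms of that accession are discarded (isoform- and
#'     canonical-unique peptides are kept for their own entries).
#'   \item Peptides shared between the canonical and an isoform with no
#'     unique peptide anywhere are assigned to the canonical.
#'   \item Intensities are summed per (resolved accession, species);
#'     heavy species get an `"_H"` accession suffix.
#'   \item Species with fewer than `min_peptides` distinct peptide
#'     sequences are flagged below threshold.
#' }
#'
#' @param psm Data frame with columns `accessions` (";"-separated),
#'   `sequence`, `species` (`"L"`/`"H"`), and the channel intensity
#'   columns.
#' @param channel_cols Names of the channel intensity columns.
#' @param min_peptides Peptide-support floor per species (default 2).
#' @return List with `intensity` (matrix protein-species x channel),
#'   `support` (named peptide counts), `below_threshold` (logical),
#'   `n_discarded_multi` (rule-1 rows), `n_rejected` (empty accession
#'   rows).
#' @export
rollup_peptides <- function(psm, channel_cols, min_peptides = 2) {
  resolved <- resolve_psm_accessions(psm$accessions)
  n_rejected <- attr(resolved, "n_empty")
  if (n_rejected > 0L) message(n_rejected, " PSM row(s) with empty accession rejected")
  kept <- !is.na(resolved)
  species_id <- ifelse(psm$species[kept] == "H",
                       paste0(resolved[kept], "_H"), resolved[kept])
  X <- as.matrix(psm[kept, channel_cols, drop = FALSE])
  intensity <- rowsum(X, group = species_id, reorder = TRUE)
  support <- vapply(split(psm$sequence[kept], species_id),
                    function(s) length(unique(s)), integer(1))
  support <- support[rownames(intensity)]
  list(intensity = intensity, support = support,
       below_threshold = support < min_peptides,
       n_discarded_multi = attr(resolved, "n_multi"),
       n_rejected = n_rejected)
}

#' Map TMT channels to ultracentrifugation fractions
#'
#' Reorders the columns of a protein x channel matrix into fraction order
#' (F1..Fn) according to the per-experiment randomized design.
#'
#' @param mat Matrix with channel columns.
#' @param design Data frame with columns `channel`, `fraction` giving a
#'   bijective channel-to-fraction assignment for one experiment.
#' @return Matrix with columns renamed and ordered F1..Fn.
#' @export
apply_design <- function(mat, design) {
  if (anyDuplicated(design$channel) || anyDuplicated(design$fraction))
    stop("design must map channels to fractions bijectively")
  missing_ch <- setdiff(colnames(mat), as.character(design$channel))
  if (length(missing_ch) > 0L)
    stop("design missing channel(s): ", paste(missing_ch, collapse = ", "))
  fr <- as.character(design$fraction)
  ord <- order(as.integer(sub("^F", "", fr)))
  out <- mat[, as.character(design$channel)[ord], drop = FALSE]
  colnames(out) <- fr[ord]
  out
}

#' Column- and row-normalize fraction profiles
#'
#' Divides each fraction column by its sum (removing per-fraction loading
#' differences), then each protein row by its sum, yielding simplex
#' sedimentation profiles. All-zero rows are dropped with a message.
#'
#' @param mat Non-negative protein x fraction matrix for one replicate.
#' @return Matrix of row-simplex profiles (possibly fewer rows).
#' @export
normalize_profiles <- function(mat) {
  if (any(mat < 0, na.rm = TRUE)) stop("negative intensities in profile matrix")
  zero_row <- rowSums(mat, na.rm = TRUE) == 0
  if (any(zero_row)) {
    message(sum(zero_row), " all-zero row(s) dropped during normalization")
    mat <- mat[!zero_row, , drop = FALSE]
  }
  cs <- colSums(mat, na.rm = TRUE)
  cs[cs == 0] <- 1
  m <- sweep(mat, 2L, cs, "/")
  sweep(m, 1L, rowSums(m), "/")
}

#' Filter PSMs on precursor-ion purity
#'
#' Removes PSM rows whose precursor isolation purity falls below a
#' threshold. Purity values are computed upstream; this gate only filters
#' on the provided column.
#'
#' @param psm PSM data frame.
#' @param min_purity Threshold in `[0, 1]`; 0 disables filtering.
#' @param column Purity column name (default `"purity"`).
#' @return Filtered data frame; attribute `n_removed` records the count.
#' @export
spectral_purity_gate <- function(psm, min_purity = 0.5, column = "purity") {
  if (min_purity <= 0) return(structure(psm, n_removed = 0L))
  if (!column %in% names(psm))
    stop("purity gate enabled but column '", column, "' is absent")
  keep <- !is.na(psm[[column]]) & psm[[column]] >= min_purity
  structure(psm[keep, , drop = FALSE], n_removed = sum(!keep))
}
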