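# Readers and writers for the table dialects consumed and emitted by the
# pipeline, plus an optional mzML spectrum-stream adapter.

PSM_REQUIRED_COLS <- c("sequence", "modifications", "accessions",
                       "charge", "rt_s", "q_value")

# Does a modification string carry a dynamic SILAC heavy K/R mass?
is_heavy_modification <- function(modifications) {
  grepl("8\\.0142|10\\.0083", as.character(modifications))
}

#' Read and validate a PSM evidence table
#'
#' Reads a tab-separated identification table (Percolator-style rows plus
#' quantification columns), checks the required schema, drops rows above
#' the identification q-value threshold, and infers the SILAC species of
#' each row from its modification masses (+8.0142 on K / +10.0083 on R
#' mark the heavy species). Missing `n_K`/`n_R` columns are derived from
#' the peptide sequence.
#'
#' @param path Tab-separated file with at least the columns `sequence`,
#'   `modifications`, `accessions` (";"-separated), `charge`, `rt_s`,
#'   `q_value`, plus `intensity_<channel>` reporter columns and/or
#'   `area_m*` isotopomer columns.
#' @param q_max Identification FDR threshold (default 0.01).
#' @return Validated data frame with a `species` column (`"L"`/`"H"`);
#'   attribute `n_q_filtered` records the rows removed by the q-value
#'   gate.
#' @export
read_psm_table <- function(path, q_max = 0.01) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(PSM_REQUIRED_COLS, names(d))
  if (length(missing_cols) > 0L)
    stop("PSM table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  n0 <- nrow(d)
  d <- d[!is.na(d$q_value) & d$q_value <= q_max, , drop = FALSE]
  d$modifications[is.na(d$modifications)] <- ""
  d$species <- ifelse(is_heavy_modification(d$modifications), "H", "L")
  if (!"n_K" %in% names(d))
    d$n_K <- vapply(strsplit(d$sequence, ""), function(s) sum(s == "K"),
                    integer(1))
  if (!"n_R" %in% names(d))
    d$n_R <- vapply(strsplit(d$sequence, ""), function(s) sum(s == "R"),
                    integer(1))
  structure(d, n_q_filtered = n0 - nrow(d))
}

#' Read a channel-to-fraction design table
#'
#' @param path CSV with columns `condition`, `replicate`, `channel`,
#'   `fraction` describing the randomized label assignment of each
#'   experiment.
#' @return Data frame; errors if any experiment's assignment is not
#'   bijective.
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(channel = "character"))
  need <- c("condition", "replicate", "channel", "fraction")
  if (!all(need %in% names(d)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  for (key in split(d, paste(d$condition, d$replicate))) {
    if (anyDuplicated(key$channel) || anyDuplicated(key$fraction))
      stop("non-bijective channel-fraction design in experiment ",
           key$condition[1], " replicate ", key$replicate[1])
  }
  d
}

#' Read an organelle marker list
#'
#' @param path CSV with columns `accession`, `compartment`.
#' @return Data frame with unique accessions.
#' @export
read_markers <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "compartment") %in% names(d)))
    stop("marker table must have columns accession, compartment")
  if (anyDuplicated(d$accession)) stop("duplicate marker accessions")
  d
}

#' Read an mzML file as a spectrum stream
#'
#' Adapter over Bioconductor's mzR returning the in-memory scan list
#' consumed by [integrate_isotopomers()]: one element per scan with
#' `rt` (seconds), `ms_level`, `mz`, `intensity`, ordered by retention
#' time. Each call re-opens the file (stateless contract).
#'
#' @param path mzML file with MS1 (and optionally MS2) scans.
#' @return List of scans in retention-time order.
#' @export
read_spectra <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  if (!file.exists(path)) stop("mzML file not found: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) stop("no scans in mzML file: ", path)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(seq_len(nrow(hdr)), function(i) {
    list(rt = hdr$retentionTime[i], ms_level = hdr$msLevel[i],
         mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
  })
  scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
}

# Shared TSV writer for pipeline outputs
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
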