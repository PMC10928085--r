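# Pipeline orchestration: purity gate -> impurity correction -> rollup
# -> design mapping -> normalization -> kinetics -> classification ->
# differential localization and pair-distance statistics.

#' Pipeline parameters
#'
#' Tunable parameters of [analyse_dataset()] / [run_pipeline()] with the
#' defaults used throughout: 1% identification FDR, purity floor 0.5,
#' two-peptide support per protein species per experiment, allocation and
#' differential-localization probability thresholds of 0.95, 200
#' bootstrap resamples, 250 light reference partners for drift
#' normalization.
#'
#' @param q_max Identification q-value ceiling (default 0.01).
#' @param min_purity Precursor purity floor (default 0.5; 0 disables).
#' @param min_peptides Peptide support floor per protein species per
#'   experiment (default 2).
#' @param allocation_threshold,dl_threshold Posterior probability
#'   thresholds (default 0.95 each).
#' @param n_boot Bootstrap resamples per differential-localization call
#'   (default 200).
#' @param n_ref Light reference partners for drift normalization
#'   (default 250).
#' @param marker_floor,prune_budget,prune_stall Marker-pruning controls
#'   (defaults 6, 500, 100).
#' @param lambda,outlier_scale,epsilon,outlier_df Compartment-model
#'   hyperparameters (see [fit_compartment_model()]).
#' @param r2_floor Peptide fit-quality gate for protein rate summaries
#'   (default 0).
#' @param max_peptides Peptide cap for between-condition rate comparisons
#'   (default 10).
#' @param stages Stages to run, a subset of
#'   `c("kinetics", "classify", "dl", "pairdist")`.
#' @param seed Integer seed for all stochastic steps (pruning, bootstrap,
#'   null sampling).
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(q_max = 0.01, min_purity = 0.5,
                            min_peptides = 2,
                            allocation_threshold = 0.95,
                            dl_threshold = 0.95, n_boot = 200,
                            n_ref = 250, marker_floor = 6,
                            prune_budget = 500, prune_stall = 100,
                            lambda = 0.01, outlier_scale = 4,
                            epsilon = 1e-6, outlier_df = 4,
                            r2_floor = 0, max_peptides = 10,
                            stages = c("kinetics", "classify", "dl",
                                       "pairdist"),
                            seed = 1) {
  p <- as.list(environment())
  bad <- setdiff(stages, c("kinetics", "classify", "dl", "pairdist"))
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (allocation_threshold <= 0 || allocation_threshold > 1 ||
      dl_threshold <= 0 || dl_threshold > 1)
    stop("probability thresholds must lie in (0, 1]")
  structure(p, class = "pipeline_params")
}

# Quantify one experiment (condition x replicate): peptide- and
# protein-level fraction matrices after rollup, design mapping and
# normalization.
quantify_experiment <- function(rows, feature, design_exp, channel_cols,
                                min_peptides) {
  pep_id <- paste(feature, rows$sequence, sep = "\r")
  pep_ch <- rowsum(as.matrix(rows[, channel_cols, drop = FALSE]), pep_id)
  colnames(pep_ch) <- sub("^intensity_", "", colnames(pep_ch))
  pep_fr <- apply_design(pep_ch, design_exp)
  split_id <- strsplit(rownames(pep_fr), "\r", fixed = TRUE)
  pep_feature <- vapply(split_id, `[`, character(1), 1L)
  pep_seq <- vapply(split_id, `[`, character(1), 2L)

  prot <- rowsum(pep_fr, pep_feature)
  support <- vapply(split(pep_seq, pep_feature),
                    function(s) length(unique(s)), integer(1))[rownames(prot)]
  prot <- prot[support >= min_peptides, , drop = FALSE]
  profiles <- normalize_profiles(prot)
  col_factors <- colSums(prot)
  # peptide matrices on the column-normalized scale for bootstrapping
  pep_scaled <- sweep(pep_fr, 2L, ifelse(col_factors > 0, col_factors, 1), "/")
  list(profiles = profiles, support = support,
       pep_mat = pep_scaled, pep_feature = pep_feature, pep_seq = pep_seq,
       col_factors = col_factors)
}

# Concatenate replicate profiles of one condition; keeps features
# quantified in every replicate (profiles with any missing replicate are
# excluded from classification).
concat_replicates <- function(exp_list) {
  feats <- Reduce(intersect, lapply(exp_list, function(e) rownames(e$profiles)))
  mats <- lapply(seq_along(exp_list), function(r) {
    m <- exp_list[[r]]$profiles[feats, , drop = FALSE]
    colnames(m) <- paste0("r", r, "_", colnames(m))
    m
  })
  do.call(cbind, mats)
}

kinetics_stage <- function(psm, params) {
  light <- psm[psm$species == "L", , drop = FALSE]
  resolved <- resolve_psm_accessions(light$accessions)
  light <- light[!is.na(resolved), , drop = FALSE]
  light$accession <- resolved[!is.na(resolved)]
  area_cols <- intersect(ISO_AREA_COLS, names(light))
  if (length(area_cols) == 0L) stop("no isotopomer area columns in PSM table")
  # vectorized equivalent of fractional_synthesis() over all rows:
  # mask areas at offsets not applicable to each peptide's composition
  amat <- as.matrix(light[, area_cols, drop = FALSE])
  amat[is.na(amat)] <- 0
  labs <- sub("^area_", "", area_cols)
  mask <- sapply(labs, function(l) switch(l,
    m0 = rep(TRUE, nrow(light)),
    m8 = light$n_K >= 1, m10 = light$n_R >= 1,
    m16 = light$n_K >= 2, m18 = light$n_K >= 1 & light$n_R >= 1,
    m20 = light$n_R >= 2))
  mask <- matrix(mask, nrow = nrow(light))
  denom <- rowSums(amat * mask)
  fs <- ifelse(denom > 0, 1 - amat[, which(labs == "m0")] / denom, NA_real_)
  weight <- denom
  obs <- data.frame(condition = light$condition,
                    accession = light$accession,
                    peptide = light$sequence,
                    t_h = light$time_h, fs = fs, weight = weight)
  obs <- obs[!is.na(obs$fs), , drop = FALSE]
  key <- interaction(obs$condition, obs$accession, obs$peptide, drop = TRUE)
  fits <- do.call(rbind, lapply(split(obs, key), function(d) {
    f <- fit_turnover_rate(d$t_h, d$fs, d$weight)
    data.frame(condition = d$condition[1], accession = d$accession[1],
               peptide = d$peptide[1], k = f$k, se_k = f$se_k,
               half_life_h = f$half_life_h, n_obs = f$n_obs,
               r_squared = f$r_squared, intensity = mean(d$weight))
  }))
  rownames(fits) <- NULL
  rates <- do.call(rbind, lapply(split(fits, fits$condition), function(d) {
    s <- protein_rate_summary(d, r2_floor = params$r2_floor)
    cbind(condition = d$condition[1], s)
  }))
  rownames(rates) <- NULL
  conds <- unique(psm$condition)
  comparison <- if (length(conds) == 2L) {
    compare_turnover_table(fits, conds[1], conds[2],
                           max_peptides = params$max_peptides)
  } else NULL
  list(peptide_fits = fits, protein_rates = rates, comparison = comparison)
}

dl_stage <- function(exp_data, models, conds, params) {
  pep_feats <- function(cond) {
    tab <- table(unlist(lapply(exp_data[[cond]], function(e)
      unique(paste(e$pep_feature, e$pep_seq, sep = "\r")))))
    # features with >= 2 distinct peptides observed in the condition
    f <- vapply(strsplit(names(tab), "\r", fixed = TRUE), `[`,
                character(1), 1L)
    names(which(table(f) >= 2L))
  }
  feats <- intersect(pep_feats(conds[1]), pep_feats(conds[2]))
  feats <- intersect(feats, rownames(models[[conds[1]]]$profiles_ref))
  feats <- intersect(feats, rownames(models[[conds[2]]]$profiles_ref))
  pep_matrices <- function(cond, f) {
    seqs <- sort(unique(unlist(lapply(exp_data[[cond]], function(e)
      e$pep_seq[e$pep_feature == f]))))
    lapply(exp_data[[cond]], function(e) {
      m <- matrix(0, length(seqs), ncol(e$pep_mat),
                  dimnames = list(seqs, colnames(e$pep_mat)))
      idx <- which(e$pep_feature == f)
      m[e$pep_seq[idx], ] <- e$pep_mat[idx, , drop = FALSE]
      m
    })
  }
  records <- lapply(seq_along(feats), function(i) {
    f <- feats[i]
    r <- bootstrap_dl_probability(
      pep_matrices(conds[1], f), pep_matrices(conds[2], f),
      models[[conds[1]]]$model, models[[conds[2]]]$model,
      n_boot = params$n_boot, seed = params$seed + i)
    data.frame(id = f, source = r$source, destination = r$destination,
               dl_prob = r$dl_prob, n_boot = r$n_boot)
  })
  records <- if (length(records) > 0L) do.call(rbind, records)
             else data.frame(id = character(), source = character(),
                             destination = character(),
                             dl_prob = numeric(), n_boot = integer())
  list(records = records,
       paired = paired_dl_filter(records, params$dl_threshold))
}

pairdist_stage <- function(profile_sets, conds, n_replicates, params) {
  per_condition <- lapply(conds, function(cd) {
    X <- profile_sets[[cd]]
    light <- X[!grepl("_H$", rownames(X)), , drop = FALSE]
    heavy <- X[grepl("_H$", rownames(X)), , drop = FALSE]
    accs <- intersect(rownames(light), sub("_H$", "", rownames(heavy)))
    d <- vapply(accs, function(a)
      pair_distance(light[a, ], heavy[paste0(a, "_H"), ], n_replicates),
      numeric(1))
    null <- null_distance_sample(light, n_pairs = max(length(accs), 2L),
                                 n_replicates = n_replicates,
                                 seed = params$seed)
    list(heavy_light = d, null = null)
  })
  names(per_condition) <- conds
  change <- if (length(conds) == 2L) {
    split_lh <- function(cd) {
      X <- profile_sets[[cd]]
      list(light = X[!grepl("_H$", rownames(X)), , drop = FALSE],
           heavy = X[grepl("_H$", rownames(X)), , drop = FALSE])
    }
    a <- split_lh(conds[1]); b <- split_lh(conds[2])
    tryCatch(
      normalized_pair_change(a$light, a$heavy, b$light, b$heavy,
                             n_replicates = n_replicates,
                             n_ref = params$n_ref, seed = params$seed),
      error = function(e) NULL)
  } else NULL
  list(per_condition = per_condition, change = change)
}

#' Run the full analysis on in-memory tables
#'
#' Executes the pipeline stages on a PSM table plus its design, impurity
#' and marker tables: spectral purity gating, q-value filtering, NNLS
#' impurity correction, isoform-aware species-split rollup, design
#' mapping, column/row normalization, turnover kinetics, compartment
#' classification per condition, bootstrap differential localization and
#' heavy-light pair-distance statistics.
#'
#' @param psm PSM data frame (see [read_psm_table()] for the schema; a
#'   `species` column is inferred if absent).
#' @param design Design data frame (`condition`, `replicate`, `channel`,
#'   `fraction`).
#' @param impurity An [impurity_matrix()].
#' @param markers Marker data frame (`accession`, `compartment`).
#' @param params A [pipeline_params()].
#' @return List with elements `profiles` (per-condition concatenated
#'   replicate profile matrices), `kinetics`, `classification` (per
#'   condition: pruned markers, fitted model, allocations, expected
#'   FDR), `dl`, `pairdist`, and `manifest` (per-stage row counts and
#'   parameters).
#' @seealso [run_pipeline()] for the file-based front end.
#' @export
analyse_dataset <- function(psm, design, impurity, markers,
                            params = pipeline_params()) {
  manifest <- list(params = unclass(params), counts = list())
  manifest$counts$psm_input <- nrow(psm)
  if (!"species" %in% names(psm))
    psm$species <- ifelse(is_heavy_modification(psm$modifications), "H", "L")
  if (!"time_h" %in% names(psm)) stop("PSM table needs a time_h column")

  # purity and identification gates
  if ("purity" %in% names(psm) && params$min_purity > 0) {
    psm <- spectral_purity_gate(psm, params$min_purity)
    manifest$counts$purity_removed <- attr(psm, "n_removed")
  }
  psm <- psm[psm$q_value <= params$q_max, , drop = FALSE]
  manifest$counts$psm_retained <- nrow(psm)

  # impurity correction on all reporter columns at once
  channel_cols <- grep("^intensity_", names(psm), value = TRUE)
  if (length(channel_cols) != ncol(impurity))
    stop("impurity matrix dimension (", ncol(impurity),
         ") does not match channel count (", length(channel_cols), ")")
  corrected <- correct_impurities(as.matrix(psm[, channel_cols]), impurity)
  psm[, channel_cols] <- as.matrix(corrected)

  conds <- unique(as.character(psm$condition))
  reps <- sort(unique(psm$replicate))
  resolved <- resolve_psm_accessions(psm$accessions)
  manifest$counts$multi_accession_removed <- attr(resolved, "n_multi")
  feature <- ifelse(psm$species == "H", paste0(resolved, "_H"), resolved)

  # per-experiment quantification
  exp_data <- lapply(conds, function(cd) {
    lapply(reps, function(r) {
      sel <- which(psm$condition == cd & psm$replicate == r &
                     !is.na(resolved))
      quantify_experiment(psm[sel, , drop = FALSE], feature[sel],
                          design[design$condition == cd &
                                   design$replicate == r, ],
                          channel_cols, params$min_peptides)
    })
  })
  names(exp_data) <- conds
  profile_sets <- lapply(exp_data, concat_replicates)
  manifest$counts$features_profiled <-
    lapply(profile_sets, nrow)

  out <- list(profiles = profile_sets, manifest = manifest)

  if ("kinetics" %in% params$stages) {
    out$kinetics <- kinetics_stage(psm, params)
    out$manifest$counts$peptide_fits <- nrow(out$kinetics$peptide_fits)
  }

  models <- NULL
  if ("classify" %in% params$stages) {
    models <- lapply(conds, function(cd) {
      X <- profile_sets[[cd]]
      mk <- markers[markers$accession %in% rownames(X), ]
      Xm <- X[mk$accession, , drop = FALSE]
      pruned <- prune_markers(Xm, mk$compartment,
                              floor = params$marker_floor,
                              budget = params$prune_budget,
                              max_stall = params$prune_stall,
                              seed = params$seed)
      model <- fit_compartment_model(Xm[pruned$keep, , drop = FALSE],
                                     pruned$labels,
                                     lambda = params$lambda,
                                     outlier_scale = params$outlier_scale,
                                     epsilon = params$epsilon,
                                     outlier_df = params$outlier_df)
      alloc <- allocate(model, X, threshold = params$allocation_threshold)
      list(model = model, pruned = pruned, allocations = alloc,
           expected_fdr = expected_fdr(alloc$probability,
                                       params$allocation_threshold),
           profiles_ref = X)
    })
    names(models) <- conds
    out$classification <- models
    out$manifest$counts$confident_allocations <-
      lapply(models, function(m) sum(m$allocations$confident))
  }

  if ("dl" %in% params$stages && length(conds) == 2L && !is.null(models)) {
    out$dl <- dl_stage(exp_data, models, conds, params)
    out$manifest$counts$dl_calls <-
      sum(out$dl$records$dl_prob > params$dl_threshold)
    out$manifest$counts$paired_dl <- length(out$dl$paired)
  }

  if ("pairdist" %in% params$stages) {
    out$pairdist <- pairdist_stage(profile_sets, conds, length(reps), params)
  }
  out
}

#' Run the pipeline from files
#'
#' File-based front end over [analyse_dataset()]: reads the PSM, design,
#' impurity and marker tables, runs the configured stages, and writes
#' the output TSVs plus a JSON run manifest recording parameters, seeds
#' and per-stage row counts.
#'
#' @param config Named list (or path to a YAML file) with elements
#'   `psm`, `design`, `impurity`, `markers`, `output_dir`, and optional
#'   `params` (arguments to [pipeline_params()]).
#' @return The [analyse_dataset()] result, invisibly; outputs are
#'   written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (p in c("psm", "design", "impurity", "markers")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("config must point to an existing '", p, "' file")
  }
  params <- do.call(pipeline_params, config$params %||% list())
  psm <- read_psm_table(config$psm, q_max = params$q_max)
  design <- read_design(config$design)
  impurity <- read_impurity_matrix(config$impurity)
  markers <- read_markers(config$markers)
  res <- analyse_dataset(psm, design, impurity, markers, params)

  dir.create(config$output_dir %||% ".", recursive = TRUE,
             showWarnings = FALSE)
  outdir <- config$output_dir %||% "."
  for (cd in names(res$profiles)) {
    X <- res$profiles[[cd]]
    write_tsv(data.frame(id = rownames(X), X, check.names = FALSE),
              file.path(outdir, paste0("profiles_", cd, ".tsv")))
  }
  if (!is.null(res$kinetics)) {
    write_tsv(res$kinetics$peptide_fits,
              file.path(outdir, "peptide_rates.tsv"))
    write_tsv(res$kinetics$protein_rates,
              file.path(outdir, "protein_rates.tsv"))
    if (!is.null(res$kinetics$comparison))
      write_tsv(res$kinetics$comparison,
                file.path(outdir, "rate_comparison.tsv"))
  }
  if (!is.null(res$classification)) {
    for (cd in names(res$classification))
      write_tsv(res$classification[[cd]]$allocations,
                file.path(outdir, paste0("allocations_", cd, ".tsv")))
  }
  if (!is.null(res$dl)) {
    write_tsv(res$dl$records, file.path(outdir, "dl_records.tsv"))
    writeLines(res$dl$paired, file.path(outdir, "paired_dl.txt"))
  }
  if (!is.null(res$pairdist) && !is.null(res$pairdist$change)) {
    write_tsv(res$pairdist$change, file.path(outdir, "pair_distances.tsv"))
  }
  res$manifest$versions <- list(
    package = as.character(utils::packageVersion("turnloc")),
    r = R.version.string)
  jsonlite::write_json(res$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
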