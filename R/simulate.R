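# Synthetic dataset generator with a ground-truth ledger: compartment
# sedimentation profiles, first-order SILAC labeling at the chase time,
# TMT reporter spillover through the impurity matrix, replicate
# structure, and planted differential-localization / heavy-only
# partition events.

compartment_names <- function(n) {
  ac16 <- c("cytosol", "ER", "golgi", "lysosome", "mitochondrion",
            "nucleus", "peroxisome", "PM", "proteasome", "ribosome",
            "chromatin", "cytoplasm")
  if (n <= length(ac16)) ac16[seq_len(n)] else sprintf("C%02d", seq_len(n))
}

channel_names <- function(n) {
  if (n == 10L) TMT10_CHANNELS else sprintf("tag%02d", seq_len(n))
}

# Synthetic 10-plex lot sheet: per-channel -2/-1/+1/+2 spill percentages
# in the range reported on vendor certificates (up to ~8% to +1).
default_spills <- function(channels, lot = "SIM-LOT-1") {
  n <- length(channels)
  i <- seq_len(n)
  data.frame(
    channel = channels,
    minus2 = rep(0, n),
    minus1 = round(0.4 + 0.12 * i, 2),
    plus1 = round(7 - 0.35 * i, 2),
    plus2 = round(0.08 + 0.012 * i, 2),
    lot = lot
  )
}

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic dataset
#' generator. Defaults describe the study design the generator emulates:
#' 12 subcellular compartments resolved over 10 ultracentrifugation
#' fractions, 3 replicate experiments per condition, a single 16 h
#' dynamic SILAC chase, and mild multiplicative reporter noise.
#'
#' @param n_compartments Number of compartments (default 12).
#' @param n_fractions Number of ultracentrifugation fractions
#'   (default 10; must be >= 2).
#' @param n_proteins Number of non-marker proteins (default 200).
#' @param markers_per_compartment Marker proteins per compartment
#'   (default 12).
#' @param peptide_lambda,peptide_min Peptides per protein are
#'   `peptide_min + Poisson(peptide_lambda)` (defaults 4 and 3).
#' @param chase_time_h SILAC chase time(s) in hours (default 16; a
#'   vector generates a multi-timepoint design for rate-fit tests).
#' @param rate_range True turnover rates are log-uniform on this per-hour
#'   interval (default `c(0.005, 0.2)`).
#' @param rate_effect Multiplier applied to all true rates in the second
#'   condition (default 1 = no kinetic change).
#' @param replicate_count Replicates per condition (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on every area/intensity (default 0.05).
#' @param dl_fraction Fraction of proteins with a planted full
#'   relocalization (both species move) in condition 2 (default 0.05).
#' @param partition_fraction Fraction with a heavy-only relocalization
#'   (default 0.02).
#' @param conditions Condition labels (length 1 or 2;
#'   default `c("ctl", "stress")`).
#' @param concentration Dirichlet concentration of compartment profiles
#'   (default 0.5, giving peaked sedimentation-like profiles).
#' @param min_profile_distance Minimum pairwise Euclidean distance
#'   between compartment profiles (default 0.3).
#' @param missed_cleavage_rate Fraction of peptides carrying two K/R
#'   residues (default 0.1).
#' @param junk_q_fraction Fraction of PSM rows given a q-value above the
#'   1% identification threshold (default 0.02).
#' @param identity_impurity Use a zero-spill (identity) impurity matrix
#'   instead of the synthetic lot sheet (default `FALSE`).
#' @param seed Integer seed making the whole dataset deterministic.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_compartments = 12, n_fractions = 10,
                       n_proteins = 200, markers_per_compartment = 12,
                       peptide_lambda = 4, peptide_min = 3,
                       chase_time_h = 16, rate_range = c(0.005, 0.2),
                       rate_effect = 1, replicate_count = 3,
                       noise_cv = 0.05, dl_fraction = 0.05,
                       partition_fraction = 0.02,
                       conditions = c("ctl", "stress"),
                       concentration = 0.5, min_profile_distance = 0.3,
                       missed_cleavage_rate = 0.1,
                       junk_q_fraction = 0.02,
                       identity_impurity = FALSE, seed = 1) {
  cfg <- as.list(environment())
  if (n_fractions < 2) stop("n_fractions must be >= 2")
  if (n_compartments < 2) stop("n_compartments must be >= 2")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (dl_fraction < 0 || partition_fraction < 0 ||
      dl_fraction + partition_fraction > 1)
    stop("dl_fraction + partition_fraction must lie in [0, 1]")
  if (!length(conditions) %in% 1:2 || anyDuplicated(conditions))
    stop("conditions must be 1 or 2 unique labels")
  if (any(chase_time_h <= 0)) stop("chase_time_h must be positive")
  if (rate_range[1] <= 0 || rate_range[2] < rate_range[1])
    stop("rate_range must be an increasing positive interval")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic dataset configuration\n")
  cat(sprintf("  %d compartments x %d fractions, %d proteins (+%d markers/compartment)\n",
              x$n_compartments, x$n_fractions, x$n_proteins,
              x$markers_per_compartment))
  cat(sprintf("  conditions: %s; %d replicates; chase %s h; noise CV %.3g\n",
              paste(x$conditions, collapse = ", "), x$replicate_count,
              paste(x$chase_time_h, collapse = ", "), x$noise_cv))
  cat(sprintf("  planted events: DL %.3g, heavy-only partition %.3g; seed %d\n",
              x$dl_fraction, x$partition_fraction, x$seed))
  invisible(x)
}

sim_profiles_impl <- function(n_compartments, n_fractions, concentration,
                              min_distance, max_tries = 500) {
  profiles <- matrix(NA_real_, n_compartments, n_fractions,
                     dimnames = list(compartment_names(n_compartments), NULL))
  for (i in seq_len(n_compartments)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- as.numeric(rdirichlet(1, rep(concentration, n_fractions)))
      if (i == 1L || all(sqrt(rowSums(sweep(
            profiles[seq_len(i - 1L), , drop = FALSE], 2L, p)^2)) >=
            min_distance)) {
        profiles[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("retry budget exhausted: cannot place ", n_compartments,
           " compartments at minimum profile distance ", min_distance)
  }
  colnames(profiles) <- paste0("F", seq_len(n_fractions))
  profiles
}

#' Simulate separated compartment sedimentation profiles
#'
#' Draws one simplex profile per compartment from a Dirichlet
#' distribution, rejecting draws closer than `min_distance` (Euclidean)
#' to any accepted profile. Low concentrations produce peaked profiles
#' resembling differential-ultracentrifugation sedimentation.
#'
#' @param n_compartments Number of compartments (>= 2).
#' @param n_fractions Number of fractions (default 10).
#' @param concentration Dirichlet concentration (> 0; default 0.5).
#' @param seed Integer seed.
#' @param min_distance Minimum pairwise Euclidean separation
#'   (default 0.3).
#' @param max_tries Rejection-sampling budget per compartment
#'   (default 500); exhausting it is an error.
#' @return Matrix (compartments x fractions) of simplex rows; attribute
#'   `"min_pairwise_distance"` reports the realized separation.
#' @export
simulate_compartment_profiles <- function(n_compartments, n_fractions = 10,
                                          concentration = 0.5, seed = 1,
                                          min_distance = 0.3,
                                          max_tries = 500) {
  if (n_compartments < 2) stop("n_compartments must be >= 2")
  stopifnot_scalar(concentration, "concentration", lower = 1e-12)
  p <- with_seed(seed, sim_profiles_impl(n_compartments, n_fractions,
                                         concentration, min_distance,
                                         max_tries))
  attr(p, "min_pairwise_distance") <- min(stats::dist(p))
  p
}

# Random tryptic-looking peptide sequences with the requested K/R
# composition (terminal K/R; missed-cleavage peptides carry one internal).
random_peptides <- function(n_K, n_R) {
  aa <- setdiff(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]], character())
  n <- length(n_K)
  vapply(seq_len(n), function(i) {
    len <- sample(7:14, 1L)
    body <- sample(aa, len, replace = TRUE)
    res <- sample(c(rep("K", n_K[i]), rep("R", n_R[i])))
    term <- res[1L]
    internal <- res[-1L]
    if (length(internal) > 0L)
      body[sample.int(len, length(internal))] <- internal
    paste0(paste(body, collapse = ""), term)
  }, character(1))
}

#' Simulate a complete dual-encoded spatiotemporal proteomics dataset
#'
#' Generates a PSM evidence table, channel-to-fraction design,
#' impurity spill sheet, marker list and ground-truth ledger under the
#' configured study design. Each protein is assigned a compartment and a
#' true first-order rate k; at chase time t the light/heavy abundance
#' split obeys `heavy / (heavy + light) = 1 - exp(-k t)` exactly before
#' noise. Light PSM rows carry the MS1 isotopomer areas (m0 plus the
#' fully heavy partner); both species carry TMT channel intensities
#' equal to the species abundance times the compartment profile, pushed
#' through the impurity matrix, with mean-one multiplicative lognormal
#' noise at `noise_cv`. Planted DL events move both species in the
#' second condition; partition events move only the heavy species.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_dataset`: list with `psm`, `design`,
#'   `spills`, `impurity`, `markers`, `truth` (per-protein ledger),
#'   `profiles` (compartment x fraction), `config`.
#' @export
simulate_dataset <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  with_seed(cfg$seed, {
    n_comp <- cfg$n_compartments
    comps <- compartment_names(n_comp)
    profiles <- sim_profiles_impl(n_comp, cfg$n_fractions,
                                  cfg$concentration,
                                  cfg$min_profile_distance)
    channels <- channel_names(cfg$n_fractions)
    spills <- if (isTRUE(cfg$identity_impurity)) {
      data.frame(channel = channels, minus2 = 0, minus1 = 0,
                 plus1 = 0, plus2 = 0, lot = "IDENTITY")
    } else default_spills(channels)
    M <- impurity_matrix(spills, lot = spills$lot[1])

    n_mark <- cfg$markers_per_compartment * n_comp
    acc <- c(sprintf("MK%04d", seq_len(n_mark)),
             sprintf("SP%04d", seq_len(cfg$n_proteins)))
    n_acc <- length(acc)
    is_marker <- c(rep(TRUE, n_mark), rep(FALSE, cfg$n_proteins))
    comp_base <- c(rep(comps, each = cfg$markers_per_compartment),
                   sample(comps, cfg$n_proteins, replace = TRUE))
    k_base <- exp(stats::runif(n_acc, log(cfg$rate_range[1]),
                               log(cfg$rate_range[2])))

    event <- rep("none", n_acc)
    idx_prot <- which(!is_marker)
    n_dl <- round(cfg$dl_fraction * cfg$n_proteins)
    n_pt <- round(cfg$partition_fraction * cfg$n_proteins)
    two_cond <- length(cfg$conditions) == 2L
    if (two_cond && n_dl + n_pt > 0L) {
      ev <- sample(idx_prot, n_dl + n_pt)
      event[ev[seq_len(n_dl)]] <- "DL"
      if (n_pt > 0L) event[ev[n_dl + seq_len(n_pt)]] <- "partition"
    }
    comp2_L <- comp2_H <- comp_base
    for (i in which(event == "DL"))
      comp2_L[i] <- comp2_H[i] <- sample(setdiff(comps, comp_base[i]), 1L)
    for (i in which(event == "partition"))
      comp2_H[i] <- sample(setdiff(comps, comp_base[i]), 1L)

    # peptides
    n_pep <- cfg$peptide_min + stats::rpois(n_acc, cfg$peptide_lambda)
    pep_of <- rep(seq_len(n_acc), n_pep)
    n_pep_tot <- length(pep_of)
    two_res <- stats::runif(n_pep_tot) < cfg$missed_cleavage_rate
    is_K <- stats::runif(n_pep_tot) < 0.6
    n_K <- as.integer(is_K) + ifelse(two_res, as.integer(stats::runif(n_pep_tot) < 0.5), 0L)
    n_R <- as.integer(!is_K) + ifelse(two_res, 1L - (n_K - as.integer(is_K)), 0L)
    sequences <- random_peptides(n_K, n_R)
    while (anyDuplicated(sequences)) {
      dup <- which(duplicated(sequences))
      sequences[dup] <- random_peptides(n_K[dup], n_R[dup])
    }
    base_int <- stats::rlnorm(n_pep_tot, meanlog = log(1e6), sdlog = 1)
    heavy_lab <- paste0("m", 8L * n_K + 10L * n_R)
    heavy_mod <- paste0(
      ifelse(n_K > 0, paste0(n_K, "xK+", SILAC_K_MASS), ""),
      ifelse(n_K > 0 & n_R > 0, ";", ""),
      ifelse(n_R > 0, paste0(n_R, "xR+", SILAC_R_MASS), ""))

    # randomized channel-to-fraction design per experiment
    design <- do.call(rbind, lapply(cfg$conditions, function(cd) {
      do.call(rbind, lapply(seq_len(cfg$replicate_count), function(r) {
        data.frame(condition = cd, replicate = r, channel = channels,
                   fraction = sample(paste0("F", seq_len(cfg$n_fractions))))
      }))
    }))

    comp_of <- function(cond_i, species) {
      if (cond_i == 1L) comp_base
      else if (species == "L") comp2_L else comp2_H
    }

    rows <- list()
    spec_counter <- 0L
    for (cond_i in seq_along(cfg$conditions)) {
      cd <- cfg$conditions[cond_i]
      k_c <- if (cond_i == 1L) k_base else k_base * cfg$rate_effect
      for (tt in cfg$chase_time_h) {
        fs <- 1 - exp(-k_c * tt)
        for (r in seq_len(cfg$replicate_count)) {
          des <- design[design$condition == cd & design$replicate == r, ]
          fr_idx <- match(des$fraction, colnames(profiles))  # per channel
          for (species in c("L", "H")) {
            comp_i <- match(comp_of(cond_i, species), comps)
            abund <- base_int * (if (species == "L") 1 - fs else fs)[pep_of]
            prof <- profiles[comp_i[pep_of], , drop = FALSE]
            true_ch <- (abund * prof)[, fr_idx, drop = FALSE]
            obs <- true_ch %*% t(unclass(M)) *
              matrix(lognormal_noise(n_pep_tot * length(channels),
                                     cfg$noise_cv),
                     n_pep_tot, length(channels))
            colnames(obs) <- paste0("intensity_", channels)
            areas <- matrix(0, n_pep_tot, length(ISO_AREA_COLS),
                            dimnames = list(NULL, ISO_AREA_COLS))
            if (species == "L") {
              aL <- base_int * (1 - fs)[pep_of] *
                lognormal_noise(n_pep_tot, cfg$noise_cv)
              aH <- base_int * fs[pep_of] *
                lognormal_noise(n_pep_tot, cfg$noise_cv)
              areas[, "area_m0"] <- aL
              areas[cbind(seq_len(n_pep_tot),
                          match(paste0("area_", heavy_lab),
                                ISO_AREA_COLS))] <- aH
            }
            q <- stats::runif(n_pep_tot, 0, 0.009)
            junk <- stats::runif(n_pep_tot) < cfg$junk_q_fraction
            q[junk] <- stats::runif(sum(junk), 0.011, 0.05)
            df <- data.frame(
              condition = cd, replicate = r, time_h = tt,
              spectrum_id = sprintf("sc%07d", spec_counter + seq_len(n_pep_tot)),
              sequence = sequences,
              modifications = if (species == "H") heavy_mod else "",
              accessions = acc[pep_of],
              charge = sample(2:3, n_pep_tot, replace = TRUE),
              rt_s = round(stats::runif(n_pep_tot, 0, 5400), 1),
              q_value = q,
              purity = round(stats::rbeta(n_pep_tot, 45, 4), 4),
              species = species, n_K = n_K, n_R = n_R,
              check.names = FALSE
            )
            rows[[length(rows) + 1L]] <- cbind(df, areas, obs)
            spec_counter <- spec_counter + n_pep_tot
          }
        }
      }
    }
    psm <- do.call(rbind, rows)
    rownames(psm) <- NULL

    truth <- data.frame(accession = acc, is_marker = is_marker,
                        event = event, compartment = comp_base,
                        stringsAsFactors = FALSE)
    for (cond_i in seq_along(cfg$conditions)) {
      cd <- cfg$conditions[cond_i]
      truth[[paste0("k_", cd)]] <- if (cond_i == 1L) k_base
                                   else k_base * cfg$rate_effect
      truth[[paste0("comp_", cd, "_L")]] <- comp_of(cond_i, "L")
      truth[[paste0("comp_", cd, "_H")]] <- comp_of(cond_i, "H")
    }
    markers <- data.frame(accession = acc[is_marker],
                          compartment = comp_base[is_marker])
    structure(list(psm = psm, design = design, spills = spills,
                   impurity = M, markers = markers, truth = truth,
                   profiles = profiles, config = cfg),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic spatiotemporal proteomics dataset\n")
  cat(sprintf("  %d PSM rows; %d proteins + %d markers; %d compartments\n",
              nrow(x$psm), sum(!x$truth$is_marker), sum(x$truth$is_marker),
              nrow(x$profiles)))
  cat(sprintf("  planted events: %d DL, %d partition\n",
              sum(x$truth$event == "DL"), sum(x$truth$event == "partition")))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the table dialects consumed by the pipeline readers: PSM TSV,
#' design CSV, impurity spill CSV, marker CSV, plus the truth ledger and
#' compartment profiles (TSV) and the configuration (YAML).
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(psm = file.path(dir, "psm.tsv"),
             design = file.path(dir, "design.csv"),
             impurity = file.path(dir, "impurity.csv"),
             markers = file.path(dir, "markers.csv"),
             truth = file.path(dir, "truth.tsv"),
             profiles = file.path(dir, "profiles.tsv"),
             config = file.path(dir, "config.yaml"))
  utils::write.table(sim$psm, paths["psm"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(sim$design, paths["design"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$spills, paths["impurity"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$markers, paths["markers"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(compartment = rownames(sim$profiles),
                                sim$profiles, check.names = FALSE),
                     paths["profiles"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(sim$config), paths["config"])
  invisible(paths)
}
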