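# Synthetic-data generator with planted ground truth. It emulates the
# study design the pipeline is built for: paired tumor, premalignant and
# adjacent normal tissue from a small number of patients, profiled for
# both miRNA and mRNA, with a handful of progressively suppressed miRNAs
# whose direct targets rise as the miRNA falls and carry seed sites in
# their 3'-UTRs.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline targets: 2 patients
#' x 3 stages (normal, OLP, OSCC), 500 miRNAs of which 10 are planted as
#' progressively suppressed (log2 change -1.5 per stage, an 8-fold drop
#' normal -> OSCC), 5000 genes of which each planted miRNA up-regulates 2
#' direct targets (+1.5 per stage), sequencing depth 1e6 tags per library,
#' negative-binomial dispersion 0.1. Planted features draw their baseline
#' abundance from the upper half of the abundance distribution: the screen
#' is aimed at well-expressed regulators (an abundant suppressed miRNA and
#' a highly expressed target), and lowly expressed planted features would
#' not emulate that design.
#'
#' @param n_patients number of patients (default 2).
#' @param n_mirnas,n_genes feature counts (defaults 500, 5000).
#' @param n_planted_mirnas progressively suppressed miRNAs (default 10).
#' @param n_planted_targets_per_mirna up-regulated direct targets per
#'   planted miRNA (default 2).
#' @param delta_mirna,delta_target per-stage log2 effect for planted
#'   miRNAs / targets (defaults -1.5, +1.5).
#' @param library_size expected tags per library (default 1e6).
#' @param dispersion negative-binomial dispersion phi (default 0.1;
#'   0 gives Poisson noise).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance
#'   parameters (defaults 0, 1.5).
#' @param patient_effect_sd sd of the per-patient log2 depth/global effect
#'   (default 0.2).
#' @param gene_length_range transcript length range in bp (default
#'   500-5000; lengths feed RPKM).
#' @param utr_length_range 3'-UTR length range in nt (default 500-2000).
#' @param mirna_length mature miRNA length (default 22).
#' @param n_tools number of simulated prediction-tool exports (default 6).
#' @param tool_sensitivity probability a tool reports a true target
#'   (default 0.9).
#' @param tool_fp_rate probability a tool reports any given decoy gene
#'   (default 0.02).
#' @param n_validation samples per group in the simulated Ct / IHC tables
#'   (default 10).
#' @param validation_fold planted qPCR fold change, case vs control
#'   (default 4).
#' @param ct_noise_sd Gaussian noise on simulated Ct values (default 0.25;
#'   0 reproduces the planted fold exactly).
#' @param rng_seed integer seed; every generator output is a pure function
#'   of the configuration including this seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 2, n_mirnas = 500, n_genes = 5000,
                       n_planted_mirnas = 10, n_planted_targets_per_mirna = 2,
                       delta_mirna = -1.5, delta_target = 1.5,
                       library_size = 1e6, dispersion = 0.1,
                       baseline_meanlog = 0, baseline_sdlog = 1.5,
                       patient_effect_sd = 0.2,
                       gene_length_range = c(500, 5000),
                       utr_length_range = c(500, 2000),
                       mirna_length = 22,
                       n_tools = 6, tool_sensitivity = 0.9,
                       tool_fp_rate = 0.02,
                       n_validation = 10, validation_fold = 4,
                       ct_noise_sd = 0.25,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$n_mirnas >= 1, cfg$n_genes >= 1,
            cfg$n_planted_mirnas >= 0,
            cfg$n_planted_mirnas <= cfg$n_mirnas / 2,
            cfg$n_planted_targets_per_mirna >= 0,
            cfg$library_size >= 1, cfg$dispersion >= 0,
            cfg$baseline_sdlog >= 0, cfg$patient_effect_sd >= 0,
            length(cfg$gene_length_range) == 2,
            length(cfg$utr_length_range) == 2,
            cfg$utr_length_range[1] >= cfg$mirna_length,
            cfg$mirna_length >= 8,
            cfg$n_tools >= 1,
            cfg$tool_sensitivity >= 0, cfg$tool_sensitivity <= 1,
            cfg$tool_fp_rate >= 0, cfg$tool_fp_rate <= 1,
            cfg$n_validation >= 1, cfg$validation_fold > 0,
            cfg$ct_noise_sd >= 0)
  n_targets <- cfg$n_planted_mirnas * cfg$n_planted_targets_per_mirna
  if (n_targets > cfg$n_genes / 2)
    stop("too many planted targets for n_genes")
  structure(cfg, class = "sim_config")
}

rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu,
                                                        size = 1 / phi)
}

# Draw ids for planted features from the upper half of baseline abundance.
pick_planted <- function(weights, n_planted) {
  upper <- which(weights >= stats::median(weights))
  sort(sample(upper, n_planted))
}

sim_counts_one_assay <- function(ids, weights, delta, cfg, assay) {
  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  stages <- STAGES
  cols <- as.vector(t(outer(patients, stages, paste, sep = "_")))
  sample_ids <- paste(cols, assay, sep = "_")
  scale <- cfg$library_size / sum(weights)
  pe <- 2^stats::rnorm(cfg$n_patients, 0, cfg$patient_effect_sd)
  counts <- matrix(0, nrow = length(ids), ncol = length(sample_ids),
                   dimnames = list(ids, sample_ids))
  k <- 0
  for (p in seq_along(patients)) {
    for (s in seq_along(stages)) {
      k <- k + 1
      mu <- scale * weights * 2^(delta * (s - 1)) * pe[p]
      counts[, k] <- rnb(length(ids), mu, cfg$dispersion)
    }
  }
  man <- data.frame(sample_id = sample_ids,
                    patient_id = rep(patients, each = length(stages)),
                    stage = rep(stages, times = length(patients)),
                    assay = assay, stringsAsFactors = FALSE)
  list(counts = counts, manifest = man)
}

#' Simulate paired miRNA and mRNA count matrices with planted truth
#'
#' Counts are negative-binomial with mean
#' `baseline_i * 2^(delta_i * stage_index) * patient_effect * depth_scale`
#' (stage_index 0, 1, 2 for normal, OLP, OSCC); delta is 0 for decoys,
#' `delta_mirna` for planted miRNAs and `delta_target` for their targets,
#' so planted change is geometric per stage and monotone by construction.
#' Library sizes are the realized column sums.
#'
#' @param config a [sim_config()].
#' @return list(mirna = [count_matrix()], mrna = [count_matrix()] with
#'   transcript lengths, manifest = [sample_manifest()], truth = list with
#'   planted_mirnas, planted_targets, planted_pairs, mirna_seqs).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  mir_ids <- sprintf("MIR%04d", seq_len(config$n_mirnas))
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))

  w_mir <- stats::rlnorm(config$n_mirnas, config$baseline_meanlog,
                         config$baseline_sdlog)
  planted_mir_idx <- pick_planted(w_mir, config$n_planted_mirnas)
  delta_mir <- rep(0, config$n_mirnas)
  delta_mir[planted_mir_idx] <- config$delta_mirna

  w_gene <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                          config$baseline_sdlog)
  n_targets <- config$n_planted_mirnas * config$n_planted_targets_per_mirna
  planted_gene_idx <- if (n_targets) pick_planted(w_gene, n_targets)
  else integer()
  delta_gene <- rep(0, config$n_genes)
  delta_gene[planted_gene_idx] <- config$delta_target

  mir <- sim_counts_one_assay(mir_ids, w_mir, delta_mir, config, "miRNA")
  mrna <- sim_counts_one_assay(gene_ids, w_gene, delta_gene, config, "mRNA")
  lengths <- stats::setNames(
    sample(config$gene_length_range[1]:config$gene_length_range[2],
           config$n_genes, replace = TRUE), gene_ids)

  planted_mirnas <- mir_ids[planted_mir_idx]
  planted_targets <- gene_ids[planted_gene_idx]
  pairs <- if (n_targets)
    data.frame(mirna = rep(planted_mirnas,
                           each = config$n_planted_targets_per_mirna),
               gene = planted_targets, stringsAsFactors = FALSE)
  else data.frame(mirna = character(), gene = character(),
                  stringsAsFactors = FALSE)
  mirna_seqs <- stats::setNames(random_dna(rep(config$mirna_length,
                                               config$n_planted_mirnas)),
                                planted_mirnas)
  list(
    mirna = count_matrix(mir$counts),
    mrna = count_matrix(mrna$counts, feature_lengths = lengths),
    manifest = sample_manifest(rbind(mir$manifest, mrna$manifest)),
    truth = list(planted_mirnas = planted_mirnas,
                 planted_targets = planted_targets,
                 planted_pairs = pairs,
                 mirna_seqs = mirna_seqs))
}

# n random uppercase-DNA sequences of the given lengths.
random_dna <- function(lens) {
  total <- sum(lens)
  letters <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(letters, grp), paste, character(1), collapse = "")
}

#' Simulate 3'-UTR sequences with planted seed sites
#'
#' One i.i.d.-uniform ACGT UTR per gene. For every planted miRNA-target
#' pair, the miRNA's 7mer-A1 or 8mer match string (chosen at random) is
#' written into the target's UTR at a recorded position. Decoy UTRs that
#' contain a >= 7mer site for any planted miRNA by chance are regenerated
#' (a cleaning step, so that planted sites are the only >= 7mer signal for
#' the planted miRNAs).
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_counts()] (or a list with
#'   `planted_pairs` and `mirna_seqs`).
#' @return list(utrs = named character vector over all genes,
#'   site_positions = data.frame(gene, mirna, start, end, site_class)).
#' @export
simulate_utrs <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 1L)
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  lens <- sample(config$utr_length_range[1]:config$utr_length_range[2],
                 config$n_genes, replace = TRUE)
  utrs <- stats::setNames(random_dna(lens), gene_ids)

  patterns <- unique(unlist(lapply(truth$mirna_seqs, function(s)
    derive_seed_matches(s)[c("7mer-A1", "7mer-m8")])))
  decoys <- setdiff(gene_ids, truth$planted_pairs$gene)
  if (length(patterns)) {
    for (iter in 1:100) {
      dirty <- rep(FALSE, length(decoys))
      for (pat in patterns)
        dirty <- dirty | grepl(pat, utrs[decoys], fixed = TRUE)
      if (!any(dirty)) break
      utrs[decoys[dirty]] <- random_dna(lens[match(decoys[dirty], gene_ids)])
      if (iter == 100) stop("could not generate clean decoy UTRs")
    }
  }

  pos <- NULL
  if (nrow(truth$planted_pairs)) {
    pos <- truth$planted_pairs
    pos$start <- NA_integer_
    pos$end <- NA_integer_
    pos$site_class <- NA_character_
    for (i in seq_len(nrow(pos))) {
      m <- derive_seed_matches(truth$mirna_seqs[[pos$mirna[i]]])
      cls <- sample(c("7mer-A1", "8mer"), 1)
      site <- m[[cls]]
      g <- pos$gene[i]
      L <- nchar(utrs[[g]])
      st <- sample(seq_len(L - nchar(site) + 1L), 1)
      substr(utrs[[g]], st, st + nchar(site) - 1L) <- site
      pos$start[i] <- st
      pos$end[i] <- st + nchar(site) - 1L
      pos$site_class[i] <- cls
    }
  } else {
    pos <- data.frame(mirna = character(), gene = character(),
                      start = integer(), end = integer(),
                      site_class = character(), stringsAsFactors = FALSE)
  }
  list(utrs = utrs, site_positions = pos)
}

#' Simulate prediction-tool exports
#'
#' For every planted miRNA, each of `n_tools` tools reports each true
#' target independently with probability `tool_sensitivity` and each decoy
#' gene with probability `tool_fp_rate`.
#'
#' @param config a [sim_config()].
#' @param truth as in [simulate_utrs()].
#' @return Named list (by miRNA) of lists of [prediction_set()]s.
#' @export
simulate_prediction_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 2L)
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  out <- list()
  for (m in truth$planted_mirnas) {
    true_targets <- truth$planted_pairs$gene[truth$planted_pairs$mirna == m]
    decoys <- setdiff(gene_ids, true_targets)
    sets <- lapply(seq_len(config$n_tools), function(t) {
      hit <- true_targets[stats::runif(length(true_targets)) <
                            config$tool_sensitivity]
      fp <- decoys[stats::runif(length(decoys)) < config$tool_fp_rate]
      prediction_set(paste0("tool", t), m, c(hit, fp))
    })
    out[[m]] <- sets
  }
  out
}

#' Simulate qPCR Ct and IHC score tables
#'
#' Ct values carry a planted case-vs-control fold change of
#' `validation_fold` on the target (reference gene flat), with Gaussian
#' noise of sd `ct_noise_sd`; zero noise reproduces the planted fold
#' exactly. IHC tables draw case samples to stochastically dominate
#' controls in both percent-positive and intensity; two markers share a
#' per-sample latent severity so their weighted scores correlate.
#'
#' @param config a [sim_config()].
#' @return list(ct = Ct data.frame, ihc = marker-1 IHC data.frame,
#'   ihc2 = marker-2 IHC data.frame).
#' @export
simulate_validation_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 3L)
  n <- config$n_validation
  sd <- config$ct_noise_sd
  ids <- function(g) sprintf("%s%02d", g, seq_len(n))
  ct <- data.frame(
    sample_id = c(ids("case"), ids("ctrl")),
    group = rep(c("case", "control"), each = n),
    ct_target = c(25 - log2(config$validation_fold) + stats::rnorm(n, 0, sd),
                  25 + stats::rnorm(n, 0, sd)),
    ct_reference = 20 + stats::rnorm(2 * n, 0, sd),
    stringsAsFactors = FALSE)

  make_ihc <- function(u, group) {
    case <- group == "case"
    percent <- ifelse(case, pmin(100, 50 + 45 * u + stats::rnorm(n, 0, 5)),
                      pmax(0, 30 * u + stats::rnorm(n, 0, 5)))
    intensity <- ifelse(case, 2 + (u > 0.5), 0 + (u > 0.5))
    data.frame(sample_id = ids(if (case[1]) "case" else "ctrl"),
               group = if (case[1]) "case" else "control",
               percent_positive = round(percent, 1),
               intensity = as.integer(intensity), stringsAsFactors = FALSE)
  }
  u_case <- stats::runif(n)
  u_ctrl <- stats::runif(n)
  ihc <- rbind(make_ihc(u_case, rep("case", n)),
               make_ihc(u_ctrl, rep("control", n)))
  # second marker from the same latent severity, independent measurement
  # noise, so per-sample scores correlate across markers
  ihc2 <- rbind(make_ihc(pmin(1, pmax(0, u_case + stats::rnorm(n, 0, 0.1))),
                         rep("case", n)),
                make_ihc(pmin(1, pmax(0, u_ctrl + stats::rnorm(n, 0, 0.1))),
                         rep("control", n)))
  ihc$a <- ihc_bin_percent(ihc$percent_positive)
  ihc$score <- ihc_score(ihc$a, ihc$intensity)
  ihc2$a <- ihc_bin_percent(ihc2$percent_positive)
  ihc2$score <- ihc_score(ihc2$a, ihc2$intensity)
  list(ct = ct, ihc = ihc, ihc2 = ihc2)
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator with seeds derived from `rng_seed` and optionally
#' writes all pipeline input files (counts and manifest TSVs, UTR and
#' miRNA FASTA, per-tool prediction TSVs, Ct and IHC TSVs) plus
#' `truth.json` to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list(counts-bundle fields, utrs, site_positions, predictions,
#'   validation, config).
#' @export
simulate_all <- function(config = sim_config(), out_dir = NULL) {
  cb <- simulate_counts(config)
  ub <- simulate_utrs(config, cb$truth)
  preds <- simulate_prediction_sets(config, cb$truth)
  val <- simulate_validation_tables(config)
  cb$truth$site_positions <- ub$site_positions
  res <- list(mirna = cb$mirna, mrna = cb$mrna, manifest = cb$manifest,
              truth = cb$truth, utrs = ub$utrs, predictions = preds,
              validation = val, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_count_table(cb$mirna, file.path(out_dir, "mirna_counts.tsv"))
    write_count_table(cb$mrna, file.path(out_dir, "mrna_counts.tsv"))
    write_sample_manifest(cb$manifest, file.path(out_dir, "manifest.tsv"))
    write_fasta(ub$utrs, file.path(out_dir, "utrs.fa"))
    write_fasta(cb$truth$mirna_seqs, file.path(out_dir, "mirnas.fa"))
    pd <- file.path(out_dir, "predictions")
    dir.create(pd, showWarnings = FALSE)
    for (m in names(preds))
      for (s in preds[[m]])
        write_gene_list(s$genes,
                        file.path(pd, paste0(m, "_", s$tool_name, ".tsv")))
    utils::write.table(val$ct, file.path(out_dir, "ct_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(val$ihc, file.path(out_dir, "ihc_marker1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(val$ihc2, file.path(out_dir, "ihc_marker2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cb$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
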