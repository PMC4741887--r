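# End-to-end orchestration: simulate (or load) -> progression screen ->
# target-prediction cascade -> validation statistics -> machine-readable
# report. Every threshold and the seed are recorded verbatim in the
# report, and the whole run is a pure function of the configuration.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] (synthetic run) or NULL when all inputs are
#'   supplied as files via `paths`.
#' @param paths named list of input file paths for a file-based run:
#'   mirna_counts, mrna_counts, manifest, utrs, mirnas (FASTA),
#'   predictions (directory of `<mirna>_<tool>.tsv` gene lists),
#'   regulator_targets, ct, ihc, ihc2 (all optional except the first three).
#' @param thresholds a [screen_thresholds()] list.
#' @param consensus_k minimum supporting prediction tools (default 3).
#' @param min_site_class minimum seed-site class for the UTR filter
#'   (default "7mer": 7mer-A1, 7mer-m8 or 8mer).
#' @param rng_seed seed for a synthetic run; overrides `sim$rng_seed`.
#' @export
run_config <- function(sim = sim_config(), paths = list(),
                       thresholds = screen_thresholds(),
                       consensus_k = 3, min_site_class = "7mer",
                       rng_seed = NULL) {
  if (!is.null(sim) && !is.null(rng_seed)) sim$rng_seed <- rng_seed
  structure(list(sim = sim, paths = paths, thresholds = thresholds,
                 consensus_k = consensus_k, min_site_class = min_site_class),
            class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    res <- simulate_all(config$sim)
    # a regulator-target list may accompany a synthetic run
    if (!is.null(config$paths$regulator_targets))
      res$regulator_targets <- read_gene_list(config$paths$regulator_targets)
    return(res)
  }
  p <- config$paths
  for (need in c("mirna_counts", "mrna_counts", "manifest"))
    if (is.null(p[[need]])) stop("paths$", need, " is required")
  manifest <- read_sample_manifest(p$manifest)
  res <- list(
    mirna = read_count_table(p$mirna_counts, manifest),
    mrna = read_count_table(p$mrna_counts, manifest),
    manifest = manifest, truth = NULL,
    utrs = if (!is.null(p$utrs)) read_fasta(p$utrs),
    predictions = NULL, validation = list(ct = NULL, ihc = NULL, ihc2 = NULL))
  mirna_seqs <- if (!is.null(p$mirnas)) read_fasta(p$mirnas)
  if (!is.null(p$predictions)) {
    files <- list.files(p$predictions, pattern = "\\.tsv$", full.names = TRUE)
    preds <- list()
    for (f in files) {
      base <- tools::file_path_sans_ext(basename(f))
      parts <- strsplit(base, "_", fixed = TRUE)[[1]]
      m <- toupper(parts[1])
      tool <- paste(parts[-1], collapse = "_")
      preds[[m]] <- c(preds[[m]],
                      list(prediction_set(tool, m, read_gene_list(f))))
    }
    res$predictions <- preds
  }
  if (!is.null(mirna_seqs)) {
    nm <- toupper(names(mirna_seqs))
    res$truth <- list(mirna_seqs = stats::setNames(as.character(mirna_seqs),
                                                   nm))
  }
  if (!is.null(p$ct)) res$validation$ct <- read_ct_table(p$ct)
  if (!is.null(p$ihc)) res$validation$ihc <- read_ihc_table(p$ihc)
  if (!is.null(p$ihc2)) res$validation$ihc2 <- read_ihc_table(p$ihc2)
  if (!is.null(p$regulator_targets))
    res$regulator_targets <- read_gene_list(p$regulator_targets)
  res
}

# The per-miRNA prediction cascade: consensus -> intersect up-regulated ->
# seed filter -> rank. Returns the stage cardinalities alongside the
# ranked candidates, so the monotone filtering chain is inspectable.
target_cascade <- function(mirna_id, mirna_seq, pred_sets, upregulated,
                           utrs, mrna_expr, mirna_expr, manifest,
                           consensus_k, min_site_class, pseudo) {
  consensus <- consensus_targets(pred_sets, k = consensus_k)
  upreg_hits <- intersect_upregulated(consensus, upregulated)
  filtered <- seed_filter(upreg_hits, utrs, mirna_seq, mirna_id,
                          min_class = min_site_class)
  ranked <- rank_candidates(filtered, mrna_expr, mirna_expr, manifest,
                            mirna_id, support = attr(consensus, "support"),
                            sites = attr(filtered, "sites"), pseudo = pseudo)
  list(mirna_id = mirna_id,
       cardinality = c(consensus = length(consensus),
                       upregulated_intersection = length(upreg_hits),
                       seed_filtered = length(filtered)),
       candidates = ranked, sites = attr(filtered, "sites"))
}

#' Run the full screen-and-predict pipeline
#'
#' Simulates (or loads) all inputs, screens miRNAs for consistent
#' progressive change and mRNAs for consistent up-regulation, runs the
#' prediction cascade for every screened-down miRNA with available
#' prediction sets, intersects the up-regulated genes with a regulator
#' target list when one is supplied, computes the validation statistics,
#' and, when planted truth is available, scores recovery against it.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes the screen TSVs,
#'   per-miRNA candidate/site TSVs and `report.json`.
#' @return The run report (list, JSON-serializable).
#' @export
run_full_pipeline <- function(config = run_config(), out_dir = NULL) {
  inputs <- load_inputs(config)
  th <- config$thresholds

  mir_screen <- screen_mirnas(inputs$mirna, inputs$manifest, th)
  upregulated <- screen_upregulated_mrnas(inputs$mrna, inputs$manifest, th)
  mrna_expr <- normalize_counts(inputs$mrna)
  mirna_expr <- normalize_counts(inputs$mirna)

  cascades <- list()
  down <- as.character(mir_screen$down)
  seqs <- inputs$truth$mirna_seqs
  preds <- inputs$predictions
  for (m in down) {
    if (is.null(seqs) || !m %in% names(seqs) || is.null(preds[[m]])) next
    cascades[[m]] <- target_cascade(
      m, seqs[[m]], preds[[m]], upregulated, inputs$utrs,
      mrna_expr, mirna_expr, inputs$manifest,
      config$consensus_k, config$min_site_class, th$pseudo)
  }

  downstream <- NULL
  if (!is.null(inputs$regulator_targets))
    downstream <- as.character(
      downstream_intersection(upregulated, inputs$regulator_targets))

  val <- validation_stats(inputs$validation$ct, inputs$validation$ihc,
                          inputs$validation$ihc2)

  truth_metrics <- NULL
  if (!is.null(inputs$truth$planted_mirnas)) {
    truth <- inputs$truth
    called <- as.character(mir_screen$down)
    recovered <- intersect(called, truth$planted_mirnas)
    false_calls <- union(setdiff(called, truth$planted_mirnas),
                         as.character(mir_screen$up))
    pair_ok <- logical(nrow(truth$planted_pairs))
    for (i in seq_len(nrow(truth$planted_pairs))) {
      m <- truth$planted_pairs$mirna[i]
      g <- truth$planted_pairs$gene[i]
      pair_ok[i] <- g %in% as.character(upregulated) &&
        !is.null(cascades[[m]]) && g %in% cascades[[m]]$candidates$gene
    }
    eligible <- truth$planted_pairs$gene %in% as.character(upregulated) &
      truth$planted_pairs$mirna %in% called
    truth_metrics <- list(
      n_planted_mirnas = length(truth$planted_mirnas),
      n_recovered_mirnas = length(recovered),
      mirna_sensitivity = length(recovered) /
        max(1, length(truth$planted_mirnas)),
      n_false_mirna_calls = length(false_calls),
      mirna_fdr = length(false_calls) /
        max(1, length(false_calls) + length(recovered)),
      n_planted_pairs = nrow(truth$planted_pairs),
      n_eligible_pairs = sum(eligible),
      n_pairs_through_cascade = sum(pair_ok),
      pairs_all_eligible_recovered = all(pair_ok[eligible]))
  }

  report <- list(
    config = list(thresholds = th, consensus_k = config$consensus_k,
                  min_site_class = config$min_site_class,
                  rng_seed = if (!is.null(config$sim)) config$sim$rng_seed),
    screen = list(
      n_mirnas_tested = nrow(mir_screen$consensus),
      n_mirnas_up = length(mir_screen$up),
      n_mirnas_down = length(mir_screen$down),
      mirnas_down = as.character(mir_screen$down),
      n_genes_upregulated = length(upregulated)),
    cascades = lapply(cascades, function(cc)
      list(mirna_id = cc$mirna_id, cardinality = as.list(cc$cardinality),
           candidates = cc$candidates)),
    downstream_intersection = downstream,
    validation = list(
      qpcr_mean_fold = if (!is.null(val$qpcr)) val$qpcr$mean_fold,
      qpcr_mw_p = if (!is.null(val$qpcr)) val$qpcr$mw$p,
      ihc_mw_p = if (!is.null(val$ihc) && !is.null(val$ihc$mw))
        val$ihc$mw$p,
      marker_spearman_rho = if (!is.null(val$marker_correlation))
        val$marker_correlation$rho,
      marker_spearman_p = if (!is.null(val$marker_correlation))
        val$marker_correlation$p),
    truth_metrics = truth_metrics)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_screen_result(mir_screen, file.path(out_dir, "mirna_screen"))
    write_gene_list(upregulated, file.path(out_dir, "upregulated_genes.tsv"))
    for (m in names(cascades)) {
      utils::write.table(cascades[[m]]$candidates,
                         file.path(out_dir, paste0(m, "_candidates.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_seed_sites(cascades[[m]]$sites,
                       file.path(out_dir, paste0(m, "_seed_sites.tsv")))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(report)
}
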