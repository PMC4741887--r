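# Monotone-progression screen across normal -> OLP -> OSCC.
#
# A feature is called in one patient when its expression moves in the same
# direction over both stage transitions (OLP vs normal, OSCC vs OLP), the
# overall normal -> OSCC change passes the fold cutoff, and the exact test
# on the extreme contrast (normal vs OSCC counts) passes the FDR threshold.
# The intermediate stage contributes monotonicity only; no trend test is
# invented. A feature enters the final up/down list only when every patient
# agrees on the direction.

#' Screen thresholds
#'
#' Extends [de_thresholds()] with the monotonicity options.
#'
#' @param strict_transitions require each single transition to pass the fold
#'   cutoff too (default FALSE: the cutoff applies to the overall
#'   normal -> OSCC contrast only).
#' @param allow_flat_transition treat a transition with log2 ratio exactly 0
#'   as monotone (default FALSE: flat breaks monotonicity).
#' @inheritParams de_thresholds
#' @export
screen_thresholds <- function(min_abs_log2fc = 1, max_q = 0.05, pseudo = 0.5,
                              strict_transitions = FALSE,
                              allow_flat_transition = FALSE) {
  c(de_thresholds(min_abs_log2fc, max_q, pseudo),
    list(strict_transitions = strict_transitions,
         allow_flat_transition = allow_flat_transition))
}

#' Progression call for one feature in one patient
#'
#' @param stage_values expression values at (normal, OLP, OSCC).
#' @param stage_counts raw counts at (normal, OLP, OSCC) for the exact test.
#' @param stage_depths library sizes at the three stages.
#' @param thresholds a [screen_thresholds()] list.
#' @param q FDR-adjusted q for the normal-vs-OSCC test; defaults to the raw
#'   p (single-feature use).
#' @return one-row data.frame: transition and overall log2 ratios, p, q,
#'   direction in \{up, down, none\}.
#' @export
progression_call <- function(stage_values, stage_counts, stage_depths,
                             thresholds = screen_thresholds(), q = NULL) {
  if (length(stage_values) != 3L || any(is.na(stage_values)))
    stop("need expression values for all of (normal, OLP, OSCC)")
  t1 <- log2_ratio(stage_values[2], stage_values[1], thresholds$pseudo)
  t2 <- log2_ratio(stage_values[3], stage_values[2], thresholds$pseudo)
  overall <- log2_ratio(stage_values[3], stage_values[1], thresholds$pseudo)
  p <- ac_exact_test(stage_counts[1], stage_counts[3],
                     stage_depths[1], stage_depths[3])
  if (is.null(q)) q <- p
  dir <- call_direction(t1, t2, overall, q, thresholds)
  data.frame(transition_log2fc_1 = t1, transition_log2fc_2 = t2,
             overall_log2fc = overall, p = p, q = q, direction = dir,
             stringsAsFactors = FALSE)
}

# Vectorized direction rule shared by progression_call and screen_features.
call_direction <- function(t1, t2, overall, q, th) {
  up_mono <- if (th$allow_flat_transition) t1 >= 0 & t2 >= 0 else t1 > 0 & t2 > 0
  dn_mono <- if (th$allow_flat_transition) t1 <= 0 & t2 <= 0 else t1 < 0 & t2 < 0
  fold <- abs(overall) >= th$min_abs_log2fc
  if (th$strict_transitions)
    fold <- fold & abs(t1) >= th$min_abs_log2fc & abs(t2) >= th$min_abs_log2fc
  sig <- q <= th$max_q
  dir <- rep("none", length(overall))
  dir[up_mono & overall > 0 & fold & sig] <- "up"
  dir[dn_mono & overall < 0 & fold & sig] <- "down"
  dir
}

#' Consensus direction across patients
#'
#' Returns a direction only when every patient's call shares it.
#' @param directions character vector of per-patient calls
#'   ("up"/"down"/"none"), at least one.
#' @export
cross_patient_consensus <- function(directions) {
  if (!length(directions)) stop("need at least one patient call")
  u <- unique(directions)
  if (length(u) == 1L && u %in% c("up", "down")) u else "none"
}

#' Progression screen over a count matrix
#'
#' Applies [progression_call()] to every feature in every patient of one
#' assay, with Benjamini-Hochberg adjustment over all features within each
#' patient's normal-vs-OSCC contrast before thresholding, then takes the
#' cross-patient consensus.
#'
#' @param cm a [count_matrix()] for the assay.
#' @param manifest a [sample_manifest()]; every patient of the assay must
#'   have all three stages.
#' @param assay "miRNA" or "mRNA".
#' @param thresholds a [screen_thresholds()] list.
#' @return A `screen_result`: list with `up` and `down` [gene_list()]s,
#'   `calls` (per feature x patient data.frame), `consensus` (per feature),
#'   and `thresholds`.
#' @export
screen_features <- function(cm, manifest, assay = c("miRNA", "mRNA"),
                            thresholds = screen_thresholds()) {
  assay <- match.arg(assay)
  man <- manifest[manifest$assay == assay, , drop = FALSE]
  if (!nrow(man)) stop("manifest has no samples for assay ", assay)
  missing_samp <- setdiff(man$sample_id, colnames(cm$counts))
  if (length(missing_samp))
    stop("manifest sample(s) absent from counts: ",
         paste(missing_samp, collapse = ", "))
  patients <- sort(unique(man$patient_id))
  expr <- normalize_counts(cm)$values
  calls <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pm <- man[man$patient_id == patients[i], , drop = FALSE]
    got <- as.character(pm$stage)
    if (!setequal(got, STAGES))
      stop("patient ", patients[i], " (", assay, ") is missing stage(s): ",
           paste(setdiff(STAGES, got), collapse = ", "))
    sid <- stats::setNames(pm$sample_id, as.character(pm$stage))[STAGES]
    v <- expr[, sid, drop = FALSE]
    t1 <- log2_ratio(v[, 2], v[, 1], thresholds$pseudo)
    t2 <- log2_ratio(v[, 3], v[, 2], thresholds$pseudo)
    overall <- log2_ratio(v[, 3], v[, 1], thresholds$pseudo)
    p <- ac_exact_test(cm$counts[, sid[1]], cm$counts[, sid[3]],
                       cm$library_sizes[[sid[1]]], cm$library_sizes[[sid[3]]])
    q <- bh_fdr(p)
    dir <- call_direction(t1, t2, overall, q, thresholds)
    calls[[i]] <- data.frame(
      feature_id = rownames(cm$counts), patient_id = patients[i],
      v_normal = v[, 1], v_OLP = v[, 2], v_OSCC = v[, 3],
      transition_log2fc_1 = t1, transition_log2fc_2 = t2,
      overall_log2fc = overall, p = p, q = q, direction = dir,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  dirmat <- matrix(calls$direction, ncol = length(patients),
                   dimnames = list(rownames(cm$counts), patients))
  consensus <- apply(dirmat, 1, cross_patient_consensus)
  consensus_df <- data.frame(feature_id = rownames(cm$counts),
                             direction = unname(consensus),
                             row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    up = gene_list(names(consensus)[consensus == "up"], name = "up"),
    down = gene_list(names(consensus)[consensus == "down"], name = "down"),
    calls = calls, consensus = consensus_df, assay = assay,
    thresholds = thresholds), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result (", x$assay, "): ", length(x$up), " up, ",
      length(x$down), " down of ", nrow(x$consensus), " features\n", sep = "")
  invisible(x)
}

#' Screen miRNAs for consistent progressive change
#'
#' @inheritParams screen_features
#' @return A `screen_result` (see [screen_features()]).
#' @export
screen_mirnas <- function(cm, manifest, thresholds = screen_thresholds()) {
  screen_features(cm, manifest, assay = "miRNA", thresholds = thresholds)
}

#' Screen mRNAs and return the consistently up-regulated genes
#'
#' The up-regulated side of the mRNA screen: candidate miRNA targets are
#' expected among genes rising with progression when the miRNA falls.
#'
#' @inheritParams screen_features
#' @return A [gene_list()] of consensus up-regulated genes; the full
#'   `screen_result` is attached as attribute `"screen"`.
#' @export
screen_upregulated_mrnas <- function(cm, manifest,
                                     thresholds = screen_thresholds()) {
  res <- screen_features(cm, manifest, assay = "mRNA", thresholds = thresholds)
  structure(res$up, screen = res)
}

#' Write a screen result to TSV files
#' @export
write_screen_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$calls, file.path(dir, "screen_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$consensus, file.path(dir, "screen_consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(res$up, file.path(dir, "up.tsv"))
  write_gene_list(res$down, file.path(dir, "down.tsv"))
  invisible(dir)
}
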