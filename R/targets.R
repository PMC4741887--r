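# Canonical miRNA seed-site scanning and the target-prediction cascade:
# consensus over tool exports -> intersection with up-regulated genes ->
# de-novo 3'-UTR seed-site filter -> ranking by abundance and
# anti-correlation -> regulator-target intersection.

SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
# specificity for collapsing nested matches: 8mer > 7mer-m8 >= 7mer-A1 > 6mer
SITE_RANK <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)

revcomp_dna <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Seed-match strings of a mature miRNA
#'
#' Canonical site classes on the sense strand of a target 3'-UTR, written
#' 5'->3' in the DNA alphabet:
#' \itemize{
#'   \item 6mer: reverse complement of miRNA nucleotides 2-7 (the seed);
#'   \item 7mer-m8: reverse complement of nucleotides 2-8;
#'   \item 7mer-A1: the 6mer followed by a literal A opposite miRNA
#'     nucleotide 1;
#'   \item 8mer: the 7mer-m8 followed by that literal A.
#' }
#'
#' @param mirna_seq mature miRNA sequence, 5'->3', RNA or DNA alphabet,
#'   length >= 8.
#' @return Named character vector of the four match strings.
#' @export
derive_seed_matches <- function(mirna_seq) {
  s <- chartr("U", "T", toupper(mirna_seq))
  if (nchar(s) < 8L)
    stop("mature miRNA must be at least 8 nt, got ", nchar(s))
  if (grepl("[^ACGTN]", s)) stop("illegal character in miRNA sequence")
  m6 <- revcomp_dna(substr(s, 2, 7))
  m7m8 <- revcomp_dna(substr(s, 2, 8))
  c("6mer" = m6, "7mer-A1" = paste0(m6, "A"),
    "7mer-m8" = m7m8, "8mer" = paste0(m7m8, "A"))
}

# All (possibly overlapping) start positions of a fixed pattern.
all_starts <- function(seq, pattern) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Scan a 3'-UTR for canonical seed sites of one miRNA
#'
#' Reports every occurrence of every site class; a match whose interval is
#' contained in the interval of a more specific reported site is collapsed
#' into it (e.g. the 6mer and both 7mers inside an 8mer are not reported
#' separately). Coordinates are 1-based inclusive on the sense strand of
#' the supplied UTR; the antisense strand is never searched.
#'
#' @param utr_id identifier for the UTR.
#' @param utr_seq UTR sequence (DNA or RNA alphabet; normalized internally).
#' @param mirna_seq mature miRNA sequence.
#' @param mirna_id identifier recorded in the output.
#' @return data.frame: utr_id, start, end, site_class, matched_seq,
#'   mirna_id; sorted by start; zero rows when nothing matches.
#' @export
scan_utr <- function(utr_id, utr_seq, mirna_seq, mirna_id = NA_character_) {
  seq <- chartr("U", "T", toupper(utr_seq))
  matches <- derive_seed_matches(mirna_seq)
  cand <- lapply(names(matches), function(cl) {
    st <- all_starts(seq, matches[[cl]])
    if (!length(st)) return(NULL)
    data.frame(start = st, end = st + nchar(matches[[cl]]) - 1L,
               site_class = cl, matched_seq = matches[[cl]],
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand))
    return(empty_sites(utr_id, mirna_id))
  cand <- cand[order(-SITE_RANK[cand$site_class], cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    kept <- which(keep)
    contained <- length(kept) &&
      any(cand$start[kept] <= cand$start[i] & cand$end[kept] >= cand$end[i] &
            SITE_RANK[cand$site_class[kept]] > SITE_RANK[cand$site_class[i]])
    keep[i] <- !contained
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  data.frame(utr_id = utr_id, out, mirna_id = mirna_id,
             row.names = NULL, stringsAsFactors = FALSE)
}

empty_sites <- function(utr_id = character(), mirna_id = character()) {
  data.frame(utr_id = character(), start = integer(), end = integer(),
             site_class = character(), matched_seq = character(),
             mirna_id = character(), stringsAsFactors = FALSE)
}

#' Scan many UTRs for one miRNA
#'
#' @param utrs named character vector of UTR sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams scan_utr
#' @return Row-bound [scan_utr()] results.
#' @export
scan_utrs <- function(utrs, mirna_seq, mirna_id = NA_character_) {
  res <- lapply(names(utrs), function(id)
    scan_utr(id, utrs[[id]], mirna_seq, mirna_id))
  out <- do.call(rbind, res)
  if (is.null(out)) empty_sites() else out
}

#' Write seed sites as a BED-like 1-based TSV
#' @export
write_seed_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' A target-prediction tool export
#'
#' @param tool_name name of the prediction tool the genes came from.
#' @param mirna_id the miRNA the predictions are for.
#' @param genes predicted target gene symbols.
#' @export
prediction_set <- function(tool_name, mirna_id, genes) {
  structure(list(tool_name = tool_name, mirna_id = toupper(mirna_id),
                 genes = gene_list(genes, name = tool_name)),
            class = "prediction_set")
}

#' Consensus targets across prediction tools
#'
#' Genes predicted by at least `k` of the supplied tools (the
#' multi-program prediction cutoff).
#'
#' @param sets list of [prediction_set()]s, all for the same miRNA, unique
#'   tool names.
#' @param k minimum number of supporting tools (default 3).
#' @return A [gene_list()] with per-gene support counts in attribute
#'   `"support"`.
#' @export
consensus_targets <- function(sets, k = 3) {
  stopifnot(k >= 1, length(sets) >= 1)
  tools <- vapply(sets, `[[`, character(1), "tool_name")
  if (anyDuplicated(tools))
    stop("duplicate tool name: ", tools[duplicated(tools)][1])
  mirnas <- unique(vapply(sets, `[[`, character(1), "mirna_id"))
  if (length(mirnas) > 1L)
    stop("prediction sets mix miRNAs: ", paste(mirnas, collapse = ", "))
  support <- table(unlist(lapply(sets, function(s) unique(s$genes))))
  kept <- names(support)[support >= k]
  structure(gene_list(kept, name = paste0("consensus_k", k)),
            support = stats::setNames(as.integer(support), names(support)))
}

#' Intersect predicted targets with up-regulated genes
#'
#' Case-insensitive set intersection (a suppressed miRNA's direct targets
#' are expected among the genes rising with progression).
#' @param predicted,upregulated [gene_list()]s or character vectors.
#' @export
intersect_upregulated <- function(predicted, upregulated) {
  intersect_gene_lists(predicted, upregulated)
}

#' Filter candidate genes by the presence of a seed site in their 3'-UTR
#'
#' Keeps genes whose UTR carries at least one site of the minimum class or
#' better; genes lacking a UTR record are dropped with a warning.
#'
#' @param genes candidate gene symbols.
#' @param utrs named character vector, gene symbol -> 3'-UTR sequence.
#' @param mirna_seq mature miRNA sequence.
#' @param mirna_id recorded in the site table.
#' @param min_class minimum qualifying site class; `"7mer"` (default) means
#'   7mer-A1, 7mer-m8 or 8mer; any single class name sets that floor.
#' @return A [gene_list()] of surviving genes, with the qualifying site
#'   table in attribute `"sites"`.
#' @export
seed_filter <- function(genes, utrs, mirna_seq, mirna_id = NA_character_,
                        min_class = "7mer") {
  min_rank <- if (identical(min_class, "7mer")) SITE_RANK[["7mer-A1"]]
  else SITE_RANK[[match.arg(min_class, SITE_CLASSES)]]
  genes <- toupper(as.character(genes))
  names(utrs) <- toupper(names(utrs))
  missing <- setdiff(genes, names(utrs))
  if (length(missing))
    warning("no UTR record for gene(s), dropped: ",
            paste(missing, collapse = ", "))
  present <- intersect(genes, names(utrs))
  sites <- scan_utrs(utrs[present], mirna_seq, mirna_id)
  sites <- sites[SITE_RANK[sites$site_class] >= min_rank, , drop = FALSE]
  structure(gene_list(unique(sites$utr_id), name = "seed_filtered"),
            sites = sites)
}

#' Rank candidate targets by abundance and anti-correlation
#'
#' For each gene, `peak_expression` is its maximum normalized expression
#' over all samples, and `anticorr` is the Pearson correlation between the
#' gene's and the miRNA's per-patient stage-transition log2 ratios (two
#' transitions per patient). A strong direct target of a falling miRNA is
#' abundant and anti-correlated. Ordering: descending peak expression, then
#' ascending anticorr (most negative first, undefined last), then gene
#' symbol.
#'
#' @param genes candidate gene symbols.
#' @param mrna_expr `expression_matrix` for the mRNA assay (e.g. RPKM).
#' @param mirna_expr `expression_matrix` for the miRNA assay.
#' @param manifest a [sample_manifest()] covering both assays.
#' @param mirna_id the screened miRNA's feature id in `mirna_expr`.
#' @param support optional named support counts (from [consensus_targets()]).
#' @param sites optional seed-site table (from [seed_filter()]).
#' @param pseudo pseudocount for the transition log2 ratios.
#' @return data.frame of candidates in rank order: gene, support_count,
#'   n_seed_sites, peak_expression, anticorr.
#' @export
rank_candidates <- function(genes, mrna_expr, mirna_expr, manifest, mirna_id,
                            support = NULL, sites = NULL, pseudo = 0.5) {
  genes <- toupper(as.character(genes))
  if (!length(genes)) {
    return(data.frame(gene = character(), support_count = integer(),
                      n_seed_sites = integer(), peak_expression = numeric(),
                      anticorr = numeric(), stringsAsFactors = FALSE))
  }
  gm <- mrna_expr$values
  rownames(gm) <- toupper(rownames(gm))
  missing <- setdiff(genes, rownames(gm))
  if (length(missing))
    stop("no expression for gene(s): ", paste(missing, collapse = ", "))
  mm <- mirna_expr$values
  rownames(mm) <- toupper(rownames(mm))
  if (!toupper(mirna_id) %in% rownames(mm))
    stop("no expression for miRNA ", mirna_id)
  mir_ratios <- transition_ratios(mm[toupper(mirna_id), , drop = FALSE],
                                  manifest, "miRNA", pseudo)[1, ]
  gene_ratios <- transition_ratios(gm[genes, , drop = FALSE],
                                   manifest, "mRNA", pseudo)
  anticorr <- apply(gene_ratios, 1, function(g) {
    if (length(g) < 2 || stats::sd(g) == 0 || stats::sd(mir_ratios) == 0)
      return(NA_real_)
    stats::cor(g, mir_ratios)
  })
  peak <- apply(gm[genes, , drop = FALSE], 1, max)
  sup <- if (is.null(support)) rep(NA_integer_, length(genes))
  else as.integer(support[genes])
  nsites <- if (is.null(sites)) rep(NA_integer_, length(genes))
  else as.integer(table(factor(sites$utr_id, levels = genes)))
  out <- data.frame(gene = genes, support_count = sup, n_seed_sites = nsites,
                    peak_expression = unname(peak),
                    anticorr = unname(anticorr), stringsAsFactors = FALSE)
  ord <- order(-out$peak_expression, out$anticorr, out$gene, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-patient stage-transition log2 ratios for each feature row.
# Columns ordered by (patient, transition): normal->OLP then OLP->OSCC.
transition_ratios <- function(values, manifest, assay, pseudo = 0.5) {
  man <- manifest[manifest$assay == assay, , drop = FALSE]
  patients <- sort(unique(man$patient_id))
  cols <- lapply(patients, function(p) {
    pm <- man[man$patient_id == p, , drop = FALSE]
    sid <- stats::setNames(pm$sample_id, as.character(pm$stage))[STAGES]
    if (any(is.na(sid)))
      stop("patient ", p, " (", assay, ") lacks a stage sample")
    cbind(log2_ratio(values[, sid[2]], values[, sid[1]], pseudo),
          log2_ratio(values[, sid[3]], values[, sid[2]], pseudo))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(t(outer(patients, c("t1", "t2"), paste,
                                     sep = "_")))
  out
}

#' Intersect up-regulated genes with a regulator's target list
#'
#' Downstream-effector search: which screen-recovered up-regulated genes
#' are known targets of a candidate transcription factor (the regulator
#' list is consumed as a plain gene list, e.g. a pathway-tool export).
#' @param upregulated,regulator_targets [gene_list()]s or character vectors.
#' @export
downstream_intersection <- function(upregulated, regulator_targets) {
  intersect_gene_lists(upregulated, regulator_targets)
}
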