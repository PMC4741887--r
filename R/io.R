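#' @keywords internal
"_PACKAGE"

STAGES <- c("normal", "OLP", "OSCC")
ASSAYS <- c("miRNA", "mRNA")

#' Construct and validate a sample manifest
#'
#' A manifest maps every sequenced sample to its patient, tissue stage and
#' assay. Stages follow the fixed progression order
#' normal < OLP < OSCC (oral lichen planus, oral squamous cell carcinoma).
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `stage`
#'   (one of `"normal"`, `"OLP"`, `"OSCC"`) and `assay` (`"miRNA"` or
#'   `"mRNA"`).
#' @return A validated `sample_manifest` data.frame; `stage` is an ordered
#'   factor.
#' @export
sample_manifest <- function(df) {
  req <- c("sample_id", "patient_id", "stage", "assay")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$stage), STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(STAGES, collapse = ", "), ")")
  bad <- setdiff(unique(df$assay), ASSAYS)
  if (length(bad))
    stop("unknown assay(s): ", paste(bad, collapse = ", "))
  key <- paste(df$patient_id, df$assay, df$stage)
  if (anyDuplicated(key))
    stop("a (patient, assay) group has more than one sample for a stage: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df$stage <- factor(df$stage, levels = STAGES, ordered = TRUE)
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Read a sample manifest from a tab-separated file
#'
#' @param path TSV with header columns sample_id, patient_id, stage, assay.
#' @return A `sample_manifest` (see [sample_manifest()]).
#' @export
read_sample_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_manifest(df)
}

#' @export
write_sample_manifest <- function(manifest, path) {
  out <- as.data.frame(manifest)
  out$stage <- as.character(out$stage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a count matrix
#'
#' Raw read/tag counts, features x samples, with per-sample library sizes
#' (total mapped tags, the N of RPKM) and, for mRNA, per-feature transcript
#' lengths in base pairs (the L of RPKM).
#'
#' @param counts non-negative integer matrix with feature row names and
#'   sample column names.
#' @param library_sizes named positive numeric, one per sample; defaults to
#'   the column sums of `counts`.
#' @param feature_lengths optional named positive integer, one per feature;
#'   required for RPKM normalization.
#' @return A `count_matrix` object (list with elements `counts`,
#'   `library_sizes`, `feature_lengths`).
#' @export
count_matrix <- function(counts, library_sizes = NULL, feature_lengths = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no features")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
  } else {
    library_sizes <- library_sizes[colnames(counts)]
    if (any(is.na(library_sizes)))
      stop("library_sizes missing for sample(s): ",
           paste(colnames(counts)[is.na(library_sizes)], collapse = ", "))
    if (any(library_sizes < 1)) stop("library sizes must be >= 1")
    if (any(library_sizes < colSums(counts)))
      stop("library size smaller than column sum for sample(s): ",
           paste(colnames(counts)[library_sizes < colSums(counts)],
                 collapse = ", "))
  }
  if (!is.null(feature_lengths)) {
    feature_lengths <- feature_lengths[rownames(counts)]
    if (any(is.na(feature_lengths)) || any(feature_lengths < 1))
      stop("feature lengths must be positive and cover every feature")
  }
  structure(list(counts = counts, library_sizes = library_sizes,
                 feature_lengths = feature_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("library sizes:", paste(format(x$library_sizes, big.mark = ","),
                              collapse = ", "), "\n")
  if (!is.null(x$feature_lengths)) cat("feature lengths present (RPKM-ready)\n")
  invisible(x)
}

#' Read a count table from a tab-separated file
#'
#' Dialect: header row of sample ids, first column `feature_id`, optional
#' `length` column (transcript length in bp). Library sizes come from an
#' optional two-column sidecar TSV (sample_id, library_size) and default to
#' the column sums.
#'
#' @param path counts TSV.
#' @param manifest optional [sample_manifest()]; every sample column in the
#'   file must appear in it.
#' @param library_sizes_path optional sidecar TSV path.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, manifest = NULL, library_sizes_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no features in ", path)
  if (names(df)[1] != "feature_id")
    stop("first column must be 'feature_id', found '", names(df)[1], "'")
  lengths <- NULL
  if ("length" %in% names(df)) {
    lengths <- df$length
    df$length <- NULL
  }
  sample_cols <- setdiff(names(df), "feature_id")
  if (!length(sample_cols)) stop("no sample columns in ", path)
  if (!is.null(manifest)) {
    unknown <- setdiff(sample_cols, manifest$sample_id)
    if (length(unknown))
      stop("sample(s) in file absent from manifest: ",
           paste(unknown, collapse = ", "))
  }
  m <- as.matrix(df[sample_cols])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at feature '",
         df$feature_id[bad[1, 1]], "', sample '", sample_cols[bad[1, 2]], "'")
  rownames(m) <- df$feature_id
  ls <- NULL
  if (!is.null(library_sizes_path)) {
    sc <- utils::read.delim(library_sizes_path, stringsAsFactors = FALSE)
    ls <- stats::setNames(as.numeric(sc[[2]]), sc[[1]])
  }
  if (!is.null(lengths)) lengths <- stats::setNames(as.integer(lengths),
                                                    df$feature_id)
  count_matrix(m, library_sizes = ls, feature_lengths = lengths)
}

#' Write a count table (round-trips with [read_count_table()])
#' @export
write_count_table <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), check.names = FALSE)
  if (!is.null(cm$feature_lengths)) df$length <- cm$feature_lengths
  df <- cbind(df, as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Accepts the alphabet A, C, G, T, U, N (case-insensitive). Sequences are
#' normalized to uppercase DNA (U -> T) so that miRNA (RNA) and 3'-UTR (DNA)
#' sequences live on one alphabet for seed matching; whether a record
#' originally used U is recorded in the `"was_rna"` attribute.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  bad <- regexpr("[^ACGTUN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i])
  }
  was_rna <- grepl("U", seqs, fixed = TRUE)
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  attr(seqs, "was_rna") <- stats::setNames(was_rna, ids)
  seqs
}

#' Write named sequences to FASTA
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a gene list
#'
#' Gene symbols are compared case-insensitively: symbols are uppercased and
#' deduplicated, and kept sorted for order-stable output.
#'
#' @param genes character vector of gene symbols.
#' @param name optional list name.
#' @return Sorted, unique, uppercase character vector of class `gene_list`.
#' @export
gene_list <- function(genes = character(), name = NULL) {
  genes <- sort(unique(toupper(as.character(genes))))
  structure(genes, class = "gene_list", name = name)
}

#' @export
print.gene_list <- function(x, ...) {
  nm <- attr(x, "name")
  cat("gene_list", if (!is.null(nm)) paste0("'", nm, "'"), "with", length(x),
      "gene(s)\n")
  if (length(x)) print(unclass(x)[seq_len(min(10, length(x)))])
  invisible(x)
}

#' Read a gene list (one symbol per line, optional `gene` header)
#' @export
read_gene_list <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[1]), "gene"))
    lines <- lines[-1]
  if (!length(lines)) warning("empty gene list: ", path)
  gene_list(lines, name = if (is.null(name))
    tools::file_path_sans_ext(basename(path)) else name)
}

#' Write a gene list (sorted, one symbol per line, `gene` header)
#' @export
write_gene_list <- function(genes, path) {
  writeLines(c("gene", as.character(genes)), path)
  invisible(path)
}

#' Intersect two gene lists case-insensitively
#' @export
intersect_gene_lists <- function(a, b) {
  gene_list(intersect(toupper(as.character(a)), toupper(as.character(b))))
}
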