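# Small in-code fixtures shared across tests.

toy_manifest <- function(patients = "P001", assay = "miRNA") {
  rows <- expand.grid(stage = c("normal", "OLP", "OSCC"),
                      patient_id = patients, stringsAsFactors = FALSE)
  sample_manifest(data.frame(
    sample_id = paste(rows$patient_id, rows$stage, assay, sep = "_"),
    patient_id = rows$patient_id, stage = rows$stage, assay = assay,
    stringsAsFactors = FALSE))
}

# Counts with chosen per-million expression at fixed depth, one patient.
toy_counts <- function(values_by_stage, depth = 1e6, assay = "miRNA",
                       patients = "P001") {
  n <- nrow(values_by_stage)
  ids <- rownames(values_by_stage)
  if (is.null(ids)) ids <- sprintf("F%03d", seq_len(n))
  man <- toy_manifest(patients, assay)
  counts <- matrix(0, n, nrow(man), dimnames = list(ids, man$sample_id))
  for (i in seq_len(nrow(man)))
    counts[, i] <- values_by_stage[, as.character(man$stage[i])]
  count_matrix(counts, library_sizes = stats::setNames(rep(depth, nrow(man)),
                                                       man$sample_id))
}

mir375_seq <- function() {
  fa <- read_fasta(system.file("extdata", "mir375.fa", package = "mirprog"))
  unname(fa[1])
}

# Synthetic stand-in supplementary lists with the cascade's published
# cardinalities: 1088 predicted targets and 932 up-regulated genes sharing
# exactly 25 genes (among them the four UTR-confirmed candidates), plus a
# 50-gene regulator-target list sharing exactly KLF5 and BIRC5 with the
# up-regulated set.
synthetic_sd_lists <- function() {
  confirmed <- c("KLF5", "RTF1", "PDPK1", "SLC7A11")
  shared <- c(confirmed, sprintf("SHARED%02d", 1:21))          # 25
  predicted <- c(shared, sprintf("PRED%04d", 1:1063))          # 1088
  upreg <- c(shared, "BIRC5", sprintf("UP%04d", 1:906))        # 932
  regulator <- c("KLF5", "BIRC5", sprintf("REG%02d", 1:48))    # 50
  list(predicted = gene_list(predicted, "predicted"),
       upregulated = gene_list(upreg, "upregulated"),
       regulator = gene_list(regulator, "regulator"),
       confirmed = confirmed)
}
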