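test_that("seed-match strings derive from the seed reverse complement", {
  m <- derive_seed_matches(mir375_seq())
  expect_equal(m[["7mer-A1"]], "GAACAAA")
  expect_equal(m[["6mer"]], "GAACAA")
  expect_equal(m[["7mer-m8"]], "CGAACAA")
  expect_equal(m[["8mer"]], "CGAACAAA")

  # against an independent reverse-complement oracle
  seq <- mir375_seq()
  rc <- function(z) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(z)))
  expect_equal(m[["6mer"]], rc(substr(seq, 2, 7)))
  expect_equal(m[["7mer-m8"]], rc(substr(seq, 2, 8)))

  hp <- derive_seed_matches("UUUUUUUU")
  expect_equal(unname(hp[c("6mer", "8mer")]), c("AAAAAA", "AAAAAAAA"))
  expect_error(derive_seed_matches("ACGUACG"), "at least 8")
})

test_that("scan_utr reports sites with 1-based inclusive coordinates", {
  mir <- mir375_seq()
  sites <- scan_utr("u1", paste0("TTT", "GAACAAA", "TTT"), mir)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$start, 4)
  expect_equal(sites$end, 10)
  expect_equal(sites$site_class, "7mer-A1")
  expect_equal(sites$matched_seq, "GAACAAA")

  expect_equal(nrow(scan_utr("u2", "TTTTTTTTTT", mir)), 0)

  # nested matches collapse to the most specific class
  sites <- scan_utr("u3", "CGAACAAA", mir)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_class, "8mer")
  expect_equal(c(sites$start, sites$end), c(1, 8))
})

test_that("matched_seq always equals the UTR substring at its coordinates", {
  set.seed(21)
  mir <- mir375_seq()
  for (i in 1:20) {
    utr <- random_dna_str(300)
    utr <- paste0(utr, "GAACAAA", random_dna_str(50))
    sites <- scan_utr("u", utr, mir)
    expect_gte(nrow(sites), 1)
    expect_equal(substring(utr, sites$start, sites$end), sites$matched_seq)
    expect_equal(nchar(sites$matched_seq),
                 unname(c("6mer" = 6, "7mer-A1" = 7, "7mer-m8" = 7,
                          "8mer" = 8)[sites$site_class]))
  }
})

test_that("scan_utr agrees with the exhaustive position-by-position oracle", {
  set.seed(99)
  for (i in 1:200) {
    mir <- random_dna_str(22)
    utr <- random_dna_str(sample(50:500, 1))
    # spike in matches so agreement is tested on non-empty cases too
    if (i %% 3 == 0) {
      m <- derive_seed_matches(mir)
      pos <- sample(1:(nchar(utr) - 8), 1)
      cls <- sample(names(m), 1)
      substr(utr, pos, pos + nchar(m[[cls]]) - 1) <- m[[cls]]
    }
    got <- scan_utr("u", utr, mir)
    want <- oracle_scan(utr, mir)
    expect_equal(got[c("start", "end", "site_class", "matched_seq")],
                 want, ignore_attr = TRUE)
  }
})

test_that("sites live on the sense strand only", {
  set.seed(4)
  mir <- mir375_seq()
  utr <- paste0(random_dna_str(100), "CGAACAAA", random_dna_str(100))
  fwd <- scan_utr("u", utr, mir)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(utr)))
  rev <- scan_utr("u", rc, mir)
  expect_gte(nrow(fwd), 1)
  expect_false(nrow(rev) == nrow(fwd) &&
                 all(rev$site_class == fwd$site_class))
})

test_that("consensus voting keeps genes supported by at least k tools", {
  sets <- list(
    prediction_set("t1", "mir-x", c("A", "B", "C")),
    prediction_set("t2", "mir-x", c("A", "B")),
    prediction_set("t3", "mir-x", c("A", "B", "D")),
    prediction_set("t4", "mir-x", "A"),
    prediction_set("t5", "mir-x", "E"),
    prediction_set("t6", "mir-x", "E"))
  expect_equal(as.character(consensus_targets(sets, k = 3)), c("A", "B"))
  expect_equal(attr(consensus_targets(sets, k = 3), "support")[["A"]], 4L)
  expect_equal(as.character(consensus_targets(sets, k = 1)),
               sort(c("A", "B", "C", "D", "E")))
  # monotone decreasing in k
  for (k in 1:5)
    expect_true(all(as.character(consensus_targets(sets, k + 1)) %in%
                      as.character(consensus_targets(sets, k))))
  expect_error(consensus_targets(list(
    prediction_set("t1", "mir-x", "A"),
    prediction_set("t2", "mir-y", "A"))), "mix")
  expect_error(consensus_targets(list(
    prediction_set("t1", "mir-x", "A"),
    prediction_set("t1", "mir-x", "B"))), "duplicate tool")
})

test_that("intersections are case-insensitive set operations", {
  expect_equal(as.character(intersect_upregulated(c("A", "B", "C"),
                                                  c("B", "C", "D"))),
               c("B", "C"))
  expect_length(intersect_upregulated(c("A"), c("B")), 0)
  expect_equal(as.character(intersect_upregulated("KLF5", "klf5")), "KLF5")
  gl <- gene_list(c("KLF5", "BIRC5", "X"))
  expect_equal(as.character(downstream_intersection(gl, gl)),
               as.character(gl))
})

test_that("the packaged regulator list intersects to the two known genes", {
  reg <- read_gene_list(system.file(
    "extdata", "regulator_targets_klf5_synthetic.tsv", package = "mirprog"))
  expect_length(reg, 50)
  up <- gene_list(c("KLF5", "BIRC5", "GENEX", "GENEY"))
  expect_equal(as.character(downstream_intersection(up, reg)),
               c("BIRC5", "KLF5"))
  expect_length(downstream_intersection(gene_list(character()), reg), 0)
})

test_that("the seed filter keeps >=7mer sites and warns on missing UTRs", {
  mir <- mir375_seq()
  utrs <- c(WITH7 = paste0("TT", "GAACAAA", "TT"),
            ONLY6 = paste0("TT", "GAACAAT", "TT"),
            NONE = "TTTTTTTTTTT")
  kept <- seed_filter(c("with7", "only6", "none"), utrs, mir)
  expect_equal(as.character(kept), "WITH7")
  # a 6mer suffices when the floor is lowered
  kept6 <- seed_filter(c("with7", "only6"), utrs, mir, min_class = "6mer")
  expect_setequal(as.character(kept6), c("WITH7", "ONLY6"))
  expect_warning(seed_filter(c("with7", "ghost"), utrs, mir), "GHOST")
})

test_that("candidates rank by abundance with anti-correlation tie-break", {
  man <- toy_manifest(c("P001", "P002"), assay = "mRNA")
  man_mir <- toy_manifest(c("P001", "P002"), assay = "miRNA")
  manifest <- rbind(as.data.frame(man), as.data.frame(man_mir))
  manifest$stage <- as.character(manifest$stage)
  manifest <- sample_manifest(manifest)
  stage_idx <- function(m) match(as.character(m$stage),
                                 c("normal", "OLP", "OSCC"))
  # miRNA falls 8,4,1 per stage; ANTI rises mirroring it, FLAT is constant
  mir_counts <- matrix(0, 1, nrow(man_mir),
                       dimnames = list("MIRX", man_mir$sample_id))
  mir_counts[1, ] <- c(800, 400, 100)[stage_idx(man_mir)]
  gene_counts <- matrix(0, 2, nrow(man),
                        dimnames = list(c("ANTI", "FLAT"), man$sample_id))
  gene_counts["ANTI", ] <- c(100, 200, 800)[stage_idx(man)]
  gene_counts["FLAT", ] <- 900
  depths <- function(m) stats::setNames(rep(1e6, nrow(m)), m$sample_id)
  mrna_expr <- compute_per_million(count_matrix(gene_counts, depths(man)))
  mirna_expr <- compute_per_million(count_matrix(mir_counts, depths(man_mir)))

  ranked <- rank_candidates(c("ANTI", "FLAT"), mrna_expr, mirna_expr,
                            manifest, "MIRX")
  expect_equal(ranked$anticorr[ranked$gene == "ANTI"], -1)
  expect_true(is.na(ranked$anticorr[ranked$gene == "FLAT"]))
  # FLAT has the higher peak expression and therefore ranks first
  expect_equal(ranked$gene, c("FLAT", "ANTI"))
})
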