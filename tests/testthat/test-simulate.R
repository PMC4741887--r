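test_that("simulation is a pure function of its seed", {
  cfg <- sim_config(n_mirnas = 50, n_genes = 40, n_planted_mirnas = 3,
                    rng_seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$mirna$counts, b$mirna$counts)
  expect_identical(a$mrna$counts, b$mrna$counts)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg
  cfg2$rng_seed <- 8
  expect_false(identical(simulate_counts(cfg2)$mirna$counts,
                         a$mirna$counts))

  ua <- simulate_utrs(cfg, a$truth)
  ub <- simulate_utrs(cfg, a$truth)
  expect_identical(ua, ub)
  va <- simulate_validation_tables(cfg)
  vb <- simulate_validation_tables(cfg)
  expect_identical(va, vb)
})

test_that("a null Poisson configuration gives flat per-million expression", {
  cfg <- sim_config(n_mirnas = 100, n_genes = 10, n_planted_mirnas = 0,
                    n_planted_targets_per_mirna = 0, dispersion = 0,
                    baseline_sdlog = 0.2, patient_effect_sd = 0,
                    rng_seed = 3)
  sim <- simulate_counts(cfg)
  pm <- compute_per_million(sim$mirna)$values
  rel_sd <- apply(pm, 1, stats::sd) / rowMeans(pm)
  expect_lt(stats::median(rel_sd), 0.05)
})

test_that("planted miRNAs drop by the configured geometric factor", {
  cfg <- sim_config(n_mirnas = 200, n_genes = 10, n_planted_mirnas = 10,
                    n_planted_targets_per_mirna = 0, dispersion = 0.05,
                    rng_seed = 12)
  sim <- simulate_counts(cfg)
  pm <- compute_per_million(sim$mirna)$values
  man <- sim$manifest[sim$manifest$assay == "miRNA", ]
  norm <- man$sample_id[man$stage == "normal"]
  oscc <- man$sample_id[man$stage == "OSCC"]
  ratio <- rowMeans(pm[sim$truth$planted_mirnas, oscc, drop = FALSE]) /
    rowMeans(pm[sim$truth$planted_mirnas, norm, drop = FALSE])
  # configured delta of -1.5 per stage: expect about 2^-3 overall
  expect_equal(mean(log2(ratio)), -3, tolerance = 0.5)
})

test_that("UTRs carry the planted site and decoys are clean", {
  cfg <- sim_config(n_mirnas = 40, n_genes = 60, n_planted_mirnas = 4,
                    rng_seed = 23)
  sim <- simulate_counts(cfg)
  ub <- simulate_utrs(cfg, sim$truth)
  lens <- nchar(ub$utrs)
  expect_true(all(lens >= cfg$utr_length_range[1] &
                    lens <= cfg$utr_length_range[2]))
  for (i in seq_len(nrow(ub$site_positions))) {
    rec <- ub$site_positions[i, ]
    m <- derive_seed_matches(sim$truth$mirna_seqs[[rec$mirna]])
    expect_equal(substring(ub$utrs[[rec$gene]], rec$start, rec$end),
                 unname(m[[rec$site_class]]))
  }
  decoys <- setdiff(names(ub$utrs), sim$truth$planted_pairs$gene)
  for (m in sim$truth$planted_mirnas) {
    sites <- scan_utrs(ub$utrs[decoys], sim$truth$mirna_seqs[[m]], m)
    expect_false(any(sites$site_class %in% c("7mer-A1", "7mer-m8", "8mer")))
  }
})

test_that("prediction sets follow the sensitivity and false-positive rates", {
  cfg <- sim_config(n_mirnas = 20, n_genes = 50, n_planted_mirnas = 2,
                    tool_sensitivity = 1, tool_fp_rate = 0, rng_seed = 31)
  sim <- simulate_counts(cfg)
  preds <- simulate_prediction_sets(cfg, sim$truth)
  for (m in names(preds)) {
    truth_set <- gene_list(
      sim$truth$planted_pairs$gene[sim$truth$planted_pairs$mirna == m])
    for (s in preds[[m]])
      expect_equal(as.character(s$genes), as.character(truth_set))
  }

  cfg0 <- sim_config(n_mirnas = 20, n_genes = 50, n_planted_mirnas = 2,
                     tool_sensitivity = 0, tool_fp_rate = 0.05, rng_seed = 32)
  sim0 <- simulate_counts(cfg0)
  preds0 <- simulate_prediction_sets(cfg0, sim0$truth)
  for (m in names(preds0)) {
    cons <- consensus_targets(preds0[[m]], k = 3)
    expect_false(any(sim0$truth$planted_pairs$gene %in% as.character(cons)))
  }

  # support of a true target is binomial(n_tools, sensitivity)
  support <- integer()
  for (s in 1:200) {
    cfgi <- sim_config(n_mirnas = 20, n_genes = 30, n_planted_mirnas = 1,
                       n_planted_targets_per_mirna = 1, rng_seed = 4000 + s)
    simi <- simulate_counts(cfgi)
    pr <- simulate_prediction_sets(cfgi, simi$truth)
    g <- simi$truth$planted_pairs$gene[1]
    support <- c(support, sum(vapply(pr[[1]], function(x)
      g %in% as.character(x$genes), logical(1))))
  }
  expected <- 6 * 0.9
  se <- sqrt(6 * 0.9 * 0.1 / 200)
  expect_lt(abs(mean(support) - expected), 3 * se)
})

test_that("validation tables recover the planted fold change", {
  cfg <- sim_config(n_validation = 100, ct_noise_sd = 0, rng_seed = 6)
  tabs <- simulate_validation_tables(cfg)
  case <- tabs$ct[tabs$ct$group == "case", ]
  ctrl <- tabs$ct[tabs$ct$group == "control", ]
  expect_equal(ddct_fold(case, ctrl), rep(4, 100))

  cfgn <- sim_config(n_validation = 100, ct_noise_sd = 0.25, rng_seed = 6)
  tabsn <- simulate_validation_tables(cfgn)
  casen <- tabsn$ct[tabsn$ct$group == "case", ]
  ctrln <- tabsn$ct[tabsn$ct$group == "control", ]
  expect_equal(mean(ddct_fold(casen, ctrln)), 4, tolerance = 0.25 * 4 / 4)
})

test_that("generated files satisfy every reader contract", {
  cfg <- sim_config(n_mirnas = 30, n_genes = 40, n_planted_mirnas = 3,
                    rng_seed = 17)
  dir <- withr::local_tempdir()
  sim <- simulate_all(cfg, out_dir = dir)
  man <- read_sample_manifest(file.path(dir, "manifest.tsv"))
  mir <- read_count_table(file.path(dir, "mirna_counts.tsv"), man)
  mrna <- read_count_table(file.path(dir, "mrna_counts.tsv"), man)
  expect_equal(mir$counts, sim$mirna$counts)
  expect_equal(mrna$counts, sim$mrna$counts)
  expect_equal(mrna$feature_lengths, sim$mrna$feature_lengths)
  utrs <- read_fasta(file.path(dir, "utrs.fa"))
  expect_equal(as.character(utrs), unname(sim$utrs))
  expect_true(file.exists(file.path(dir, "truth.json")))
  pred_files <- list.files(file.path(dir, "predictions"))
  expect_length(pred_files, cfg$n_planted_mirnas * cfg$n_tools)
})
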