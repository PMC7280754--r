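cfg <- simulation_config(rng_seed = 11L)

test_that("repertoire generation is deterministic and honours shift probabilities", {
  r1 <- generate_isomir_repertoire(cfg)
  r2 <- generate_isomir_repertoire(cfg)
  expect_identical(r1, r2)
  # canonical-only when both shift probabilities are zero
  quiet <- simulation_config(rng_seed = 2L, prob_shift5 = 0, prob_shift3 = 0)
  r0 <- generate_isomir_repertoire(quiet)
  expect_true(all(r0$templates$shift5 == 0L & r0$templates$shift3 == 0L))
  # sequences always match their spans, in transcript orientation
  for (i in seq_len(nrow(r1$templates))) {
    sp <- parse_isomir_coordinate(r1$templates$coordinate[i])
    expect_equal(nchar(r1$templates$sequence[i]), span_length(sp))
  }
  # binomial tally: with many templates the 3'-variant fraction approaches
  # prob_shift3 and the 5' fraction prob_shift5
  big <- simulation_config(rng_seed = 3L, n_loci = 2000L,
                           isomirs_per_locus = 5, prob_shift5 = 0.2,
                           prob_shift3 = 0.6)
  tpl <- generate_isomir_repertoire(big)$templates
  extra <- tpl[grepl("iso0[2-9]$|iso[1-9][0-9]$", tpl$isomir_id), ]
  expect_gt(nrow(extra), 8000)
  expect_lt(abs(mean(extra$shift3 != 0L) - 0.6), 0.02)
  expect_lt(abs(mean(extra$shift5 != 0L) - 0.2), 0.02)
})

test_that("count generation plants exact group mean ratios and realistic dispersion", {
  # near-Poisson limit: variance ~ mean
  tiny <- simulation_config(rng_seed = 5L, nb_dispersion = 1e-8,
                            n_tumor = 5000L, n_normal = 5000L,
                            nb_mean_log_range = log(c(500, 500)))
  cm <- generate_count_matrix("f1", tiny)
  sf <- attr(cm, "size_factors_true")
  # Pearson residuals against the known per-sample Poisson means have unit
  # variance in the dispersion -> 0 limit (with dispersion 0.1 this
  # variance would be ~1 + 0.1 * 500 = 51)
  z <- (cm$counts[1, ] - 500 * sf) / sqrt(500 * sf)
  expect_lt(abs(var(z) - 1), 0.1)

  # planted log2FC = 2.5 recovered in the empirical group ratio
  feats <- sprintf("f%02d", 1:50)
  planted <- data.frame(feature_id = feats, log2FC = 2.5)
  cfg2 <- simulation_config(rng_seed = 6L, n_tumor = 30L, n_normal = 30L,
                            nb_mean_log_range = log(c(500, 500)),
                            nb_dispersion = 0.1)
  cm2 <- generate_count_matrix(feats, cfg2, planted_de = planted)
  sf2 <- attr(cm2, "size_factors_true")
  norm <- sweep(cm2$counts, 2, sf2, "/")
  ratio <- log2(rowMeans(norm[, cm2$groups == "tumor"]) /
                  rowMeans(norm[, cm2$groups == "normal"]))
  expect_lt(abs(mean(ratio) - 2.5), 0.3)

  # null: no planted effects -> group means equal within sampling error
  cm3 <- generate_count_matrix(feats, cfg2)
  norm3 <- sweep(cm3$counts, 2, attr(cm3, "size_factors_true"), "/")
  ratio3 <- log2(rowMeans(norm3[, cm3$groups == "tumor"]) /
                   rowMeans(norm3[, cm3$groups == "normal"]))
  expect_lt(abs(mean(ratio3)), 0.1)

  expect_error(generate_count_matrix(feats, cfg2,
                                     planted_de = data.frame(
                                       feature_id = "nope", log2FC = 1)),
               "not among")
})

test_that("UTR collections contain exactly the planted sites and nothing else", {
  seeds <- c("GAGGUAG", "AGGUAGU", "CCAUAAA")
  small <- simulation_config(rng_seed = 7L, n_genes = 50L, utr_length = 500L)
  # no plants: rejection guarantees zero matches for any monitored seed
  u0 <- generate_utr_collection(small, monitored_seeds = seeds)
  for (sd in seeds)
    expect_equal(nrow(scan_sites(sd, u0$utrs)$sites), 0L)

  # planted sites: brute-force oracle scan agrees with the ledger exactly
  plants <- data.frame(
    gene_id = c("gene001", "gene002", "gene002", "gene010"),
    seed = c("GAGGUAG", "AGGUAGU", "GAGGUAG", "CCAUAAA"),
    site_type = c("8mer", "7mer-m8", "7mer-A1", "8mer"),
    stringsAsFactors = FALSE)
  u1 <- generate_utr_collection(small, monitored_seeds = seeds,
                                planted_sites = plants)
  expect_equal(nrow(u1$ledger), nrow(plants))
  found <- do.call(rbind, lapply(seeds, function(sd) {
    hits <- do.call(rbind, lapply(names(u1$utrs), function(g) {
      s <- oracle_scan_one(sd, u1$utrs[[g]])
      if (nrow(s)) cbind(gene_id = g, seed = sd, s) else NULL
    }))
    hits
  }))
  expect_equal(nrow(found), nrow(u1$ledger))
  key <- function(d) sort(paste(d$gene_id, d$seed, d$site_type, d$utr_start))
  expect_equal(key(found), key(u1$ledger))
  expect_error(generate_utr_collection(small, seeds,
                                       planted_sites = data.frame(
                                         gene_id = "gene001", seed = "AAAAAAA",
                                         site_type = "8mer")),
               "not monitored")
})

test_that("copula coupling hits the target Spearman correlation", {
  cfg4 <- simulation_config(rng_seed = 8L, n_tumor = 30L, n_normal = 30L)
  feats <- sprintf("iso%02d", 1:20)
  iso_cm <- generate_count_matrix(feats, cfg4)
  genes <- sprintf("gene%03d", 1:60)
  pairs <- data.frame(isomir_id = feats, gene_id = genes[1:20], rho = -0.6)
  mrna <- generate_coupled_mrna_counts(iso_cm, cfg4, genes,
                                       planted_pairs = pairs)
  iso_norm <- sweep(iso_cm$counts, 2, size_factors(iso_cm), "/")
  mrna_norm <- sweep(mrna$counts, 2, size_factors(mrna), "/")
  rhos <- vapply(seq_len(nrow(pairs)), function(j)
    cor(rank(iso_norm[pairs$isomir_id[j], ]),
        rank(mrna_norm[pairs$gene_id[j], ])), numeric(1))
  expect_lt(abs(mean(rhos) - (-0.6)), 0.15)
  # decoys stay near zero: |rho| < 0.3 for at least 95% of decoy pairs
  decoy_rhos <- vapply(21:60, function(j)
    cor(rank(iso_norm[feats[1 + (j %% 20)], ]), rank(mrna_norm[genes[j], ])),
    numeric(1))
  expect_gte(mean(abs(decoy_rhos) < 0.3), 0.95)
  expect_identical(mrna,
                   generate_coupled_mrna_counts(iso_cm, cfg4, genes,
                                                planted_pairs = pairs))
  expect_error(generate_coupled_mrna_counts(iso_cm, cfg4, genes,
                                            planted_pairs = data.frame(
                                              isomir_id = "zzz",
                                              gene_id = genes[1], rho = -0.5)),
               "unknown isomiRs")
})

test_that("survival and drug generators plant the configured effects", {
  expr <- setNames(c(rnorm(50, 10), rnorm(50, 20)), sprintf("s%03d", 1:100))
  surv <- generate_survival_data(expr, cfg)
  expect_equal(nrow(surv), 100L)
  expect_true(all(surv$time > 0))
  # hazard ratio 3: the high group fails faster
  med <- tapply(surv$time, surv$group, median)
  expect_lt(med["high"], med["low"])
  # censoring rate 0: every event observed
  cfg_nc <- simulation_config(rng_seed = 12L, censoring_rate = 0)
  expect_true(all(generate_survival_data(expr, cfg_nc)$event == 1L))

  groups <- setNames(rep(c("shifted", "comparison"), each = 40),
                     sprintf("CL%02d", 1:80))
  drug <- generate_drug_response_data(groups, cfg)
  diff <- mean(drug$sensitivity[drug$group == "shifted"]) -
    mean(drug$sensitivity[drug$group == "comparison"])
  expect_lt(abs(diff - 0.2), 0.05)
  expect_true(all(drug$sensitivity >= 0 & drug$sensitivity <= 1))
  # null effect: group means equal within sampling error
  cfg0 <- simulation_config(rng_seed = 13L, drug_effect = 0)
  d0 <- generate_drug_response_data(groups, cfg0)
  expect_lt(abs(mean(d0$sensitivity[d0$group == "shifted"]) -
                  mean(d0$sensitivity[d0$group == "comparison"])), 0.05)
  expect_identical(drug, generate_drug_response_data(groups, cfg))
})

test_that("the assembled dataset is deterministic and its files byte-identical", {
  small <- simulation_config(rng_seed = 21L, n_loci = 4L, n_genes = 60L,
                             n_tumor = 20L, n_normal = 20L,
                             n_planted_background = 6L)
  d1 <- simulate_dataset(small)
  d2 <- simulate_dataset(small)
  expect_identical(d1$isomir_counts$counts, d2$isomir_counts$counts)
  expect_identical(d1$utrs, d2$utrs)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  # the ledger describes real structure: planted sites reference monitored
  # seeds and planted DE features exist in the count matrix
  expect_true(all(d1$ledger$planted_de_isomir$feature_id %in%
                    rownames(d1$isomir_counts$counts)))
  expect_true(all(d1$ledger$planted_sites$gene_id %in% names(d1$utrs)))
})
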