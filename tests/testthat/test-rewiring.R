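test_that("opposite-expression screening keeps only significant opposite-direction target pairs", {
  iso <- data.frame(feature_id = c("v-up", "v-dn", "v-ns"),
                    direction = c("up", "down", "ns"),
                    significant = c(TRUE, TRUE, FALSE))
  genes <- data.frame(feature_id = c("g-dn", "g-up", "g-ns"),
                      direction = c("down", "up", "ns"),
                      significant = c(TRUE, TRUE, FALSE))
  sets <- list(
    "v-up" = structure(list(seed_label = "v-up",
                            genes = c("g-dn", "g-up", "g-ns", "g-other")),
                       class = "target_set"),
    "v-dn" = structure(list(seed_label = "v-dn", genes = c("g-up", "g-dn")),
                       class = "target_set"))
  cand <- screen_opposite_pairs(iso, genes, sets)
  expect_equal(cand[cand$seed_label == "v-up", "gene_id"], "g-dn")
  expect_equal(cand[cand$seed_label == "v-dn", "gene_id"], "g-up")
  # non-target genes and ns features never appear
  expect_false("g-other" %in% cand$gene_id)
  expect_false("v-ns" %in% cand$seed_label)
})

test_that("correlation screen enforces rho < 0, FDR and the 50-per-group rule", {
  withr::with_seed(41, {
    n <- 120
    samples <- sprintf("s%03d", 1:n)
    groups <- setNames(rep(c("tumor", "normal"), each = n / 2), samples)
    x <- matrix(rnorm(n), 1, dimnames = list("v1", samples))
    down <- -0.8 * x[1, ] + rnorm(n, sd = 0.5)
    up <- 0.8 * x[1, ] + rnorm(n, sd = 0.5)
    noise <- rnorm(n)
    y <- rbind(gneg = down, gpos = up, gnull = noise)
    colnames(y) <- samples
    cand <- data.frame(seed_label = "v1", gene_id = c("gneg", "gpos", "gnull"))
    sc <- correlation_screen(cand, x, y, groups, min_n = 50)
    expect_true(sc$passes[sc$gene_id == "gneg"])
    expect_false(sc$passes[sc$gene_id == "gpos"]) # positive rho
    expect_false(sc$passes[sc$gene_id == "gnull"]) # no signal
    # group size 49 fails regardless of rho
    small_groups <- setNames(rep(c("tumor", "normal"), c(49, 71)), samples)
    sc2 <- correlation_screen(cand, x, y, small_groups, min_n = 50)
    expect_true(all(!sc2$passes))
    expect_equal(sc2$rho, sc$rho) # statistics unchanged, only the gate
  })
})

test_that("overlap_pvalue matches its printed examples and handles support edges", {
  expect_equal(overlap_pvalue(10, 5, 4, 2), 55 / 210)
  expect_equal(overlap_pvalue(10, 4, 4, 4), 209 / 210)
  expect_equal(overlap_pvalue(50, 10, 8, 0), 0) # empty sum
  # forced overlap: Nx + Ny > N makes small t out of support
  expect_equal(overlap_pvalue(10, 9, 9, 8),
               oracle_overlap_cdf(10, 9, 9, 8), tolerance = 1e-12)
  # cross-check against the complementary upper tail from base R
  expect_equal(overlap_pvalue(200, 40, 30, 10),
               phyper(9, 40, 160, 30), tolerance = 1e-12)
  expect_error(overlap_pvalue(10, 5, 4, 5), "inconsistent")
})

test_that("divergence scan flags disjoint novel seeds and skips small sets", {
  variants <- data.frame(
    label = c("loc-5p+0", "loc-5p+1", "loc-5p+2"),
    seed = c("AAAAAAA", "CCCCCCC", "GGGGGGG"),
    shift = c(0L, 1L, 2L),
    is_annotated = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  universe <- sprintf("g%03d", 1:500)
  mk_set <- function(lab, genes)
    structure(list(seed_label = lab, genes = genes), class = "target_set")
  sets <- list(
    "loc-5p+0" = mk_set("loc-5p+0", universe[1:12]),
    "loc-5p+1" = mk_set("loc-5p+1", universe[13:24]), # disjoint
    "loc-5p+2" = mk_set("loc-5p+2", universe[1:3]))   # too small
  dv <- divergence_scan(sets, variants, universe)
  r1 <- dv[dv$seed_x == "loc-5p+1", ]
  expect_true(r1$tested)
  expect_true(r1$divergent)
  expect_equal(r1$Nxy, 0L)
  expect_equal(r1$p_value, 0)
  r2 <- dv[dv$seed_x == "loc-5p+2", ]
  expect_false(r2$tested)
  expect_false(r2$divergent)
  # identical target sets: p near 1, not divergent
  sets2 <- sets
  sets2[["loc-5p+1"]] <- mk_set("loc-5p+1", universe[1:12])
  dv2 <- divergence_scan(sets2, variants, universe)
  expect_gt(dv2$p_value[dv2$seed_x == "loc-5p+1"], 0.95)
  expect_false(dv2$divergent[dv2$seed_x == "loc-5p+1"])
})

test_that("overlap_pvalue is monotone in the shared count", {
  for (args in list(c(30, 10, 8), c(100, 20, 15), c(15, 7, 7))) {
    p <- vapply(0:min(args[2], args[3]), function(k)
      overlap_pvalue(args[1], args[2], args[3], k), numeric(1))
    expect_true(all(diff(p) >= -1e-14))
  }
})

test_that("gain/loss is exact set algebra with conservation", {
  gl <- gain_loss(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(gl$shared, c("B", "C"))
  expect_equal(gl$gained, "A")
  expect_equal(gl$lost, "D")
  gl2 <- gain_loss(c("A", "B"), c("A", "B"))
  expect_equal(length(gl2$gained) + length(gl2$lost), 0L)
  withr::with_seed(43, {
    for (i in 1:10) {
      nov <- sample(letters, sample(5:15, 1))
      ann <- sample(letters, sample(5:15, 1))
      gl3 <- gain_loss(nov, ann)
      expect_equal(length(gl3$shared) + length(gl3$gained), length(nov))
      expect_equal(length(gl3$shared) + length(gl3$lost), length(ann))
    }
  })
})

test_that("ORA reproduces the hypergeometric example and penalises no overlap", {
  universe <- sprintf("g%02d", 1:20)
  coll <- list(sets = list(s5 = universe[1:5], s_none = universe[16:20]),
               description = c(s5 = "", s_none = ""))
  query <- universe[c(1:3, 10, 11)]
  res <- ora_enrichment(query, coll, universe)
  expect_equal(res$p_value[res$set_name == "s5"], 1126 / 15504)
  expect_equal(res$p_value[res$set_name == "s_none"], 1)
  # query genes outside the universe are dropped with a warning
  expect_warning(ora_enrichment(c(query, "alien"), coll, universe),
                 "outside the universe")
  # query equal to the set minimises p among same-size queries
  p_self <- ora_enrichment(universe[1:5], coll, universe)
  p_self <- p_self$p_value[p_self$set_name == "s5"]
  others <- utils::combn(20, 5)[, seq(1, 1000, by = 37)]
  p_other <- apply(others, 2, function(idx) {
    r <- ora_enrichment(universe[idx], coll, universe)
    r$p_value[r$set_name == "s5"]
  })
  expect_true(all(p_other >= p_self - 1e-12))
})

test_that("rewired networks partition genes and tally annotation categories", {
  variants <- data.frame(label = c("loc-5p+0", "loc-5p+1"),
                         is_annotated = c(TRUE, FALSE),
                         stringsAsFactors = FALSE)
  mk_set <- function(lab, genes) {
    sites <- data.frame(gene_id = genes, site_type = "8mer",
                        utr_start = seq_along(genes) * 10L,
                        utr_end = seq_along(genes) * 10L + 7L,
                        stringsAsFactors = FALSE)
    structure(list(seed_label = lab, genes = genes, sites = sites),
              class = "target_set")
  }
  sets <- list("loc-5p+0" = mk_set("loc-5p+0", c("gA", "gB", "gC")),
               "loc-5p+1" = mk_set("loc-5p+1", c("gB", "gC", "gD")))
  coll <- list(sets = list(hallmark = c("gA", "gB", "gD", "gZ")),
               description = c(hallmark = ""))
  nw <- build_rewired_network(sets, variants, annotations = coll)
  part <- setNames(nw$gene_partition$class, nw$gene_partition$gene_id)
  expect_equal(unname(part[c("gA", "gB", "gD")]),
               c("annotated-specific", "shared", "novel-specific"))
  # hand tally: annotated seed hits hallmark genes gA, gB; novel hits gB, gD
  ac <- nw$annotation_counts
  expect_equal(ac$n_genes[ac$seed_label == "loc-5p+0"], 2L)
  expect_equal(ac$n_genes[ac$seed_label == "loc-5p+1"], 2L)
  # screen restriction: empty screen results -> empty network
  empty_screen <- data.frame(seed_label = character(), gene_id = character(),
                             passes = logical())
  nw2 <- build_rewired_network(sets, variants, screen_results = empty_screen)
  expect_equal(nrow(nw2$edges), 0L)
  # partition classes are disjoint and cover all edge genes
  expect_setequal(nw$gene_partition$gene_id, unique(nw$edges$gene_id))
})
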