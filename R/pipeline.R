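# End-to-end orchestration: assemble the complete synthetic study (with a
# focal locus carrying one seed-shifted and one 3'-only isomiR and disjoint
# planted target sets), run every stage in dependency order, persist all
# outputs, and emit a JSON run summary with per-stage counts, thresholds and
# timings.

#' Simulate a complete synthetic study with a plant ledger
#'
#' Builds every pipeline input: a background isomiR repertoire plus a focal
#' 5p locus carrying the annotated mature, a +1 seed-shifted isomiR (novel
#' seed) and a 3'-only isomiR (same seed as annotated); negative-binomial
#' tumor/normal counts with the focal isomiRs and a set of background
#' features planted as deregulated; a UTR collection with disjoint planted
#' target sites for the annotated and novel seeds; mRNA counts down-
#' regulated and negatively coupled to the focal isomiRs for the planted
#' target genes; exponential survival keyed to the novel isomiR's tumor
#' expression; a drug-sensitivity table with a planted group shift; and a
#' small gene-set collection annotating the planted targets. The returned
#' `ledger` records every planted effect and is sufficient to score every
#' downstream stage.
#'
#' @param config A [simulation_config()].
#' @return A list of class `seedshift_dataset` with elements `loci`,
#'   `templates`, `isomir_counts`, `mrna_counts`, `utrs`, `clinical`,
#'   `drug`, `annotations`, `ledger`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  rep <- generate_isomir_repertoire(config)

  # focal locus: annotated mature, a +1 5'-shifted isomiR (novel seed) and
  # a 3'-only isomiR sharing the annotated seed. The reference is redrawn
  # until the two seeds' site patterns contain no substring of each other:
  # cross-contained patterns would make every planted site an unavoidable
  # off-target match and stall the UTR rejection sampler.
  focal <- withr::with_seed(config$rng_seed + 707L, {
    repeat {
      ref <- rand_rna(1L, 40L)
      seed_a <- extract_seed(substr(ref, 10L, 31L))
      seed_n <- extract_seed(substr(ref, 11L, 32L))
      if (seed_a != seed_n && seed_patterns_disjoint(seed_a, seed_n)) break
    }
    ref_start <- 46112742L
    data.frame(locus_id = "mir-focal", family = "fam-focal", arm = "5p",
               chrom = "chr22", strand = "+", ref_start = ref_start,
               ref_seq = ref, mature_start = ref_start + 9L,
               mature_end = ref_start + 30L, stringsAsFactors = FALSE)
  })
  focal$mature_coordinate <- sprintf("hg38:%s:%d-%d:%s", focal$chrom,
                                     focal$mature_start, focal$mature_end,
                                     focal$strand)
  focal_shifts <- data.frame(shift5 = c(0L, 1L, 0L), shift3 = c(0L, 1L, 2L))
  focal_templates <- do.call(rbind, lapply(seq_len(3L), function(k) {
    start <- focal$mature_start + focal_shifts$shift5[k]
    end <- focal$mature_end + focal_shifts$shift3[k]
    data.frame(
      isomir_id = sprintf("%s-5p-iso%02d", focal$locus_id, k),
      locus_id = focal$locus_id, arm = "5p",
      coordinate = sprintf("hg38:%s:%d-%d:+", focal$chrom, start, end),
      sequence = locus_subsequence(focal$ref_seq, focal$ref_start, start,
                                   end, "+"),
      shift5 = focal_shifts$shift5[k], shift3 = focal_shifts$shift3[k],
      stringsAsFactors = FALSE)
  }))
  seed_annotated <- extract_seed(focal_templates$sequence[1])
  seed_novel <- extract_seed(focal_templates$sequence[2])
  if (seed_novel == seed_annotated)
    stop("degenerate focal reference: shifted seed equals annotated seed",
         call. = FALSE) # probability 4^-7 under the fixed seed; never hit
  loci <- rbind(focal, rep$loci)
  templates <- rbind(focal_templates, rep$templates)

  # planted isomiR deregulation: focal isomiRs up, plus background features
  n_bg <- min(config$n_planted_background, nrow(rep$templates))
  bg_ids <- withr::with_seed(config$rng_seed + 808L,
                             sample(rep$templates$isomir_id, n_bg))
  planted_de_isomir <- rbind(
    data.frame(feature_id = focal_templates$isomir_id,
               log2FC = config$planted_lfc, stringsAsFactors = FALSE),
    if (n_bg) data.frame(feature_id = bg_ids,
                         log2FC = rep_len(c(config$planted_lfc,
                                            -config$planted_lfc), n_bg),
                         stringsAsFactors = FALSE))
  isomir_counts <- generate_count_matrix(templates, config,
                                         planted_de = planted_de_isomir)

  # disjoint planted target genes for the annotated and the novel seed
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  n_a <- config$n_sites_annotated
  n_n <- config$n_sites_novel
  if (n_a + n_n > config$n_genes)
    stop("more planted target genes than genes in the collection",
         call. = FALSE)
  genes_annotated <- genes[seq_len(n_a)]
  genes_novel <- genes[n_a + seq_len(n_n)]
  site_cycle <- c("8mer", "7mer-m8")
  planted_sites <- rbind(
    data.frame(gene_id = genes_annotated, seed = seed_annotated,
               site_type = rep_len(site_cycle, n_a), stringsAsFactors = FALSE),
    data.frame(gene_id = genes_novel, seed = seed_novel,
               site_type = rep_len(site_cycle, n_n), stringsAsFactors = FALSE))
  utr <- generate_utr_collection(config,
                                 monitored_seeds = c(seed_annotated,
                                                     seed_novel),
                                 planted_sites = planted_sites)

  # planted pairs: each focal variant negatively coupled to its targets;
  # all planted target genes down-regulated (opposite to the up isomiRs)
  planted_pairs <- rbind(
    data.frame(isomir_id = focal_templates$isomir_id[1],
               gene_id = genes_annotated, rho = config$coupling_rho,
               stringsAsFactors = FALSE),
    data.frame(isomir_id = focal_templates$isomir_id[2],
               gene_id = genes_novel, rho = config$coupling_rho,
               stringsAsFactors = FALSE))
  planted_de_mrna <- data.frame(feature_id = c(genes_annotated, genes_novel),
                                log2FC = -config$planted_lfc,
                                stringsAsFactors = FALSE)
  mrna_counts <- generate_coupled_mrna_counts(isomir_counts, config,
                                              gene_ids = genes,
                                              planted_pairs = planted_pairs,
                                              planted_de = planted_de_mrna)

  # survival keyed to the novel isomiR's expression over tumor samples
  iso_norm <- sweep(isomir_counts$counts, 2L, size_factors(isomir_counts),
                    "/")
  tumor <- names(isomir_counts$groups)[isomir_counts$groups == "tumor"]
  clinical <- generate_survival_data(iso_norm[focal_templates$isomir_id[2],
                                              tumor], config)

  # drug response: cell lines median-split on the novel isomiR's expression
  drug <- withr::with_seed(config$rng_seed + 909L, {
    cl <- sprintf("CL%03d", seq_len(2L * config$n_cell_lines))
    expr <- setNames(rexp(length(cl), rate = 1 / 100), cl)
    groups <- setNames(ifelse(median_split(expr) == "high", "shifted",
                              "comparison"), cl)
    generate_drug_response_data(groups, config,
                                isomir_expression = expr,
                                seed = config$rng_seed + 606L)
  })

  # gene-set collection: hallmark-like sets over the gene universe, built
  # to include the planted targets so enrichment/annotation stages have
  # signal to find
  annotations <- withr::with_seed(config$rng_seed + 1010L, {
    sets <- list(
      hallmark_growth = unique(c(genes_annotated,
                                 sample(genes, 15L))),
      hallmark_invasion = unique(c(genes_novel, sample(genes, 15L))),
      hallmark_angiogenesis = sample(genes, 20L),
      hallmark_apoptosis = sample(genes, 20L))
    list(sets = sets,
         description = setNames(rep("synthetic hallmark-like set",
                                    length(sets)), names(sets)))
  })

  ledger <- list(
    focal = list(locus_id = focal$locus_id,
                 isomir_ids = focal_templates$isomir_id,
                 labels = c(annotated = "mir-focal-5p+0",
                            novel = "mir-focal-5p+1",
                            three_prime_only = "mir-focal-5p+0"),
                 seed_annotated = seed_annotated, seed_novel = seed_novel,
                 genes_annotated = genes_annotated,
                 genes_novel = genes_novel),
    planted_de_isomir = planted_de_isomir,
    planted_de_mrna = planted_de_mrna,
    planted_sites = utr$ledger,
    planted_pairs = planted_pairs,
    survival_hazard_ratio = config$survival_hazard_ratio,
    drug_effect = config$drug_effect)

  structure(list(loci = loci, templates = templates,
                 isomir_counts = isomir_counts, mrna_counts = mrna_counts,
                 utrs = utr$utrs, clinical = clinical, drug = drug,
                 annotations = annotations, ledger = ledger,
                 config = config),
            class = "seedshift_dataset")
}

#' @export
print.seedshift_dataset <- function(x, ...) {
  cat("<seedshift_dataset> ", nrow(x$templates), " isomiR templates / ",
      nrow(x$loci), " loci; ", ncol(x$isomir_counts$counts), " samples; ",
      length(x$utrs), " UTRs; ", nrow(x$ledger$planted_sites),
      " planted sites\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's file dialects
#'
#' Emits the isomiR quantification TSV, mRNA count matrix and sample
#' metadata TSVs, UTR FASTA, annotation GMT, clinical TSV, drug TSV and the
#' plant-ledger JSON. Identical datasets produce byte-identical files.
#'
#' @param dataset A `seedshift_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_isomir_table(list(info = dataset$templates[, isomir_table_fixed_cols],
                          counts = dataset$isomir_counts$counts),
                     p("isomirs.tsv"))
  write_count_matrix(dataset$mrna_counts, p("mrna_counts.tsv"),
                     p("samples.tsv"))
  write_fasta(dataset$utrs, p("utrs.fasta"))
  write_gmt(dataset$annotations, p("annotations.gmt"))
  write.table(dataset$clinical, p("clinical.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$drug, p("drug.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(dataset$ledger, p("ledger.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Pipeline run configuration
#'
#' Bundles the simulation configuration, every analysis threshold, and the
#' output directory. Thresholds default to the standard decision rules:
#' deregulation at |log2FC| > 1.5 with adjusted p < 0.05, detection in at
#' least half the samples, correlation screen at FDR < 0.05 with at least
#' 50 samples per group, divergence at FDR < 0.05 with a minimum target-set
#' size of 5, and drug response at |DR| > 0.1 with p < 0.05.
#'
#' @param simulation A [simulation_config()].
#' @param outdir Output directory.
#' @param lfc_threshold,de_alpha Deregulation thresholds.
#' @param detection_fraction Minimum detected fraction of samples.
#' @param min_rpm,min_baseMean Abundance filters.
#' @param screen_min_n,screen_alpha Correlation-screen thresholds.
#' @param divergence_alpha,min_target_set Divergence-test thresholds.
#' @param dr_threshold,dr_alpha Drug-response thresholds.
#' @param max_shift Maximum |5' offset| for seed variants.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       outdir = tempfile("seedshift_run_"),
                       lfc_threshold = 1.5, de_alpha = 0.05,
                       detection_fraction = 0.5,
                       min_rpm = 50, min_baseMean = 500,
                       screen_min_n = 50L, screen_alpha = 0.05,
                       divergence_alpha = 0.05, min_target_set = 5L,
                       dr_threshold = 0.1, dr_alpha = 0.05,
                       max_shift = 5L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline on a synthetic (or pre-built) dataset
#'
#' Stages in dependency order: detection filter, isomiR and mRNA
#' differential expression, multicopy collapse and seed-variant enumeration,
#' target-set construction, opposite-expression candidate screening,
#' negative-correlation screening, divergence scan, gain/loss partitioning,
#' over-representation analysis of gained/lost targets, rewired network
#' construction, median-split survival per focal isomiR, and drug-response
#' testing. All result tables are written under `config$outdir` together
#' with a JSON run summary recording stage input/output counts, thresholds,
#' the seed, and per-stage wall times. Identical configurations produce
#' identical outputs.
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-built `seedshift_dataset`; by default one is
#'   simulated from `config$simulation`.
#' @return The run summary (a list), invisibly; its JSON form is written to
#'   `outdir/run_summary.json`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- config[setdiff(names(config)[!vapply(config, is.list,
                                                     logical(1))], "outdir")]
  summary <- list(seed = config$simulation$rng_seed,
                  thresholds = thresholds,
                  stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    summary$stages[[name]] <<- c(list(status = "completed",
                                      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)),
                                 attr(res, "stage_info"))
    res
  }

  if (is.null(dataset))
    dataset <- stage("simulate", {
      d <- simulate_dataset(config$simulation)
      write_dataset(d, file.path(outdir, "inputs"))
      structure(d, stage_info = list(n_templates = nrow(d$templates),
                                     n_genes = length(d$utrs)))
    })

  filtered <- stage("detection_filter", {
    f <- detection_filter(dataset$isomir_counts, config$detection_fraction)
    structure(f, stage_info = list(n_in = nrow(dataset$isomir_counts$counts),
                                   n_kept = nrow(f$counts)))
  })

  de_isomir <- stage("de_isomir", {
    r <- differential_expression(filtered, lfc_threshold = config$lfc_threshold,
                                 alpha = config$de_alpha)
    write_de_results(r, file.path(outdir, "de_isomir.tsv"))
    structure(r, stage_info = list(n_significant = sum(r$significant)))
  })
  de_mrna <- stage("de_mrna", {
    r <- differential_expression(dataset$mrna_counts,
                                 lfc_threshold = config$lfc_threshold,
                                 alpha = config$de_alpha)
    write_de_results(r, file.path(outdir, "de_mrna.tsv"))
    structure(r, stage_info = list(n_significant = sum(r$significant)))
  })

  variant_data <- stage("seed_variants", {
    deduped <- dedup_multicopy(dataset$templates)
    info <- deduped$kept[deduped$kept$isomir_id %in%
                           rownames(filtered$counts), , drop = FALSE]
    var_rows <- list()
    membership <- list()
    for (lid in unique(info$locus_id)) {
      li <- dataset$loci[dataset$loci$locus_id == lid, , drop = FALSE]
      recs <- info[info$locus_id == lid, , drop = FALSE]
      ann_span <- genomic_span("hg38", li$chrom, li$mature_start,
                               li$mature_end, li$strand)
      ev <- enumerate_seed_variants(recs, ann_span,
                                    max_shift = config$max_shift)
      if (nrow(ev$variants)) {
        var_rows[[lid]] <- ev$variants
        for (i in seq_len(nrow(ev$variants)))
          membership[[ev$variants$label[i]]] <-
            strsplit(ev$variants$isomir_ids[i], ",", fixed = TRUE)[[1]]
      }
    }
    variants <- do.call(rbind, var_rows)
    rownames(variants) <- NULL
    # variant-level counts: sum of member isomiR counts
    vcounts <- t(vapply(variants$label, function(lab)
      colSums(filtered$counts[membership[[lab]], , drop = FALSE]),
      numeric(ncol(filtered$counts))))
    structure(list(variants = variants,
                   counts = count_matrix(vcounts, filtered$groups)),
              stage_info = list(n_variants = nrow(variants),
                                n_dropped_multicopy = nrow(deduped$dropped)))
  })
  variants <- variant_data$variants

  de_variant <- stage("de_variant", {
    r <- differential_expression(variant_data$counts,
                                 lfc_threshold = config$lfc_threshold,
                                 alpha = config$de_alpha)
    write_de_results(r, file.path(outdir, "de_variant.tsv"))
    structure(r, stage_info = list(n_significant = sum(r$significant)))
  })

  target_sets <- stage("targets", {
    ts <- build_target_sets(variants, dataset$utrs)
    sites <- do.call(rbind, lapply(ts, function(s)
      if (nrow(s$sites)) cbind(seed_label = s$seed_label, s$sites) else NULL))
    if (!is.null(sites))
      write.table(sites, file.path(outdir, "sites.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    structure(ts, stage_info = list(
      n_seeds = length(unique(variants$seed)),
      n_sites = sum(vapply(ts, function(s) nrow(s$sites), integer(1)))))
  })

  candidates <- stage("opposite_screen", {
    cc <- screen_opposite_pairs(de_variant, de_mrna, target_sets)
    structure(cc, stage_info = list(n_candidates = nrow(cc)))
  })

  screen <- stage("correlation_screen", {
    vnorm <- sweep(variant_data$counts$counts, 2L,
                   size_factors(variant_data$counts), "/")
    mnorm <- sweep(dataset$mrna_counts$counts, 2L,
                   size_factors(dataset$mrna_counts), "/")
    sc <- correlation_screen(candidates, vnorm, mnorm,
                             variant_data$counts$groups,
                             min_n = config$screen_min_n,
                             alpha = config$screen_alpha)
    write.table(sc, file.path(outdir, "pair_screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    structure(sc, stage_info = list(n_pass = sum(sc$passes)))
  })

  divergence <- stage("divergence", {
    dv <- divergence_scan(target_sets, variants, universe = names(dataset$utrs),
                          min_set_size = config$min_target_set,
                          alpha = config$divergence_alpha)
    write.table(dv, file.path(outdir, "divergence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    structure(dv, stage_info = list(n_tested = sum(dv$tested),
                                    n_divergent = sum(dv$divergent)))
  })

  gl <- stage("gain_loss", {
    out <- lapply(seq_len(nrow(divergence)), function(i)
      c(list(seed_x = divergence$seed_x[i], seed_y = divergence$seed_y[i]),
        gain_loss(target_sets[[divergence$seed_x[i]]],
                  target_sets[[divergence$seed_y[i]]])))
    jsonlite::write_json(out, file.path(outdir, "gain_loss.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    structure(out, stage_info = list(n_comparisons = length(out)))
  })

  enrichment <- stage("enrichment", {
    rows <- lapply(gl, function(x) {
      q <- unique(c(x$gained, x$lost))
      if (!length(q)) return(NULL)
      cbind(seed_x = x$seed_x,
            ora_enrichment(q, dataset$annotations, names(dataset$utrs)))
    })
    er <- do.call(rbind, rows)
    if (!is.null(er))
      write.table(er, file.path(outdir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    structure(if (is.null(er)) data.frame() else er,
              stage_info = list(n_rows = if (is.null(er)) 0L else nrow(er)))
  })

  network <- stage("network", {
    nw <- build_rewired_network(target_sets, variants,
                                screen_results = screen,
                                annotations = dataset$annotations)
    write_edge_list(nw$edges, file.path(outdir, "network_edges.tsv"))
    structure(nw, stage_info = list(n_edges = nrow(nw$edges)))
  })

  survival_res <- stage("survival", {
    tumor <- names(filtered$groups)[filtered$groups == "tumor"]
    vnorm <- sweep(variant_data$counts$counts, 2L,
                   size_factors(variant_data$counts), "/")
    focal_labels <- unique(dataset$ledger$focal$labels)
    rows <- lapply(intersect(focal_labels, rownames(vnorm)), function(lab) {
      r <- tryCatch(median_split_survival(vnorm[lab, tumor],
                                          dataset$clinical, isomir_id = lab),
                    error = function(e) NULL)
      if (is.null(r)) NULL
      else data.frame(isomir_id = lab, chi_square = r$chi_square,
                      p_value = r$p_value, unreliable = r$unreliable,
                      stringsAsFactors = FALSE)
    })
    sv <- do.call(rbind, rows)
    if (!is.null(sv))
      write.table(sv, file.path(outdir, "survival.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    structure(if (is.null(sv)) data.frame() else sv,
              stage_info = list(n_tested = if (is.null(sv)) 0L else nrow(sv)))
  })

  drug_res <- stage("drug_response", {
    d <- dataset$drug
    groups <- setNames(d$group, d$cell_line)
    sens <- setNames(d$sensitivity, d$cell_line)
    r <- drug_response_test(sens, groups, drug = d$drug[1],
                            dr_threshold = config$dr_threshold,
                            alpha = config$dr_alpha)
    dr <- data.frame(drug = r$drug, DR = r$DR, p_value = r$p_value,
                     call = r$call, stringsAsFactors = FALSE)
    write.table(dr, file.path(outdir, "drug_response.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    structure(dr, stage_info = list(call = r$call))
  })

  summary$results <- list(
    n_significant_isomirs = sum(de_isomir$significant),
    n_significant_genes = sum(de_mrna$significant),
    n_variants = nrow(variants),
    n_candidate_pairs = nrow(candidates),
    n_passing_pairs = sum(screen$passes),
    n_divergent_seeds = sum(divergence$divergent),
    n_network_edges = nrow(network$edges),
    n_enriched_sets = if (nrow(enrichment))
      sum(enrichment$fdr < config$screen_alpha) else 0L,
    drug_call = drug_res$call[1])
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, de_isomir = de_isomir,
                 de_mrna = de_mrna, de_variant = de_variant,
                 variants = variants, target_sets = target_sets,
                 candidates = candidates, screen = screen,
                 divergence = divergence, gain_loss = gl,
                 enrichment = enrichment, network = network,
                 survival = survival_res, drug_response = drug_res,
                 dataset = dataset))
}
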