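# Synthetic-data generators: every pipeline input with known planted
# structure (fold changes, seed sites, expression couplings, hazard and
# drug-response effects) so downstream stages can be scored exactly against
# the plant ledger. All generators are deterministic functions of the
# configuration seed; the caller's RNG state is never touched.

#' Configuration for the synthetic study
#'
#' Defaults describe the simulated study conditions: tens of miRNA loci with
#' 5'/3' end heterogeneity (3' variation more frequent than 5', as observed
#' in real isomiR repertoires), negative-binomial tumor/normal counts with
#' moderate dispersion and log2 fold changes of 2.5 planted on a subset of
#' features, 500-nt UTRs with planted seed-match sites, mRNA expression
#' negatively coupled to targeting isomiRs at Spearman rho -0.6,
#' exponential survival with hazard ratio 3 between high- and low-expression
#' groups under 20% censoring, and drug sensitivities shifted by 0.2 in one
#' group.
#'
#' @param rng_seed Integer master seed; identical configurations give
#'   byte-identical datasets.
#' @param n_loci Number of background miRNA loci.
#' @param isomirs_per_locus Poisson mean of non-canonical templates per
#'   locus.
#' @param prob_shift5,prob_shift3 Per-template probabilities of a 5' / 3'
#'   end shift; the default enforces `prob_shift3 >= prob_shift5`.
#' @param n_tumor,n_normal Sample sizes per group.
#' @param nb_mean_log_range Log-scale interval for baseline NB means.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param planted_lfc Magnitude of planted log2 fold changes.
#' @param n_planted_background Number of background isomiRs given planted
#'   fold changes (half up, half down).
#' @param coupling_rho Target Spearman correlation for planted isomiR:mRNA
#'   pairs (negative).
#' @param n_genes,utr_length UTR collection size and length (nt).
#' @param n_sites_annotated,n_sites_novel Number of genes given planted
#'   sites for the focal annotated / novel seed (disjoint gene sets).
#' @param survival_hazard_ratio Hazard multiplier for the high-expression
#'   group.
#' @param baseline_hazard Exponential baseline hazard rate (events per unit
#'   follow-up time).
#' @param censoring_rate Probability a subject is censored (censor time
#'   uniform on (0, event time)).
#' @param drug_effect Mean sensitivity shift of the shifted-seed group.
#' @param drug_base,drug_sd Baseline mean and standard deviation of the
#'   sensitivity measure (clipped to `[0, 1]`).
#' @param n_cell_lines Cell lines per drug-response group.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(rng_seed = 1L,
                              n_loci = 10L,
                              isomirs_per_locus = 3,
                              prob_shift5 = 0.2,
                              prob_shift3 = 0.6,
                              n_tumor = 60L,
                              n_normal = 60L,
                              nb_mean_log_range = log(c(100, 2000)),
                              nb_dispersion = 0.1,
                              planted_lfc = 2.5,
                              n_planted_background = 20L,
                              coupling_rho = -0.6,
                              n_genes = 200L,
                              utr_length = 500L,
                              n_sites_annotated = 10L,
                              n_sites_novel = 10L,
                              survival_hazard_ratio = 3,
                              baseline_hazard = 0.1,
                              censoring_rate = 0.2,
                              drug_effect = 0.2,
                              drug_base = 0.4,
                              drug_sd = 0.1,
                              n_cell_lines = 40L) {
  stopifnot(prob_shift5 >= 0, prob_shift5 <= 1, prob_shift3 >= 0,
            prob_shift3 <= 1, nb_dispersion > 0, censoring_rate >= 0,
            censoring_rate < 1, survival_hazard_ratio > 0)
  if (prob_shift3 < prob_shift5)
    stop("'prob_shift3' must be >= 'prob_shift5': 3' end variation is the ",
         "more frequent mode", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

# TRUE when no site pattern of either seed occurs inside a site pattern of
# the other: planted sites for one seed then cannot be forced off-target
# matches of the other, so rejection sampling can always terminate
seed_patterns_disjoint <- function(seed_a, seed_b) {
  pa <- site_patterns(seed_a)
  pb <- site_patterns(seed_b)
  for (p in pa)
    for (q in pb)
      if (grepl(q, p, fixed = TRUE) || grepl(p, q, fixed = TRUE))
        return(FALSE)
  TRUE
}

rand_rna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = ""), character(1))
}

# transcript-orientation sequence of a genomic sub-span of a locus reference
locus_subsequence <- function(ref_seq, ref_start, start, end, strand) {
  s <- substr(ref_seq, start - ref_start + 1L, end - ref_start + 1L)
  if (strand == "-") rna_revcomp(s) else s
}

#' Generate a multi-locus isomiR repertoire with end heterogeneity
#'
#' Each locus receives a canonical template (the annotated mature, a 22-nt
#' window inside a simulated precursor reference) plus a Poisson number of
#' isomiR templates whose 5' and 3' ends are independently shifted with the
#' configured probabilities (offsets drawn from +/-1, +/-2 nt; 5' offsets
#' are bounded to \[-5, +5\]). Minus-strand loci are generated so that
#' transcript-orientation conventions are exercised.
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed for this stage (defaults to a fixed offset of the
#'   config seed).
#' @return A list with `loci` (data frame: `locus_id`, `family`, `arm`,
#'   `chrom`, `strand`, `ref_start`, `ref_seq`, `mature_start`,
#'   `mature_end`, `mature_coordinate`) and `templates` (data frame:
#'   `isomir_id`, `locus_id`, `arm`, `coordinate`, `sequence`, `shift5`,
#'   `shift3`).
#' @export
generate_isomir_repertoire <- function(config, seed = config$rng_seed + 101L) {
  withr::with_seed(seed, {
    loci <- data.frame(
      locus_id = sprintf("mir-sim-%02d", seq_len(config$n_loci)),
      family = sprintf("fam-%d", 1L + (seq_len(config$n_loci) - 1L) %% 4L),
      arm = sample(c("5p", "3p"), config$n_loci, replace = TRUE,
                   prob = c(0.8, 0.2)),
      chrom = paste0("chr", sample(1:22, config$n_loci, replace = TRUE)),
      strand = sample(c("+", "-"), config$n_loci, replace = TRUE),
      ref_start = sample.int(1e8, config$n_loci),
      ref_seq = rand_rna(config$n_loci, 40L),
      stringsAsFactors = FALSE)
    loci$mature_start <- loci$ref_start + 9L
    loci$mature_end <- loci$ref_start + 30L
    loci$mature_coordinate <- sprintf("hg38:%s:%d-%d:%s", loci$chrom,
                                      loci$mature_start, loci$mature_end,
                                      loci$strand)
    rows <- list()
    for (i in seq_len(config$n_loci)) {
      n_extra <- rpois(1, config$isomirs_per_locus)
      shift5 <- ifelse(runif(n_extra) < config$prob_shift5,
                       sample(c(-2L, -1L, 1L, 2L), n_extra, replace = TRUE), 0L)
      shift3 <- ifelse(runif(n_extra) < config$prob_shift3,
                       sample(c(-2L, -1L, 1L, 2L), n_extra, replace = TRUE), 0L)
      shift5 <- c(0L, pmax(-5L, pmin(5L, shift5)))
      shift3 <- c(0L, shift3) # first template is the canonical
      for (k in seq_along(shift5)) {
        if (loci$strand[i] == "+") {
          start <- loci$mature_start[i] + shift5[k]
          end <- loci$mature_end[i] + shift3[k]
        } else {
          end <- loci$mature_end[i] - shift5[k]
          start <- loci$mature_start[i] - shift3[k]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          isomir_id = sprintf("%s-%s-iso%02d", loci$locus_id[i],
                              loci$arm[i], k),
          locus_id = loci$locus_id[i], arm = loci$arm[i],
          coordinate = sprintf("hg38:%s:%d-%d:%s", loci$chrom[i], start, end,
                               loci$strand[i]),
          sequence = locus_subsequence(loci$ref_seq[i], loci$ref_start[i],
                                       start, end, loci$strand[i]),
          shift5 = shift5[k], shift3 = shift3[k], stringsAsFactors = FALSE)
      }
    }
    templates <- do.call(rbind, rows)
    rownames(templates) <- NULL
    list(loci = loci, templates = templates)
  })
}

#' Generate a negative-binomial tumor/normal count matrix
#'
#' Counts are `NB(mu_i * s_j * g_ij, dispersion)` with feature baselines
#' `mu_i` log-uniform over `nb_mean_log_range`, per-sample size factors
#' `s_j` log-uniform over `[0.5, 2]`, and a symmetric group multiplier
#' `g_ij = 2^(+/- log2FC / 2)` for planted features so the tumor/normal
#' mean ratio is exactly `2^log2FC`.
#'
#' @param templates Data frame with an `isomir_id` (or `feature_id`) column,
#'   or a character vector of feature ids.
#' @param config A [simulation_config()].
#' @param planted_de Optional data frame `feature_id`, `log2FC`; features
#'   must exist among the templates.
#' @param mu Optional named baseline means overriding the log-uniform draw.
#' @param seed RNG seed for this stage.
#' @return A [count_matrix()] with tumor/normal groups; attribute
#'   `size_factors_true` records the simulated per-sample depths.
#' @export
generate_count_matrix <- function(templates, config, planted_de = NULL,
                                  mu = NULL, seed = config$rng_seed + 202L) {
  features <- if (is.character(templates)) templates
    else if (!is.null(templates$isomir_id)) templates$isomir_id
    else templates$feature_id
  if (anyDuplicated(features))
    stop("duplicate feature ids in templates", call. = FALSE)
  if (!is.null(planted_de)) {
    unknown <- setdiff(planted_de$feature_id, features)
    if (length(unknown))
      stop("planted features not among templates: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    n_feat <- length(features)
    samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
                 sprintf("N%03d", seq_len(config$n_normal)))
    groups <- setNames(rep(c("tumor", "normal"),
                           c(config$n_tumor, config$n_normal)), samples)
    if (is.null(mu)) {
      mu <- exp(runif(n_feat, config$nb_mean_log_range[1],
                      config$nb_mean_log_range[2]))
      names(mu) <- features
    } else {
      mu <- mu[features]
    }
    sf <- exp(runif(length(samples), log(0.5), log(2)))
    lfc <- setNames(rep(0, n_feat), features)
    if (!is.null(planted_de)) lfc[planted_de$feature_id] <- planted_de$log2FC
    gmult <- outer(lfc, ifelse(groups == "tumor", 0.5, -0.5),
                   function(l, h) 2^(l * h))
    mu_mat <- (mu %o% sf) * gmult
    counts <- matrix(rnbinom(n_feat * length(samples), mu = mu_mat,
                             size = 1 / config$nb_dispersion),
                     nrow = n_feat,
                     dimnames = list(features, samples))
    cm <- count_matrix(counts, groups)
    attr(cm, "size_factors_true") <- setNames(sf, samples)
    attr(cm, "mu_true") <- mu
    cm
  })
}

#' Generate a 3'UTR collection with planted seed-match sites
#'
#' Every planted `(gene, seed, site_type)` is embedded at a recorded
#' position; rejection sampling guarantees that scanning any monitored seed
#' over the finished collection recovers exactly the plant ledger — no
#' unplanned site to any monitored seed survives anywhere.
#'
#' @param config A [simulation_config()].
#' @param monitored_seeds Character vector of 7-nt seeds that must have no
#'   unplanned matches.
#' @param planted_sites Optional data frame `gene_id`, `seed`, `site_type`;
#'   seeds must be monitored.
#' @param max_attempts Rejection-sampling attempts per gene before erroring.
#' @param seed RNG seed for this stage.
#' @return A list with `utrs` (named character vector) and `ledger` (data
#'   frame `gene_id`, `seed`, `site_type`, `utr_start`, `utr_end`).
#' @export
generate_utr_collection <- function(config, monitored_seeds,
                                    planted_sites = NULL, max_attempts = 200L,
                                    seed = config$rng_seed + 303L) {
  monitored_seeds <- unique(normalize_rna(monitored_seeds))
  if (!is.null(planted_sites) && nrow(planted_sites)) {
    planted_sites$seed <- normalize_rna(planted_sites$seed)
    if (!all(planted_sites$seed %in% monitored_seeds))
      stop("planted sites reference seeds that are not monitored",
           call. = FALSE)
  }
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  L <- config$utr_length
  withr::with_seed(seed, {
    utrs <- character(config$n_genes)
    names(utrs) <- genes
    ledger_rows <- list()
    for (g in genes) {
      wanted <- if (is.null(planted_sites)) NULL
        else planted_sites[planted_sites$gene_id == g, , drop = FALSE]
      placed <- NULL
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        utr <- rand_rna(1L, L)
        placed <- NULL
        if (!is.null(wanted) && nrow(wanted)) {
          pats <- mapply(function(sd, ty) site_patterns(sd)[[ty]],
                         wanted$seed, wanted$site_type)
          widths <- nchar(pats)
          # non-overlapping random placement, left to right with random gaps
          slack <- L - sum(widths) - 2L * nrow(wanted)
          if (slack < 0L)
            stop("UTR length ", L, " too short for ", nrow(wanted),
                 " planted sites in gene ", g,
                 "; increase 'utr_length'", call. = FALSE)
          gaps <- 1L + floor(slack * diff(c(0, sort(runif(nrow(wanted))))))
          starts <- cumsum(gaps) + cumsum(c(0L, head(widths, -1L)))
          for (j in seq_len(nrow(wanted)))
            substr(utr, starts[j], starts[j] + widths[j] - 1L) <- pats[j]
          placed <- data.frame(gene_id = g, seed = wanted$seed,
                               site_type = wanted$site_type,
                               utr_start = starts,
                               utr_end = starts + widths - 1L,
                               stringsAsFactors = FALSE)
        }
        # verify: scanning every monitored seed recovers exactly the plan
        found <- do.call(rbind, lapply(monitored_seeds, function(sd) {
          s <- scan_sites(sd, setNames(utr, g))$sites
          if (nrow(s)) cbind(seed = sd, s) else NULL
        }))
        n_found <- if (is.null(found)) 0L else nrow(found)
        n_want <- if (is.null(placed)) 0L else nrow(placed)
        if (n_found == n_want &&
            (n_want == 0L ||
             all(paste(found$seed, found$site_type, found$utr_start) %in%
                 paste(placed$seed, placed$site_type, placed$utr_start)))) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place planted sites for gene ", g, " in ",
             max_attempts, " attempts; use longer UTRs or fewer ",
             "constraints", call. = FALSE)
      utrs[g] <- utr
      if (!is.null(placed) && nrow(placed))
        ledger_rows[[length(ledger_rows) + 1L]] <- placed
    }
    ledger <- do.call(rbind, ledger_rows)
    if (is.null(ledger))
      ledger <- data.frame(gene_id = character(), seed = character(),
                           site_type = character(), utr_start = integer(),
                           utr_end = integer(), stringsAsFactors = FALSE)
    rownames(ledger) <- NULL
    list(utrs = utrs, ledger = ledger)
  })
}

#' Generate mRNA counts negatively coupled to targeting isomiRs
#'
#' Planted (isomiR, gene) pairs are coupled through a Gaussian copula: the
#' isomiR's normalised expression is rank-normalised, a correlated Gaussian
#' is drawn at the Pearson correlation `2 sin(pi * rho / 6)` that yields the
#' target Spearman `rho`, and the gene's counts come from the NB quantile
#' function at the resulting uniforms. Decoy genes are independent NB.
#'
#' @param isomir_cm [count_matrix()] of isomiR counts (provides samples and
#'   groups).
#' @param config A [simulation_config()].
#' @param gene_ids Character vector of gene ids (features of the mRNA
#'   matrix).
#' @param planted_pairs Optional data frame `isomir_id`, `gene_id`, `rho`.
#' @param planted_de Optional data frame `feature_id`, `log2FC` for gene
#'   group effects.
#' @param seed RNG seed for this stage.
#' @return A [count_matrix()] of gene counts over the same samples.
#' @export
generate_coupled_mrna_counts <- function(isomir_cm, config, gene_ids,
                                         planted_pairs = NULL,
                                         planted_de = NULL,
                                         seed = config$rng_seed + 404L) {
  stopifnot(inherits(isomir_cm, "count_matrix"))
  if (!is.null(planted_pairs)) {
    bad <- setdiff(planted_pairs$isomir_id, rownames(isomir_cm$counts))
    if (length(bad))
      stop("planted pairs reference unknown isomiRs: ",
           paste(bad, collapse = ", "), call. = FALSE)
    bad <- setdiff(planted_pairs$gene_id, gene_ids)
    if (length(bad))
      stop("planted pairs reference unknown genes: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  samples <- colnames(isomir_cm$counts)
  n_s <- length(samples)
  iso_sf <- size_factors(isomir_cm)
  iso_norm <- sweep(isomir_cm$counts, 2L, iso_sf, "/")
  withr::with_seed(seed, {
    mu <- exp(runif(length(gene_ids), config$nb_mean_log_range[1],
                    config$nb_mean_log_range[2]))
    names(mu) <- gene_ids
    sf <- exp(runif(n_s, log(0.5), log(2)))
    lfc <- setNames(rep(0, length(gene_ids)), gene_ids)
    if (!is.null(planted_de)) lfc[planted_de$feature_id] <- planted_de$log2FC
    gmult <- outer(lfc, ifelse(isomir_cm$groups == "tumor", 0.5, -0.5),
                   function(l, h) 2^(l * h))
    mu_mat <- (mu %o% sf) * gmult
    size <- 1 / config$nb_dispersion
    counts <- matrix(rnbinom(length(gene_ids) * n_s, mu = mu_mat,
                             size = size),
                     nrow = length(gene_ids),
                     dimnames = list(gene_ids, samples))
    if (!is.null(planted_pairs) && nrow(planted_pairs)) {
      for (j in seq_len(nrow(planted_pairs))) {
        iso <- planted_pairs$isomir_id[j]
        gene <- planted_pairs$gene_id[j]
        rho_s <- planted_pairs$rho[j]
        rho_p <- 2 * sin(pi * rho_s / 6)
        x <- iso_norm[iso, ]
        zx <- qnorm((rank(x, ties.method = "average") - 0.5) / n_s)
        zg <- rho_p * zx + sqrt(1 - rho_p^2) * rnorm(n_s)
        counts[gene, ] <- qnbinom(pnorm(zg), mu = mu_mat[gene, ],
                                  size = size)
      }
    }
    count_matrix(counts, isomir_cm$groups)
  })
}

#' Generate exponential survival data with a planted hazard effect
#'
#' Samples above the expression median get their exponential hazard
#' multiplied by `survival_hazard_ratio`. Censoring is independent per
#' subject: with probability `censoring_rate` the subject is censored at a
#' time uniform on (0, event time), so the realised censoring fraction is
#' controlled exactly and is independent of group under the null.
#'
#' @param expression Named numeric vector (sample -> expression).
#' @param config A [simulation_config()].
#' @param seed RNG seed for this stage.
#' @return Data frame `sample_id`, `time`, `event` (1 = event observed),
#'   `group` (the median-split label used to assign hazards).
#' @export
generate_survival_data <- function(expression, config,
                                   seed = config$rng_seed + 505L) {
  groups <- median_split(expression)
  n <- length(expression)
  withr::with_seed(seed, {
    hazard <- config$baseline_hazard *
      ifelse(groups == "high", config$survival_hazard_ratio, 1)
    t_event <- rexp(n, rate = hazard)
    censored <- runif(n) < config$censoring_rate
    time <- ifelse(censored, runif(n) * t_event, t_event)
    data.frame(sample_id = names(expression), time = time,
               event = as.integer(!censored), group = unname(groups),
               stringsAsFactors = FALSE)
  })
}

#' Generate drug-sensitivity data with a planted group shift
#'
#' Sensitivities are Gaussian around `drug_base` (sd `drug_sd`), shifted by
#' `drug_effect` for the `"shifted"` group, and clipped to `[0, 1]`.
#'
#' @param groups Named character vector (cell line -> `"shifted"` /
#'   `"comparison"`).
#' @param config A [simulation_config()].
#' @param drug Drug name recorded in the table.
#' @param isomir_expression Optional named expression vector echoed into the
#'   table.
#' @param seed RNG seed for this stage.
#' @return Data frame `cell_line`, `drug`, `sensitivity`,
#'   `isomir_expression`, `group`.
#' @export
generate_drug_response_data <- function(groups, config, drug = "drug_1",
                                        isomir_expression = NULL,
                                        seed = config$rng_seed + 606L) {
  withr::with_seed(seed, {
    n <- length(groups)
    sens <- rnorm(n, mean = config$drug_base +
                    config$drug_effect * (groups == "shifted"),
                  sd = config$drug_sd)
    sens <- pmin(1, pmax(0, sens))
    data.frame(cell_line = names(groups), drug = drug, sensitivity = sens,
               isomir_expression = if (is.null(isomir_expression))
                 NA_real_ else unname(isomir_expression[names(groups)]),
               group = unname(groups), stringsAsFactors = FALSE)
  })
}
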