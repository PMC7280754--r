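# The core analysis: screen isomiR:mRNA pairs by opposite deregulation and
# negative correlation, test novel-vs-annotated target-set divergence with a
# lower-tail hypergeometric CDF on the shared-target count, compute target
# gain/loss, run over-representation analysis, and assemble the rewired
# bipartite seed-gene network.

#' Candidate isomiR:mRNA pairs with opposite deregulation
#'
#' A pair (variant, gene) is a candidate when the gene is a predicted target
#' of the variant's seed, both are significantly deregulated, and the
#' directions are opposite (one up, one down).
#'
#' @param isomir_results DE results for seed variants: data frame with
#'   `feature_id` (variant label), `direction`, `significant`.
#' @param mrna_results DE results for genes, same columns.
#' @param target_sets Named list of `target_set` objects keyed by variant
#'   label ([build_target_sets()]).
#' @return Data frame `seed_label`, `gene_id`, `isomir_direction`,
#'   `gene_direction`.
#' @export
screen_opposite_pairs <- function(isomir_results, mrna_results, target_sets) {
  sig_iso <- isomir_results[isomir_results$significant, , drop = FALSE]
  sig_gene <- mrna_results[mrna_results$significant, , drop = FALSE]
  gene_dir <- setNames(sig_gene$direction, sig_gene$feature_id)
  rows <- list()
  for (i in seq_len(nrow(sig_iso))) {
    lab <- sig_iso$feature_id[i]
    ts <- target_sets[[lab]]
    if (is.null(ts)) next
    genes <- intersect(ts$genes, names(gene_dir))
    opp <- genes[gene_dir[genes] != sig_iso$direction[i]]
    if (length(opp))
      rows[[length(rows) + 1L]] <- data.frame(
        seed_label = lab, gene_id = opp,
        isomir_direction = sig_iso$direction[i],
        gene_direction = unname(gene_dir[opp]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seed_label = character(), gene_id = character(),
                      isomir_direction = character(),
                      gene_direction = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Negative-correlation screen over candidate pairs
#'
#' Spearman correlation per candidate pair across matched samples, BH
#' adjustment across all pairs, and the pass rule: negative rho, FDR below
#' `alpha`, and at least `min_n` samples in both the tumor and the normal
#' group. Pairs with fewer than 3 matched samples are skipped with a
#' warning.
#'
#' @param candidates Data frame from [screen_opposite_pairs()] (needs
#'   `seed_label`, `gene_id`).
#' @param isomir_expr Matrix of variant expression (variant label x sample).
#' @param mrna_expr Matrix of gene expression (gene x sample).
#' @param groups Named group vector per sample (`"tumor"`/`"normal"`).
#' @param min_n Minimum size of each group (default 50).
#' @param alpha FDR threshold (default 0.05).
#' @return Data frame `seed_label`, `gene_id`, `rho`, `p_value`, `fdr`,
#'   `n_tumor`, `n_normal`, `passes`.
#' @export
correlation_screen <- function(candidates, isomir_expr, mrna_expr, groups,
                               min_n = 50L, alpha = 0.05) {
  shared <- intersect(colnames(isomir_expr), colnames(mrna_expr))
  n_tumor <- sum(groups[shared] == "tumor")
  n_normal <- sum(groups[shared] == "normal")
  rho <- p <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    lab <- candidates$seed_label[i]
    g <- candidates$gene_id[i]
    if (!lab %in% rownames(isomir_expr) || !g %in% rownames(mrna_expr)) {
      warning("pair (", lab, ", ", g, ") missing from expression matrices; ",
              "skipped")
      next
    }
    x <- isomir_expr[lab, shared]
    y <- mrna_expr[g, shared]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      warning("pair (", lab, ", ", g, ") has fewer than 3 matched samples; ",
              "skipped")
      next
    }
    res <- spearman_correlation(x[ok], y[ok])
    rho[i] <- res$statistic
    p[i] <- res$p_value
  }
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  passes <- !is.na(rho) & rho < 0 & !is.na(fdr) & fdr < alpha &
    n_tumor >= min_n & n_normal >= min_n
  data.frame(seed_label = candidates$seed_label,
             gene_id = candidates$gene_id, rho = rho, p_value = p, fdr = fdr,
             n_tumor = n_tumor, n_normal = n_normal, passes = passes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric target-set divergence p-value
#'
#' For a novel seed with `Nx` targets and its annotated seed with `Ny`
#' targets out of a universe of `N` genes, sharing `Nxy` targets, the
#' divergence p-value is the lower-tail hypergeometric CDF evaluated just
#' below the observed overlap:
#' \deqn{p_{x,y} = F(N_{xy} - 1 \mid N, N_x, N_y)
#'   = \sum_{t=0}^{N_{xy}-1} \frac{\binom{N_x}{t}\binom{N-N_x}{N_y-t}}
#'                                {\binom{N}{N_y}}.}
#' A small p means the seeds share fewer targets than random same-size sets
#' would — the target repertoires have diverged. Terms outside the
#' hypergeometric support contribute zero; the sum is accumulated in
#' log-space. `Nxy = 0` gives the empty sum, exactly 0 (maximal
#' divergence).
#'
#' @param N Universe size (genes considered).
#' @param Nx,Ny Target-set sizes of the novel and annotated seed.
#' @param Nxy Shared-target count, `<= min(Nx, Ny)`.
#' @return The p-value in `[0, 1]`.
#' @examples
#' overlap_pvalue(10, 5, 4, 2) # 55/210
#' @export
overlap_pvalue <- function(N, Nx, Ny, Nxy) {
  if (any(c(N, Nx, Ny, Nxy) < 0) || Nx > N || Ny > N || Nxy > min(Nx, Ny))
    stop("inconsistent overlap arguments: need Nx, Ny <= N and ",
         "Nxy <= min(Nx, Ny)", call. = FALSE)
  if (Nxy == 0L) return(0)
  t <- 0:(Nxy - 1L)
  log_terms <- lchoose(Nx, t) + lchoose(N - Nx, Ny - t) - lchoose(N, Ny)
  log_terms <- log_terms[is.finite(log_terms)] # out-of-support terms are zero
  if (!length(log_terms)) return(0)
  m <- max(log_terms)
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}

#' Divergence scan: novel seeds against their annotated seed
#'
#' One comparison per novel seed variant (shift != 0) of each locus arm
#' against the annotated variant (shift 0) of the same arm, using
#' [overlap_pvalue()] with `N` equal to the universe size. P-values are BH
#' adjusted across all comparisons; a comparison is flagged divergent at
#' `fdr < alpha`. Variants whose target set (either side) is smaller than
#' `min_set_size` are excluded from testing (`tested = FALSE`) to avoid the
#' degenerate `Nxy = 0 => p = 0` artifact on near-empty sets.
#'
#' @param target_sets Named list of `target_set` objects keyed by variant
#'   label.
#' @param variants Data frame of seed variants (`label`, `seed`, `shift`,
#'   `is_annotated`) covering the labels in `target_sets`; may span several
#'   locus arms if labels are prefixed per arm.
#' @param universe Character vector of gene ids defining `N` (typically all
#'   genes with a UTR; alternatively the union of predicted targets —
#'   supply whichever universe the analysis calls for).
#' @param min_set_size Minimum targets on both sides to test (default 5).
#' @param alpha FDR threshold (default 0.05).
#' @return Data frame `seed_x` (novel), `seed_y` (annotated), `N`, `Nx`,
#'   `Ny`, `Nxy`, `p_value`, `fdr`, `tested`, `divergent`.
#' @export
divergence_scan <- function(target_sets, variants, universe,
                            min_set_size = 5L, alpha = 0.05) {
  # annotated variant per arm: label prefix before the signed shift suffix
  variants$arm_key <- sub("[+-][0-9]+$", "", variants$label)
  ann <- variants[variants$is_annotated, , drop = FALSE]
  nov <- variants[!variants$is_annotated, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(nov))) {
    a <- ann[ann$arm_key == nov$arm_key[i], , drop = FALSE]
    if (nrow(a) == 0L) next
    ts_x <- target_sets[[nov$label[i]]]
    ts_y <- target_sets[[a$label[1]]]
    if (is.null(ts_x) || is.null(ts_y)) next
    gx <- intersect(ts_x$genes, universe)
    gy <- intersect(ts_y$genes, universe)
    nxy <- length(intersect(gx, gy))
    tested <- length(gx) >= min_set_size && length(gy) >= min_set_size
    rows[[length(rows) + 1L]] <- data.frame(
      seed_x = nov$label[i], seed_y = a$label[1], N = length(universe),
      Nx = length(gx), Ny = length(gy), Nxy = nxy,
      p_value = if (tested)
        overlap_pvalue(length(universe), length(gx), length(gy), nxy)
        else NA_real_,
      tested = tested, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(seed_x = character(), seed_y = character(),
                      N = integer(), Nx = integer(), Ny = integer(),
                      Nxy = integer(), p_value = numeric(), fdr = numeric(),
                      tested = logical(), divergent = logical(),
                      stringsAsFactors = FALSE))
  out$fdr <- NA_real_
  out$fdr[out$tested] <- bh_adjust(out$p_value[out$tested])
  out$divergent <- out$tested & !is.na(out$fdr) & out$fdr < alpha
  rownames(out) <- NULL
  out
}

#' Target gain and loss between a novel and an annotated seed
#'
#' Set algebra on the two target sets: `shared` is the intersection,
#' `gained` the novel-specific targets, `lost` the annotated-specific
#' targets. `|shared| + |gained| = |novel|` and `|shared| + |lost| =
#' |annotated|` by construction.
#'
#' @param novel,annotated `target_set` objects or plain character vectors of
#'   gene ids.
#' @return List with character vectors `shared`, `gained`, `lost`.
#' @export
gain_loss <- function(novel, annotated) {
  gx <- if (inherits(novel, "target_set")) novel$genes else novel
  gy <- if (inherits(annotated, "target_set")) annotated$genes else annotated
  list(shared = sort(intersect(gx, gy)),
       gained = sort(setdiff(gx, gy)),
       lost = sort(setdiff(gy, gx)))
}

#' Over-representation analysis against a gene-set collection
#'
#' Per gene set, the hypergeometric upper-tail p-value of the overlap
#' between the query and the set, both restricted to the universe. Query
#' genes outside the universe are dropped with a warning. Both BH and
#' Bonferroni adjustments are reported so either decision rule (e.g.
#' FDR < 0.05, or Bonferroni p < 0.05 with FDR < 0.2) can be applied.
#'
#' @param query Character vector of gene ids.
#' @param collection List with `sets` (named list of gene id vectors), as
#'   from [read_gmt()].
#' @param universe Character vector of gene ids.
#' @return Data frame `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `fdr`, `bonferroni`.
#' @export
ora_enrichment <- function(query, collection, universe) {
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(unique(query), universe)
  rows <- lapply(names(collection$sets), function(nm) {
    K <- length(intersect(collection$sets[[nm]], universe))
    k <- length(intersect(intersect(collection$sets[[nm]], universe), query))
    data.frame(set_name = nm, overlap = k, set_size = K,
               query_size = length(query), universe_size = length(universe),
               p_value = if (K == 0L || length(query) == 0L) 1
                 else hypergeometric_upper_tail(k, length(universe), K,
                                                length(query)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      fdr = numeric(), bonferroni = numeric(),
                      stringsAsFactors = FALSE))
  out$fdr <- bh_adjust(out$p_value)
  out$bonferroni <- bonferroni_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Build the rewired seed-gene interaction network
#'
#' A bipartite network of seed-variant to target-gene edges, optionally
#' restricted to pairs that passed the correlation screen. Each gene is
#' partitioned into `shared` (targeted by the annotated variant and at
#' least one novel variant), `novel-specific`, or `annotated-specific`;
#' per-variant counts of genes in each annotation category (e.g. cancer
#' hallmark sets) are tallied when a collection is supplied.
#'
#' @param target_sets Named list of `target_set` objects keyed by variant
#'   label.
#' @param variants Data frame of variants (`label`, `is_annotated`).
#' @param screen_results Optional data frame from [correlation_screen()];
#'   with `restrict_to_screen = TRUE`, only passing pairs become edges.
#' @param annotations Optional gene-set collection (as from [read_gmt()])
#'   used to annotate genes and tally per-variant category counts.
#' @param restrict_to_screen Whether to keep only screen-passing edges
#'   (default `TRUE` when `screen_results` is supplied).
#' @return A list of class `rewired_network`: `edges` (data frame
#'   `seed_label`, `gene_id`, `site_type`, `annotations`), `gene_partition`
#'   (data frame `gene_id`, `class`), `annotation_counts` (data frame
#'   `seed_label`, `set_name`, `n_genes`).
#' @export
build_rewired_network <- function(target_sets, variants,
                                  screen_results = NULL, annotations = NULL,
                                  restrict_to_screen = !is.null(screen_results)) {
  edges <- do.call(rbind, lapply(names(target_sets), function(lab) {
    s <- target_sets[[lab]]$sites
    if (nrow(s) == 0L) return(NULL)
    # one edge per (variant, gene); keep the most specific site type
    prio <- match(s$site_type, c("8mer", "7mer-m8", "7mer-A1"))
    s <- s[order(s$gene_id, prio), , drop = FALSE]
    s <- s[!duplicated(s$gene_id), , drop = FALSE]
    data.frame(seed_label = lab, gene_id = s$gene_id,
               site_type = s$site_type, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(seed_label = character(), gene_id = character(),
                        site_type = character(), stringsAsFactors = FALSE)
  if (restrict_to_screen) {
    if (is.null(screen_results))
      stop("'restrict_to_screen' requires screen results", call. = FALSE)
    ok <- screen_results[screen_results$passes, c("seed_label", "gene_id")]
    edges <- merge(edges, ok, by = c("seed_label", "gene_id"))
  }
  ann_labels <- variants$label[variants$is_annotated]
  by_gene <- split(edges$seed_label, edges$gene_id)
  gene_partition <- data.frame(
    gene_id = names(by_gene),
    class = vapply(by_gene, function(labs) {
      has_ann <- any(labs %in% ann_labels)
      has_nov <- any(!labs %in% ann_labels)
      if (has_ann && has_nov) "shared"
      else if (has_nov) "novel-specific" else "annotated-specific"
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  annotation_counts <- data.frame(seed_label = character(),
                                  set_name = character(),
                                  n_genes = integer(),
                                  stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(edges)) {
    gene_sets <- annotations$sets
    rows <- list()
    for (lab in unique(edges$seed_label)) {
      genes <- edges$gene_id[edges$seed_label == lab]
      for (nm in names(gene_sets)) {
        n <- length(intersect(genes, gene_sets[[nm]]))
        if (n > 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            seed_label = lab, set_name = nm, n_genes = n,
            stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) annotation_counts <- do.call(rbind, rows)
    set_of <- lapply(split(rep(names(gene_sets),
                               lengths(gene_sets)),
                           unlist(gene_sets, use.names = FALSE)), unique)
    edges$annotations <- vapply(edges$gene_id, function(g)
      paste(sort(set_of[[g]]), collapse = ";") %||% "",
      character(1), USE.NAMES = FALSE)
  } else {
    edges$annotations <- rep("", nrow(edges))
  }
  edges <- edges[order(edges$seed_label, edges$gene_id), , drop = FALSE]
  rownames(edges) <- rownames(annotation_counts) <- NULL
  structure(list(edges = edges, gene_partition = gene_partition,
                 annotation_counts = annotation_counts),
            class = "rewired_network")
}

#' @export
print.rewired_network <- function(x, ...) {
  cat("<rewired_network> ", nrow(x$edges), " edges, ",
      nrow(x$gene_partition), " genes (",
      paste(sprintf("%s: %d", names(table(x$gene_partition$class)),
                    table(x$gene_partition$class)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
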