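# Canonical seed-match target prediction on 3'UTR sequences. A seed variant
# determines three target-strand site patterns (8mer, 7mer-m8, 7mer-A1);
# scanning is literal overlapping string search with deterministic
# precedence 8mer > 7mer-m8 > 7mer-A1 at overlapping loci.

#' Target-strand site patterns for a 7-nt seed
#'
#' For a seed (miRNA nucleotides 2-8) the canonical site types on the target
#' UTR are: `7mer-m8`, the reverse complement of the full seed (pairs miRNA
#' 2-8); `8mer`, the 7mer-m8 followed by an `A` opposite miRNA position 1;
#' and `7mer-A1`, the reverse complement of miRNA positions 2-7 followed by
#' an `A`. All patterns are in the RNA alphabet; DNA input is normalised.
#'
#' @param seed 7-nt RNA (or DNA) string.
#' @return Named character vector with entries `8mer`, `7mer-m8`, `7mer-A1`.
#' @examples
#' site_patterns("GAGGUAG")
#' # 8mer "CUACCUCA", 7mer-m8 "CUACCUC", 7mer-A1 "UACCUCA"
#' @export
site_patterns <- function(seed) {
  seed <- normalize_rna(seed)
  if (nchar(seed) != 7L)
    stop("seed must be exactly 7 nt (miRNA positions 2-8), got ",
         nchar(seed), " nt", call. = FALSE)
  m8 <- as.character(
    Biostrings::reverseComplement(Biostrings::RNAString(seed)))
  c("8mer" = paste0(m8, "A"),
    "7mer-m8" = m8,
    # dropping miRNA position 8 (the seed's last nt) drops the first
    # character of the reverse complement
    "7mer-A1" = paste0(substr(m8, 2L, 7L), "A"))
}

# all start positions of `pattern` in `subject`, overlapping occurrences
# included (literal match; RNA alphabet has no regex metacharacters)
match_positions <- function(pattern, subject) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Scan UTR sequences for seed-match sites
#'
#' Reports every occurrence of the seed's site patterns in each UTR,
#' resolving overlaps by specificity: where an 8mer and a 7mer occupy
#' overlapping positions only the 8mer is reported, and a 7mer-A1
#' overlapping a reported 7mer-m8 is likewise suppressed (precedence
#' 8mer > 7mer-m8 > 7mer-A1). Positions are 1-based inclusive on the UTR.
#'
#' @param seed 7-nt seed string, or a one-row data frame with `seed` and
#'   `label` columns (a seed-variant row).
#' @param utrs Named character vector of UTR sequences (RNA alphabet; DNA
#'   normalised).
#' @param site_types Which site types to report (default all three).
#' @param seed_label Label recorded on the result (defaults to the seed).
#' @return A list of class `target_set`: `seed_label`, `seed`, `genes`
#'   (character vector of distinct target gene ids) and `sites` (data frame
#'   `gene_id`, `site_type`, `utr_start`, `utr_end`).
#' @export
scan_sites <- function(seed, utrs, site_types = c("8mer", "7mer-m8", "7mer-A1"),
                       seed_label = NULL) {
  if (is.data.frame(seed)) {
    seed_label <- seed_label %||% seed$label[1]
    seed <- seed$seed[1]
  }
  seed <- normalize_rna(seed)
  seed_label <- if (is.null(seed_label)) seed else seed_label
  site_types <- match.arg(site_types, several.ok = TRUE)
  pats <- site_patterns(seed)
  utrs <- vapply(utrs, normalize_rna, character(1))
  priority <- c("8mer", "7mer-m8", "7mer-A1")
  rows <- vector("list", length(utrs))
  for (g in seq_along(utrs)) {
    utr <- utrs[[g]]
    kept_start <- integer(0)
    kept_end <- integer(0)
    kept_type <- character(0)
    for (ty in priority) {
      starts <- match_positions(pats[[ty]], utr)
      if (!length(starts)) next
      ends <- starts + nchar(pats[[ty]]) - 1L
      if (length(kept_start)) {
        overlaps <- vapply(seq_along(starts), function(i)
          any(starts[i] <= kept_end & ends[i] >= kept_start), logical(1))
        starts <- starts[!overlaps]
        ends <- ends[!overlaps]
      }
      if (length(starts)) {
        kept_start <- c(kept_start, starts)
        kept_end <- c(kept_end, ends)
        kept_type <- c(kept_type, rep(ty, length(starts)))
      }
    }
    keep <- kept_type %in% site_types
    if (any(keep))
      rows[[g]] <- data.frame(gene_id = names(utrs)[g],
                              site_type = kept_type[keep],
                              utr_start = kept_start[keep],
                              utr_end = kept_end[keep],
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  if (is.null(sites))
    sites <- data.frame(gene_id = character(), site_type = character(),
                        utr_start = integer(), utr_end = integer(),
                        stringsAsFactors = FALSE)
  sites <- sites[order(sites$gene_id, sites$utr_start), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(seed_label = seed_label, seed = seed,
                 genes = sort(unique(sites$gene_id)), sites = sites),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", x$seed_label, " (seed ", x$seed, "): ",
      length(x$genes), " target genes, ", nrow(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' Build target sets for a list of seed variants
#'
#' One target set per distinct seed string; variants sharing a seed (e.g.
#' 3'-only isoforms of the annotated variant) share the identical set. The
#' default site-type filter counts 8mer and 7mer-m8 sites as targets; add
#' `"7mer-A1"` to lower stringency.
#'
#' @param variants Data frame with `label` and `seed` columns (as produced
#'   by [enumerate_seed_variants()]).
#' @param utrs Named character vector of UTR sequences.
#' @param site_types Site types that qualify a gene as a target.
#' @return Named list of `target_set` objects keyed by variant label.
#' @export
build_target_sets <- function(variants, utrs,
                              site_types = c("8mer", "7mer-m8")) {
  if (nrow(variants) == 0L) return(list())
  by_seed <- list()
  out <- vector("list", nrow(variants))
  names(out) <- variants$label
  for (i in seq_len(nrow(variants))) {
    sd <- variants$seed[i]
    if (is.null(by_seed[[sd]]))
      by_seed[[sd]] <- scan_sites(sd, utrs, site_types = site_types)
    ts <- by_seed[[sd]]
    ts$seed_label <- variants$label[i]
    out[[i]] <- ts
  }
  out
}
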