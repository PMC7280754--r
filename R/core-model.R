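#' Normalise a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts `T` to `U`. Errors on characters outside
#' `{A,C,G,U,T}` (case-insensitive).
#'
#' @param x Character vector of sequences.
#' @return Character vector over `{A,C,G,U}`.
#' @export
normalize_rna <- function(x) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad))
    stop("sequence contains non-nucleotide characters: '",
         x[which(bad)[1]], "'", call. = FALSE)
  out
}

# reverse complement on the RNA alphabet; vectorised over short strings
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the seed region (nucleotides 2-8) of a miRNA or isomiR
#'
#' The seed is the heptamer at positions 2-8 (1-based) of the mature
#' sequence, the primary determinant of target recognition.
#'
#' @param sequence RNA string of length >= 8 (DNA `T` accepted, normalised).
#' @return The 7-nt seed string.
#' @examples
#' extract_seed("UGAGGUAGUAGGUUGUAUAGUU") # "GAGGUAG" (let-7 family seed)
#' @export
extract_seed <- function(sequence) {
  sequence <- normalize_rna(sequence)
  if (any(nchar(sequence) < 8L))
    stop("sequence shorter than 8 nt has no seed region (positions 2-8)",
         call. = FALSE)
  substr(sequence, 2L, 8L)
}

# signed-shift label, e.g. "let-7a-1-5p+1"
seed_variant_label <- function(locus_id, arm, shift) {
  sprintf("%s-%s%+d", locus_id, arm, shift)
}

#' Enumerate seed variants of a locus arm from an isomiR repertoire
#'
#' Each isomiR's 5' offset relative to the annotated mature span determines
#' its seed shift; variants are one row per distinct (seed, shift) pair.
#' IsomiRs whose 5' offset exceeds +/-5 nt are excluded from the variant list
#' and returned in the exclusion report, mirroring the convention of
#' enumerating seeds within the annotated seed +/- 5 nucleotides. 3'-only
#' variants (offset5 = 0) share the annotated seed variant.
#'
#' @param records Data frame with columns `isomir_id`, `locus_id`, `arm`,
#'   `coordinate` (dialect string) and `sequence`; all rows must belong to
#'   one locus arm.
#' @param annotated_span [genomic_span()] of the annotated mature.
#' @param max_shift Maximum absolute 5' offset kept (default 5).
#' @return A list with `variants` (data frame: `label`, `seed`, `shift`,
#'   `is_annotated`, `n_isomirs`, `isomir_ids`) and `excluded` (data frame of
#'   excluded isomiRs with their offsets).
#' @export
enumerate_seed_variants <- function(records, annotated_span, max_shift = 5L) {
  empty_var <- data.frame(label = character(), seed = character(),
                          shift = integer(), is_annotated = logical(),
                          n_isomirs = integer(), isomir_ids = character(),
                          stringsAsFactors = FALSE)
  empty_exc <- data.frame(isomir_id = character(), offset5 = integer(),
                          stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    return(list(variants = empty_var, excluded = empty_exc))
  if (length(unique(records$locus_id)) > 1L || length(unique(records$arm)) > 1L)
    stop("all records must belong to a single locus arm", call. = FALSE)
  offs <- vapply(records$coordinate, function(co)
    classify_shift(parse_isomir_coordinate(co), annotated_span)$offset5,
    integer(1), USE.NAMES = FALSE)
  seeds <- extract_seed(records$sequence)
  keep <- abs(offs) <= max_shift
  excluded <- data.frame(isomir_id = records$isomir_id[!keep],
                         offset5 = offs[!keep], stringsAsFactors = FALSE)
  if (!any(keep))
    return(list(variants = empty_var, excluded = excluded))
  kept <- data.frame(isomir_id = records$isomir_id[keep], seed = seeds[keep],
                     shift = offs[keep], stringsAsFactors = FALSE)
  key <- paste(kept$seed, kept$shift, sep = "@")
  grp <- split(kept, key)
  variants <- do.call(rbind, lapply(unname(grp), function(g) {
    data.frame(
      label = seed_variant_label(records$locus_id[1], records$arm[1], g$shift[1]),
      seed = g$seed[1],
      shift = g$shift[1],
      is_annotated = g$shift[1] == 0L,
      n_isomirs = nrow(g),
      isomir_ids = paste(sort(g$isomir_id), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  variants <- variants[order(variants$shift, variants$seed), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, excluded = excluded)
}

#' Collapse repeated isomiRs from multicopy pre-miRNAs
#'
#' IsomiRs with identical sequence arising from different loci (multicopy
#' pre-miRNAs or homologous family members) would be double counted in
#' sequence and function analyses. The default collapses each sequence to one
#' representative, the record with the lexicographically smallest `locus_id`
#' (ties broken by `isomir_id`); `mode = "drop_all"` removes every copy of a
#' duplicated sequence instead.
#'
#' @param records Data frame with at least `isomir_id`, `locus_id`,
#'   `sequence` columns.
#' @param mode `"collapse"` (default) keeps one representative per sequence;
#'   `"drop_all"` removes all copies of multicopy sequences.
#' @return A list with `kept` and `dropped` data frames; `dropped` carries a
#'   `duplicate_of` column naming the representative (or the sequence's first
#'   locus for `"drop_all"`).
#' @export
dedup_multicopy <- function(records, mode = c("collapse", "drop_all")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L)
    return(list(kept = records, dropped = cbind(records,
      duplicate_of = character(0))))
  ord <- order(records$sequence, records$locus_id, records$isomir_id)
  r <- records[ord, , drop = FALSE]
  first_of_seq <- !duplicated(r$sequence)
  multicopy_seq <- unique(r$sequence[duplicated(r$sequence)])
  if (mode == "collapse") {
    keep <- first_of_seq
  } else {
    keep <- !(r$sequence %in% multicopy_seq)
  }
  rep_id <- setNames(r$isomir_id[first_of_seq], r$sequence[first_of_seq])
  dropped <- r[!keep, , drop = FALSE]
  dropped$duplicate_of <- unname(rep_id[dropped$sequence])
  kept <- r[keep, , drop = FALSE]
  # restore original row order among kept records
  kept <- kept[order(match(kept$isomir_id, records$isomir_id)), , drop = FALSE]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Position frequency matrix of a set of RNA sequences
#'
#' Per-position residue fractions over `{A,C,G,U}`, the numeric form of a
#' sequence logo. Ragged lengths are allowed: the matrix spans the longest
#' sequence and shorter sequences simply do not contribute to (are not
#' padded into) the trailing positions, so every column's fractions sum to 1
#' over the residues actually observed there.
#'
#' @param sequences Non-empty character vector of RNA strings (`T`
#'   normalised to `U`).
#' @return A 4 x L numeric matrix with rows `A`, `C`, `G`, `U`; attribute
#'   `n_observed` gives the per-position denominator.
#' @examples
#' position_frequency_matrix(c("AU", "AA"))
#' @export
position_frequency_matrix <- function(sequences) {
  if (length(sequences) == 0L)
    stop("cannot build a position frequency matrix from zero sequences",
         call. = FALSE)
  sequences <- normalize_rna(sequences)
  L <- max(nchar(sequences))
  alphabet <- c("A", "C", "G", "U")
  freq <- matrix(0, nrow = 4L, ncol = L, dimnames = list(alphabet, NULL))
  n_obs <- integer(L)
  chars <- strsplit(sequences, "", fixed = TRUE)
  for (s in chars) {
    idx <- seq_along(s)
    n_obs[idx] <- n_obs[idx] + 1L
    for (j in idx) freq[s[j], j] <- freq[s[j], j] + 1
  }
  freq <- sweep(freq, 2L, n_obs, "/")
  structure(freq, n_observed = n_obs)
}
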