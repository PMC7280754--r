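# Readers/writers for the external formats the pipeline touches: isomiR
# quantification TSV, feature x sample count matrices with sample metadata,
# FASTA (via Biostrings), GMT gene sets, clinical and drug-sensitivity
# tables, and network edge lists. Readers reject malformed rows with
# located errors rather than silently coercing.

#' Count matrix with sample groups
#'
#' The container for feature x sample integer counts used throughout the
#' differential-expression and screening stages, with a tumor/normal group
#' label per sample and an optional matched-pair map.
#'
#' @param counts Non-negative integer matrix with feature rownames and
#'   sample colnames.
#' @param groups Character vector (or named vector keyed by sample) of group
#'   labels, typically `"tumor"`/`"normal"`, covering every sample.
#' @param pairs Optional character vector of matched-pair ids per sample.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, pairs = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature rownames and sample colnames", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing))
      stop("samples without a group label: ", paste(missing, collapse = ", "),
           call. = FALSE)
    groups <- groups[colnames(counts)]
  } else if (length(groups) != ncol(counts)) {
    stop("'groups' must label every sample", call. = FALSE)
  }
  groups <- setNames(as.character(groups), colnames(counts))
  if (!is.null(pairs)) {
    if (!is.null(names(pairs))) pairs <- pairs[colnames(counts)]
    pairs <- setNames(as.character(pairs), colnames(counts))
  }
  structure(list(counts = counts, groups = groups, pairs = pairs),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples (", paste(sprintf("%s: %d", names(table(x$groups)),
                                  table(x$groups)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

isomir_table_fixed_cols <- c("isomir_id", "locus_id", "arm", "coordinate",
                             "sequence")

#' Read and write isomiR quantification tables
#'
#' The table dialect is TSV with header columns `isomir_id`, `locus_id`,
#' `arm`, `coordinate` (`assembly:chrom:start-end:strand`, 1-based
#' inclusive), `sequence`, followed by one integer count column per sample.
#' Each row is validated: the coordinate must parse, the sequence length
#' must equal the span length and lie in 16-28 nt, and counts must be
#' non-negative integers; violations raise an error naming the row.
#'
#' @param path File path.
#' @return `read_isomir_table()` returns a list with `info` (data frame of
#'   the five fixed columns) and `counts` (integer matrix, isomiR x sample).
#' @export
read_isomir_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(isomir_table_fixed_cols, names(tab))
  if (length(missing))
    stop("isomiR table ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sample_cols <- setdiff(names(tab), isomir_table_fixed_cols)
  if (length(sample_cols) == 0L)
    stop("isomiR table ", path, " has no sample count columns", call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    span <- tryCatch(parse_isomir_coordinate(tab$coordinate[i]),
                     error = function(e)
                       stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
    len <- nchar(tab$sequence[i])
    if (len != span_length(span))
      stop("row ", i, ": sequence length (", len,
           ") does not match span length (", span_length(span), ")",
           call. = FALSE)
    if (len < 16L || len > 28L)
      stop("row ", i, ": sequence length ", len, " outside 16-28 nt",
           call. = FALSE)
  }
  counts <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, 1]
    stop("row ", bad, ": counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$isomir_id
  info <- tab[, isomir_table_fixed_cols]
  info$sequence <- normalize_rna(info$sequence)
  list(info = info, counts = counts)
}

#' @rdname read_isomir_table
#' @param isomirs A list with `info` and `counts` as returned by
#'   `read_isomir_table()`.
#' @export
write_isomir_table <- function(isomirs, path) {
  out <- cbind(isomirs$info,
               as.data.frame(isomirs$counts[isomirs$info$isomir_id, ,
                                            drop = FALSE]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a count matrix with sample metadata
#'
#' The counts file is TSV with a `feature_id` column then one integer column
#' per sample; the metadata file is TSV with columns `sample_id`, `group`
#' and optional `pair_id`.
#'
#' @param counts_path,metadata_path,path File paths.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, metadata_path) {
  tab <- read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "feature_id")
    stop("count matrix ", counts_path, ": first column must be 'feature_id'",
         call. = FALSE)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "group"), names(meta))
  if (length(need))
    stop("metadata ", metadata_path, " is missing columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$feature_id
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  groups <- setNames(meta$group, meta$sample_id)
  pairs <- if ("pair_id" %in% names(meta))
    setNames(meta$pair_id, meta$sample_id) else NULL
  count_matrix(counts, groups, pairs)
}

#' @rdname read_count_matrix
#' @param cm A [count_matrix()].
#' @export
write_count_matrix <- function(cm, counts_path, metadata_path) {
  tab <- data.frame(feature_id = rownames(cm$counts),
                    as.data.frame(cm$counts), check.names = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(cm$counts),
                     group = unname(cm$groups))
  if (!is.null(cm$pairs)) meta$pair_id <- unname(cm$pairs)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read a FASTA file of UTR (or other) sequences
#'
#' Wraps [Biostrings::readBStringSet()]; sequences are uppercased and `T`
#' normalised to `U` so DNA and RNA inputs are interchangeable. Duplicate
#' ids and empty sequences are rejected.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: '", ids[duplicated(ids)][1], "'", call. = FALSE)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for FASTA id '", ids[nchar(seqs) == 0L][1], "'",
         call. = FALSE)
  setNames(normalize_rna(seqs), ids)
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path,
                              width = width)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Members are deduplicated within a set; lines with fewer
#' than three fields (i.e. no members) raise an error with the line number.
#'
#' @param path GMT file path.
#' @return A list with `sets` (named list of character vectors) and
#'   `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descr <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    members <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    if (length(fields) < 3L || length(members) == 0L)
      stop("GMT line ", i, ": gene set '",
           if (length(fields)) fields[1] else "", "' has no members",
           call. = FALSE)
    if (fields[1] %in% names(sets))
      stop("GMT line ", i, ": duplicate set name '", fields[1], "'",
           call. = FALSE)
    sets[[fields[1]]] <- members
    descr[fields[1]] <- fields[2]
  }
  list(sets = sets, description = descr)
}

#' @rdname read_gmt
#' @param collection A list with `sets` and `description` as returned by
#'   `read_gmt()`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Read clinical and drug-sensitivity tables
#'
#' Clinical TSV columns: `sample_id`, `time` (positive), `event` (0/1).
#' Drug TSV columns: `cell_line`, `drug`, `sensitivity` (in `[0, 1]`),
#' `isomir_expression`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_clinical_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "time", "event"), names(tab))
  if (length(need))
    stop("clinical table ", path, " is missing columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(tab$time) | tab$time <= 0 |
                 !tab$event %in% c(0, 1))
  if (length(bad))
    stop("clinical table row ", bad[1],
         ": need time > 0 and event in {0, 1}", call. = FALSE)
  tab
}

#' @rdname read_clinical_table
#' @export
read_drug_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("cell_line", "drug", "sensitivity", "isomir_expression"),
                  names(tab))
  if (length(need))
    stop("drug table ", path, " is missing columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(tab$sensitivity) | tab$sensitivity < 0 |
                 tab$sensitivity > 1)
  if (length(bad))
    stop("drug table row ", bad[1], ": sensitivity must lie in [0, 1]",
         call. = FALSE)
  tab
}

#' Write and read a bipartite seed-to-gene edge list
#'
#' TSV with header, one edge per row, sorted stably by (`seed_label`,
#' `gene_id`); the format imports directly into Cytoscape.
#'
#' @param edges Data frame with at least `seed_label` and `gene_id`; extra
#'   attribute columns (site type, screening results, gene-set annotations)
#'   are written as-is.
#' @param path File path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("seed_label", "gene_id") %in% names(edges)))
  ord <- order(edges$seed_label, edges$gene_id)
  write.table(edges[ord, , drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
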