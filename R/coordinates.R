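#' Genomic span of an isomiR or mature miRNA
#'
#' A 1-based, inclusive genomic interval with assembly, chromosome and strand,
#' matching the coordinate dialect `assembly:chrom:start-end:strand` used in
#' isomiR quantification tables (e.g. `"hg38:chr22:46112751-46112773:+"`,
#' a 23-nt span).
#'
#' @param assembly Assembly label, e.g. `"hg38"`.
#' @param chrom Chromosome label, e.g. `"chr22"`.
#' @param start,end Positive integers, 1-based inclusive; `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_span` (a named list).
#' @examples
#' sp <- genomic_span("hg38", "chr22", 46112751, 46112773, "+")
#' span_length(sp) # 23
#' @export
genomic_span <- function(assembly, chrom, start, end, strand) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (!is.character(assembly) || length(assembly) != 1L || !nzchar(assembly))
    stop("invalid 'assembly': must be a non-empty string", call. = FALSE)
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("invalid 'chromosome': must be a non-empty string", call. = FALSE)
  if (is.na(start) || start < 1L)
    stop("invalid 'start': must be a positive integer", call. = FALSE)
  if (is.na(end) || end < 1L)
    stop("invalid 'end': must be a positive integer", call. = FALSE)
  if (end < start)
    stop("invalid span: 'start' (", start, ") > 'end' (", end, ")", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("invalid 'strand': must be '+' or '-', got '", strand, "'", call. = FALSE)
  structure(
    list(assembly = assembly, chrom = chrom, start = start, end = end,
         strand = strand),
    class = "genomic_span"
  )
}

#' @rdname genomic_span
#' @param x A `genomic_span`.
#' @export
span_length <- function(x) {
  stopifnot(inherits(x, "genomic_span"))
  x$end - x$start + 1L
}

#' Parse an isomiR coordinate string
#'
#' Parses the coordinate dialect `assembly:chrom:start-end:strand` with
#' 1-based inclusive positions, as printed in isomiR quantification tables.
#'
#' @param text A single coordinate string, e.g.
#'   `"hg38:chr22:46112751-46112773:+"`.
#' @return A [genomic_span()].
#' @examples
#' sp <- parse_isomir_coordinate("hg38:chr22:46112751-46112773:+")
#' span_length(sp) # 23
#' format_isomir_coordinate(sp)
#' @seealso [format_isomir_coordinate()] for the inverse; the two round-trip
#'   exactly.
#' @export
parse_isomir_coordinate <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("coordinate must be a single string", call. = FALSE)
  m <- regmatches(text, regexec("^([^:]+):([^:]+):([0-9]+)-([0-9]+):(.+)$", text))[[1]]
  if (length(m) == 0L)
    stop("malformed coordinate string '", text,
         "': expected assembly:chrom:start-end:strand", call. = FALSE)
  strand <- m[6]
  if (!strand %in% c("+", "-"))
    stop("malformed coordinate string '", text, "': unknown strand '",
         strand, "'", call. = FALSE)
  start <- as.integer(m[4])
  end <- as.integer(m[5])
  if (is.na(start) || is.na(end))
    stop("malformed coordinate string '", text, "': positions overflow",
         call. = FALSE)
  if (start > end)
    stop("malformed coordinate string '", text, "': start (", start,
         ") > end (", end, ")", call. = FALSE)
  genomic_span(m[2], m[3], start, end, strand)
}

#' @rdname parse_isomir_coordinate
#' @param span A [genomic_span()].
#' @export
format_isomir_coordinate <- function(span) {
  stopifnot(inherits(span, "genomic_span"))
  sprintf("%s:%s:%d-%d:%s", span$assembly, span$chrom, span$start, span$end,
          span$strand)
}

#' @export
print.genomic_span <- function(x, ...) {
  cat("<genomic_span> ", format_isomir_coordinate(x), " (", span_length(x),
      " nt)\n", sep = "")
  invisible(x)
}

#' Classify the end shifts of an isomiR relative to the annotated mature
#'
#' Offsets are reported in transcript (5'->3') orientation: `offset5 > 0`
#' means the isomiR's 5' end moved 3'-ward (5' trimming) relative to the
#' annotated mature, and `offset3 > 0` means its 3' end is extended. On the
#' minus strand the genomic end is the transcript 5' end, so genomic start
#' and end swap roles.
#'
#' @param isomir_span,annotated_span [genomic_span()] objects on the same
#'   chromosome and strand.
#' @return A list with integer fields `offset5` and `offset3`.
#' @examples
#' ann <- genomic_span("hg38", "chr22", 52, 73, "+")
#' iso <- genomic_span("hg38", "chr22", 53, 74, "+")
#' classify_shift(iso, ann) # offset5 = +1, offset3 = +1
#' @export
classify_shift <- function(isomir_span, annotated_span) {
  stopifnot(inherits(isomir_span, "genomic_span"),
            inherits(annotated_span, "genomic_span"))
  if (isomir_span$chrom != annotated_span$chrom)
    stop("isomiR and annotated mature lie on different chromosomes (",
         isomir_span$chrom, " vs ", annotated_span$chrom, ")", call. = FALSE)
  if (isomir_span$strand != annotated_span$strand)
    stop("isomiR and annotated mature lie on different strands", call. = FALSE)
  if (isomir_span$strand == "+") {
    offset5 <- isomir_span$start - annotated_span$start
    offset3 <- isomir_span$end - annotated_span$end
  } else {
    offset5 <- annotated_span$end - isomir_span$end
    offset3 <- annotated_span$start - isomir_span$start
  }
  list(offset5 = as.integer(offset5), offset3 = as.integer(offset3))
}
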