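# Genomic intervals: BED-style 0-based half-open coordinates throughout the
# package. GFF3's 1-based closed convention is converted at the file boundary.

#' Construct a set of genomic intervals
#'
#' Intervals use BED conventions: 0-based inclusive `start`, 0-based exclusive
#' `end`, strand one of `"+"`, `"-"`, `"."`.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive, `>= 0`.
#' @param end Integer vector, 0-based exclusive, `> start`.
#' @param name Optional feature names (default `"."`).
#' @param score Optional numeric scores (default `NA`).
#' @param strand Strand per interval, `"+"`, `"-"` or `"."` (default `"."`).
#' @return A `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200, name = "pk1")
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = NA_real_,
                              strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop("interval chromosome names must be non-empty")
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$end <= x$start)) stop("interval end must be > start")
  if (any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
    stop("interval coordinates must be integers")
  bad <- !x$strand %in% c("+", "-", ".")
  if (any(bad)) stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

empty_intervals <- function() {
  x <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character(),
                  stringsAsFactors = FALSE)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

#' Read a BED file (BED3 to BED6)
#'
#' Columns beyond the first three populate `name`, `score` and `strand` when
#' present. Line order is preserved. Coordinates are kept 0-based half-open.
#'
#' @param path Path to an existing BED file.
#' @return A `genomic_intervals` data frame, one row per non-empty line.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0) return(empty_intervals())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3))
    stop("BED parse error at line ", idx[which(nfield < 3)[1]],
         ": fewer than 3 tab-separated columns")
  field <- function(k, default) {
    vapply(parts, function(p) if (length(p) >= k) p[[k]] else default, "")
  }
  start <- suppressWarnings(as.numeric(field(2, NA)))
  end <- suppressWarnings(as.numeric(field(3, NA)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop("BED parse error at line ", idx[which(bad)[1]],
         ": non-integer coordinates")
  bad <- end <= start | start < 0
  if (any(bad))
    stop("BED parse error at line ", idx[which(bad)[1]],
         ": end must be greater than start and start >= 0")
  score_chr <- field(5, ".")
  score <- suppressWarnings(as.numeric(score_chr))
  x <- data.frame(
    chrom = field(1, "."),
    start = start,
    end = end,
    name = field(4, "."),
    score = score,
    strand = field(6, "."),
    stringsAsFactors = FALSE
  )
  bad <- !x$strand %in% c("+", "-", ".")
  if (any(bad))
    stop("BED parse error at line ", idx[which(bad)[1]], ": invalid strand")
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

#' Write intervals as BED6
#'
#' @param x A `genomic_intervals` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  score <- ifelse(is.na(x$score), ".",
                  format(x$score, trim = TRUE, scientific = FALSE))
  lines <- if (nrow(x) == 0) character() else
    paste(x$chrom, format(x$start, trim = TRUE, scientific = FALSE),
          format(x$end, trim = TRUE, scientific = FALSE),
          x$name, score, x$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Internal: GRanges view of an interval frame (1-based closed for IRanges).
intervals_to_granges <- function(x) {
  strand <- if (is.null(x$strand)) rep("*", nrow(x)) else
    ifelse(x$strand == ".", "*", x$strand)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Internal: overlap pairs between two interval frames (>= 1 bp).
# Returns a data.frame with query/subject row indices.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(), subject = integer()))
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(query),
                                      intervals_to_granges(subject),
                                      ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# Internal: logical vector, TRUE where query row overlaps any subject row.
overlaps_any <- function(query, subject) {
  out <- rep(FALSE, nrow(query))
  op <- overlap_pairs(query, subject)
  out[unique(op$query)] <- TRUE
  out
}
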