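#' cfDNA fragment set
#'
#' A `fragment_set` holds one plasma sample's aligned cfDNA fragments as a
#' data frame of 0-based half-open intervals (`chrom`, `start`, `end`,
#' `strand`), sorted by (chrom, start), plus the sample id and optional QC
#' metrics. This is the unit every feature-extraction operation consumes.
#'
#' @param fragments data frame with columns `chrom` (character), `start`,
#'   `end` (0-based half-open, `start < end`) and `strand` (`"+"`/`"-"`).
#'   Extra columns are preserved untouched.
#' @param sample_id sample identifier.
#' @param qc optional [qc_metrics()] record (or a list of them, one per assay).
#' @return an object of class `fragment_set`.
#' @examples
#' fs <- fragment_set(data.frame(chrom = "chr1", start = c(0L, 100L),
#'                               end = c(160L, 270L), strand = c("+", "-")),
#'                    sample_id = "s1")
#' fragment_lengths(fs)
#' @export
fragment_set <- function(fragments, sample_id = "sample", qc = NULL) {
  req <- c("chrom", "start", "end", "strand")
  if (!is.data.frame(fragments) || !all(req %in% names(fragments)))
    stop("`fragments` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  fragments$chrom <- as.character(fragments$chrom)
  fragments$start <- as.integer(fragments$start)
  fragments$end <- as.integer(fragments$end)
  fragments$strand <- as.character(fragments$strand)
  if (nrow(fragments)) {
    bad <- which(!(fragments$start < fragments$end) |
                   fragments$start < 0L |
                   !(fragments$strand %in% c("+", "-")))
    if (length(bad))
      stop("invalid fragments at rows: ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    fragments <- fragments[order(fragments$chrom, fragments$start,
                                 fragments$end), , drop = FALSE]
    rownames(fragments) <- NULL
  }
  structure(list(sample_id = as.character(sample_id),
                 fragments = fragments, qc = qc),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> sample ", x$sample_id, ": ",
      nrow(x$fragments), " fragments on ",
      length(unique(x$fragments$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @rdname fragment_set
#' @param x a `fragment_set`.
#' @export
fragment_lengths <- function(x) {
  stopifnot(inherits(x, "fragment_set"))
  x$fragments$end - x$fragments$start
}

# GRanges view of a fragment_set (1-based closed coordinates internally).
fragments_granges <- function(x) {
  stopifnot(inherits(x, "fragment_set"))
  f <- x$fragments
  GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
}

#' Read cfDNA fragments from a BED-like file
#'
#' Expects a headerless TSV whose first four columns are chrom, start, end,
#' strand (BED 0-based half-open; a 6-column BED with name/score in columns
#' 4-5 and strand in column 6 is also accepted). Malformed lines — fewer than
#' four fields, non-integer coordinates, `start >= end`, or an unrecognized
#' strand — are rejected with a warning naming their line numbers; valid
#' lines are kept.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file name.
#' @param qc optional QC metrics to attach.
#' @return a [fragment_set()].
#' @export
read_fragments <- function(path, sample_id = NULL, qc = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.(bed|tsv|txt)$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer(), strand = character()),
                        sample_id = sample_id, qc = qc))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  get <- function(i) vapply(fields, function(f) f[i], character(1))
  chrom <- get(1L)
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  col4 <- get(4L)
  strand <- ifelse(col4 %in% c("+", "-"), col4,
                   ifelse(nf >= 6L, vapply(fields, function(f)
                     if (length(f) >= 6L) f[6L] else NA_character_,
                     character(1)), NA_character_))
  ok <- nf >= 4L & !is.na(start) & !is.na(end) & start >= 0L & start < end &
    strand %in% c("+", "-")
  if (any(!ok))
    warning("rejected ", sum(!ok), " malformed line(s) in ", basename(path),
            " (lines ", paste(utils::head(which(!ok), 10L), collapse = ", "),
            ")", call. = FALSE)
  fragment_set(data.frame(chrom = chrom[ok], start = start[ok],
                          end = end[ok], strand = strand[ok],
                          stringsAsFactors = FALSE),
               sample_id = sample_id, qc = qc)
}

#' Write a fragment set as headerless BED3+strand TSV
#'
#' @param x a [fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(x, path) {
  stopifnot(inherits(x, "fragment_set"))
  utils::write.table(
    x$fragments[, c("chrom", "start", "end", "strand")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
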