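#' Construct a set of genomic intervals
#'
#' An `interval_set` is a data frame of genomic intervals in BED
#' convention: 0-based, half-open `[start, end)` coordinates.  It is the
#' atom every analysis in this package operates on: ChIP-seq peak lists,
#' histone-mark domains and TSS catalogs are all `interval_set` objects.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer-valued vector of 0-based inclusive start positions.
#' @param end integer-valued vector of exclusive end positions; must
#'   satisfy `end > start` (zero-width intervals are rejected).
#' @param name optional labels (recycled `NA` if absent).
#' @param score optional numeric scores.
#' @param strand strand codes, each one of `"+"`, `"-"`, `"."`.
#' @param label a name for the whole set (e.g. the factor or mark it
#'   represents).
#' @param source provenance string, typically a file path or `"synthetic"`.
#' @param genome optional [genome_model()]; when supplied every interval is
#'   validated against it (`chrom` present, `end` within the chromosome).
#'
#' @return A data frame of class `interval_set` with columns `chrom`,
#'   `start`, `end`, `name`, `score`, `strand` and attributes `label` and
#'   `source`.
#' @examples
#' interval_set("chr1", 100, 250, name = "peak1", score = 57, strand = "+")
#' @export
interval_set <- function(chrom, start, end, name = NA_character_,
                         score = NA_real_, strand = ".",
                         label = NA_character_, source = NA_character_,
                         genome = NULL) {
  n <- length(chrom)
  x <- data.frame(
    chrom  = as.character(chrom),
    start  = as.numeric(start),
    end    = as.numeric(end),
    name   = rep_len(as.character(name), n),
    score  = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  attr(x, "label") <- label
  attr(x, "source") <- source
  class(x) <- c("interval_set", "data.frame")
  validate_interval_set(x, genome = genome)
}

#' Validate an interval set
#'
#' Checks the structural invariants of an [interval_set()]: non-negative
#' starts, strictly positive widths, legal strand codes, and (when a
#' genome is supplied) that every interval fits on a known chromosome.
#'
#' @param x an `interval_set`.
#' @param genome optional [genome_model()] to validate bounds against.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_interval_set <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "name", "score", "strand")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L)
    stop("interval_set is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) return(x)
  if (anyNA(x$start) || anyNA(x$end))
    stop("interval coordinates must not be NA")
  if (any(x$start < 0))
    stop("interval starts must be >= 0")
  if (any(x$end <= x$start))
    stop("intervals must satisfy end > start (zero-width rejected)")
  if (any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
    stop("interval coordinates must be integer-valued")
  bad_strand <- !(x$strand %in% c("+", "-", "."))
  if (any(bad_strand))
    stop("invalid strand code(s): ",
         paste(unique(x$strand[bad_strand]), collapse = ", "))
  if (!is.null(genome)) {
    lens <- genome$chromosomes
    unknown <- setdiff(unique(x$chrom), names(lens))
    if (length(unknown) > 0L)
      stop("chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    if (any(x$end > lens[x$chrom]))
      stop("interval(s) extend beyond chromosome length")
  }
  x
}

#' @export
print.interval_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("interval_set: %d interval(s)%s\n", nrow(x),
              if (!is.na(lab)) paste0(" [", lab, "]") else ""))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Sort an interval set deterministically
#'
#' Orders by `(chrom, start, end, name)` so that equal record sets always
#' serialize identically.
#'
#' @param x an `interval_set`.
#' @return the sorted `interval_set`.
#' @export
sort_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  ord <- order(x$chrom, x$start, x$end, x$name, method = "radix")
  out <- x[ord, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$label <- attr(x, "label")
  attributes(out)$source <- attr(x, "source")
  class(out) <- class(x)
  out
}

#' Interval widths
#'
#' @param x an `interval_set`.
#' @return numeric vector of widths in bp (`end - start`).
#' @export
interval_widths <- function(x) x$end - x$start

#' Construct a genome model
#'
#' A `genome_model` records ordered chromosome lengths -- the sampling
#' space for randomization -- plus an optional set of excluded regions
#' (assembly gaps or otherwise unplaceable sequence).
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp;
#'   names must be unique, lengths strictly positive.
#' @param excluded optional [interval_set()] of regions placements must
#'   avoid when randomization is run with `respect_excluded = TRUE`.
#' @return an object of class `genome_model` with elements `chromosomes`
#'   and `excluded`.
#' @examples
#' genome_model(c(chr1 = 5e6, chr2 = 3e6, chr3 = 2e6))
#' @export
genome_model <- function(chromosomes, excluded = NULL) {
  if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
    stop("chromosomes must be a named vector")
  if (anyDuplicated(names(chromosomes)))
    stop("duplicate chromosome name(s): ",
         paste(unique(names(chromosomes)[duplicated(names(chromosomes))]),
               collapse = ", "))
  chromosomes <- stats::setNames(as.numeric(chromosomes), names(chromosomes))
  if (any(chromosomes <= 0) || anyNA(chromosomes))
    stop("chromosome lengths must be positive")
  g <- structure(list(chromosomes = chromosomes, excluded = NULL),
                 class = "genome_model")
  if (!is.null(excluded)) {
    excluded <- validate_interval_set(excluded, genome = g)
    g$excluded <- sort_intervals(excluded)
    if (placeable_length(g) <= 0)
      stop("excluded regions cover the whole genome")
  }
  g
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp total\n",
              length(x$chromosomes),
              format(sum(x$chromosomes), big.mark = ",")))
  invisible(x)
}

#' Total genome length
#' @param genome a [genome_model()].
#' @return total length in bp.
#' @export
genome_length <- function(genome) sum(genome$chromosomes)

#' Placeable genome length
#'
#' Total length minus the bases covered by the excluded set.
#' @param genome a [genome_model()].
#' @return placeable length in bp.
#' @export
placeable_length <- function(genome) {
  tot <- genome_length(genome)
  if (is.null(genome$excluded) || nrow(genome$excluded) == 0L) return(tot)
  m <- merge_intervals(genome$excluded)
  tot - sum(interval_widths(m))
}

#' Harmonize chromosome naming between interval sets
#'
#' Adds or strips a `"chr"` prefix on every chromosome name.  Mixed
#' naming conventions between a query and a genome otherwise surface as a
#' validation error rather than silent zero overlap.
#'
#' @param x an `interval_set` or `genome_model`.
#' @param style `"chr"` to ensure the prefix, `"plain"` to strip it.
#' @return the renamed object.
#' @export
normalize_chrom_names <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  rename <- function(v) {
    bare <- sub("^chr", "", v)
    if (style == "chr") paste0("chr", bare) else bare
  }
  if (inherits(x, "genome_model")) {
    names(x$chromosomes) <- rename(names(x$chromosomes))
    if (anyDuplicated(names(x$chromosomes)))
      stop("chromosome names collide after normalization")
    if (!is.null(x$excluded)) x$excluded$chrom <- rename(x$excluded$chrom)
  } else {
    x$chrom <- rename(x$chrom)
  }
  x
}
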