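#' Read a BED3--BED6 file
#'
#' Tolerates `track`, `browser` and `#` comment lines.  Coordinates are
#' kept in the native BED convention (0-based half-open).  Malformed
#' lines raise an error naming the offending line number.
#'
#' @param path path to a tab-delimited BED file.
#' @param genome optional [genome_model()]; when given, records are
#'   validated against it.
#' @param label set label; defaults to the file name without extension.
#' @return an [interval_set()].
#' @export
read_bed <- function(path, genome = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  if (!any(keep)) {
    return(interval_set(character(), numeric(), numeric(),
                        label = label, source = path))
  }
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L | nf > 12L))
    stop(sprintf("malformed BED line %d: expected 3-6+ tab-separated fields",
                 idx[which(nf < 3L | nf > 12L)[1L]]))
  getf <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  chrom <- getf(1L, NA_character_)
  start <- suppressWarnings(as.numeric(getf(2L, NA_character_)))
  end <- suppressWarnings(as.numeric(getf(3L, NA_character_)))
  bad <- is.na(start) | is.na(end) | start != floor(start) |
    end != floor(end)
  if (any(bad))
    stop(sprintf("malformed BED line %d: non-integer coordinates",
                 idx[which(bad)[1L]]))
  if (any(start >= end))
    stop(sprintf("malformed BED line %d: start >= end",
                 idx[which(start >= end)[1L]]))
  nm <- getf(4L, ".")
  nm[nm == "."] <- NA_character_
  sc <- getf(5L, ".")
  score <- suppressWarnings(as.numeric(sc))
  score[sc == "."] <- NA_real_
  strand <- getf(6L, ".")
  interval_set(chrom, start, end, name = nm, score = score,
               strand = strand, label = label, source = path,
               genome = genome)
}

#' Write an interval set as BED6
#'
#' Records are written sorted by `(chrom, start, end, name)` so output is
#' deterministic.  Absent names become `"."` and absent scores `0`,
#' making `read_bed(write_bed(x))` the identity on sorted records.
#'
#' @param x an [interval_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- sort_intervals(validate_interval_set(x))
  nm <- ifelse(is.na(x$name), ".", x$name)
  sc <- ifelse(is.na(x$score), "0",
               format(x$score, trim = TRUE, scientific = FALSE))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   nm, sc, x$strand)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con)
  invisible(path)
}

#' Read a UCSC chrom.sizes file
#'
#' @param path two-column tab-delimited file, `name<TAB>length`.
#' @return a [genome_model()] preserving file order.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (anyNA(tab$length) || any(tab$length != floor(tab$length)))
    stop("chromosome lengths must be integers: ", path)
  if (any(tab$length <= 0))
    stop("non-positive chromosome length in ", path)
  if (anyDuplicated(tab$chrom))
    stop("duplicate chromosome name(s) in ", path, ": ",
         paste(unique(tab$chrom[duplicated(tab$chrom)]), collapse = ", "))
  genome_model(stats::setNames(tab$length, tab$chrom))
}

#' Write a chrom.sizes file
#' @param genome a [genome_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(sprintf("%s\t%d", names(genome$chromosomes),
                     as.integer(genome$chromosomes)), path)
  invisible(path)
}

#' Read a MACS-style peak table
#'
#' Reads a tab-delimited peak table with a header row, as emitted by
#' MACS, into a `peak_records` data frame suitable for
#' [filter_peaks()].  Column names are configurable because peak-caller
#' dialects vary.  MACS 1.x tables use 1-based inclusive coordinates;
#' `dialect = "macs1"` converts them to 0-based half-open on read.
#'
#' @param path path to the peak table.
#' @param dialect `"bed0"` (coordinates already 0-based half-open) or
#'   `"macs1"` (1-based inclusive, converted on read).
#' @param columns named list mapping the roles `chrom`, `start`, `end`
#'   and optionally `score`, `fold`, `fdr` to header names in the file.
#' @return a data frame of class `peak_records` with columns `chrom`,
#'   `start`, `end` and whichever of `score`, `fold_enrichment`, `fdr`
#'   were mapped.
#' @export
read_macs_peaks <- function(path,
                            dialect = c("bed0", "macs1"),
                            columns = list(chrom = "chr", start = "start",
                                           end = "end", score = "score",
                                           fold = "fold_enrichment",
                                           fdr = "FDR")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  for (role in c("chrom", "start", "end")) {
    if (!(columns[[role]] %in% names(tab)))
      stop("peak table lacks required column '", columns[[role]], "'")
  }
  out <- data.frame(chrom = as.character(tab[[columns$chrom]]),
                    start = as.numeric(tab[[columns$start]]),
                    end = as.numeric(tab[[columns$end]]),
                    stringsAsFactors = FALSE)
  if (dialect == "macs1") out$start <- out$start - 1
  optional <- c(score = "score", fold = "fold_enrichment", fdr = "fdr")
  for (role in names(optional)) {
    colname <- columns[[role]]
    if (!is.null(colname) && colname %in% names(tab))
      out[[optional[[role]]]] <- as.numeric(tab[[colname]])
  }
  num <- intersect(c("score", "fold_enrichment", "fdr"), names(out))
  for (f in num) {
    v <- out[[f]]
    if (any(!is.finite(v) | v < 0, na.rm = TRUE))
      stop("peak field '", f, "' contains negative or non-finite values")
  }
  class(out) <- c("peak_records", "data.frame")
  attr(out, "source") <- path
  out
}
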