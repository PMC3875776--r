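#' Merge overlapping or nearby intervals
#'
#' Collapses an interval set into the minimal set of non-overlapping
#' intervals covering the same bases.  Under the half-open convention,
#' book-ended intervals (`end == next start`) are joined at
#' `max_gap = 0`; with `max_gap > 0`, intervals separated by at most
#' `max_gap` bp are also joined.  Names, scores and strands are dropped.
#'
#' @param x an [interval_set()].
#' @param max_gap non-negative gap (bp) across which intervals join.
#' @return a merged, sorted `interval_set`.
#' @export
merge_intervals <- function(x, max_gap = 0L) {
  stopifnot(max_gap >= 0)
  x <- sort_intervals(validate_interval_set(x))
  if (nrow(x) <= 1L) {
    out <- interval_set(x$chrom, x$start, x$end,
                        label = attr(x, "label"), source = attr(x, "source"))
    return(out)
  }
  # running maximum of end within each chromosome; a new block starts
  # where the gap to the previous covered region exceeds max_gap
  run_end <- x$end
  same_chrom <- c(FALSE, x$chrom[-1L] == x$chrom[-nrow(x)])
  for (i in seq_len(nrow(x))[-1L]) {
    if (same_chrom[i] && x$start[i] <= run_end[i - 1L] + max_gap)
      run_end[i] <- max(run_end[i - 1L], x$end[i])
  }
  new_block <- !same_chrom |
    x$start > c(-Inf, run_end[-nrow(x)]) + max_gap
  block <- cumsum(new_block)
  starts <- tapply(x$start, block, min)
  ends <- tapply(run_end, block, max)
  chroms <- x$chrom[!duplicated(block)]
  interval_set(chroms, as.numeric(starts), as.numeric(ends),
               label = attr(x, "label"), source = attr(x, "source"))
}

#' Intersect two interval sets
#'
#' Base-level intersection: the regions covered by both sets.  Used for
#' the "pre-intersected marks" reading of combined-mark subjects.
#'
#' @param a,b [interval_set()] objects.
#' @return an `interval_set` of the shared bases.
#' @export
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  pieces <- lapply(unique(a$chrom), function(cn) {
    ai <- a[a$chrom == cn, ]
    bi <- b[b$chrom == cn, ]
    if (nrow(bi) == 0L) return(NULL)
    hits <- do.call(rbind, lapply(seq_len(nrow(ai)), function(i) {
      s <- pmax(ai$start[i], bi$start)
      e <- pmin(ai$end[i], bi$end)
      ok <- e > s
      if (!any(ok)) return(NULL)
      data.frame(chrom = cn, start = s[ok], end = e[ok])
    }))
    hits
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || nrow(pieces) == 0L)
    return(interval_set(character(), numeric(), numeric(),
                        label = "intersection"))
  interval_set(pieces$chrom, pieces$start, pieces$end,
               label = "intersection")
}

# Precompute a stabbing index over a *merged* subject set: per-chromosome
# sorted starts/ends plus cumulative covered width, so the subject bases
# inside any query interval come from two findInterval() lookups.
subject_index <- function(subject) {
  m <- merge_intervals(subject)
  split_idx <- split(seq_len(nrow(m)), m$chrom)
  idx <- lapply(split_idx, function(i) {
    list(starts = m$start[i], ends = m$end[i],
         cumw = cumsum(m$end[i] - m$start[i]))
  })
  idx
}

# Covered subject bases strictly below position x on one chromosome.
.cov_below <- function(ci, x) {
  j <- findInterval(x, ci$starts)
  out <- numeric(length(x))
  nz <- j > 0L
  out[nz] <- ci$cumw[j[nz]] - pmax(ci$ends[j[nz]] - x[nz], 0)
  out
}

# Shared bp between each query interval and the merged subject.
shared_bp <- function(index, chrom, start, end) {
  out <- numeric(length(chrom))
  for (cn in unique(chrom)) {
    ci <- index[[cn]]
    sel <- chrom == cn
    if (is.null(ci)) next
    out[sel] <- .cov_below(ci, end[sel]) - .cov_below(ci, start[sel])
  }
  out
}

#' Count query intervals overlapping a subject set
#'
#' The subject is merged before counting so a query site spanning two
#' abutting subject records is counted once; each query interval counts
#' at most once.  Overlap means sharing at least `min_overlap_bp` bases
#' with the merged subject (book-ended half-open intervals share none).
#'
#' @param query an [interval_set()]; must be non-empty.
#' @param subject an [interval_set()]; may be empty, or a list of sets in
#'   which case a query interval counts only if it clears the threshold
#'   against *every* member (site-level conjunction, e.g. H3K4me1 and
#'   H3K27ac).
#' @param min_overlap_bp minimum shared bases, default 1.
#' @return an `overlap_summary`: list with `n_query`, `n_overlapping`,
#'   `fraction` and `min_overlap_bp`.
#' @examples
#' q <- interval_set("chr1", 10, 20)
#' s <- interval_set("chr1", 15, 30)
#' count_overlapping(q, s)$n_overlapping
#' @export
count_overlapping <- function(query, subject, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1)
  query <- validate_interval_set(query)
  if (nrow(query) == 0L)
    stop("query set is empty; overlap fraction undefined")
  hit <- overlap_flags(query, subject, min_overlap_bp)
  n_hit <- sum(hit)
  structure(list(n_query = nrow(query),
                 n_overlapping = n_hit,
                 fraction = n_hit / nrow(query),
                 min_overlap_bp = as.integer(min_overlap_bp)),
            class = "overlap_summary")
}

# Logical per-query overlap flags against one subject or a conjunction.
overlap_flags <- function(query, subject, min_overlap_bp = 1L) {
  subjects <- if (is.data.frame(subject)) list(subject) else subject
  hit <- rep(TRUE, nrow(query))
  for (s in subjects) {
    idx <- if (is.list(s) && !is.data.frame(s)) s else subject_index(s)
    hit <- hit &
      shared_bp(idx, query$chrom, query$start, query$end) >= min_overlap_bp
  }
  hit
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: %d / %d query intervals (%.4f, %d%%) at >= %d bp\n",
              x$n_overlapping, x$n_query, x$fraction,
              overlap_fraction_percent(x), x$min_overlap_bp))
  invisible(x)
}

#' Overlap fraction as a whole-number percentage
#'
#' Half-up rounding of `100 * fraction`, matching the convention under
#' which 1403/1605 prints as 87% and 1207/1605 as 75%.
#'
#' @param x an `overlap_summary` (or a bare fraction in `[0, 1]`).
#' @return integer percentage.
#' @export
overlap_fraction_percent <- function(x) {
  f <- if (inherits(x, "overlap_summary")) x$fraction else x
  as.integer(floor(100 * f + 0.5))
}

#' Signed distance from regions to their nearest TSS
#'
#' Distance is measured from the region midpoint, `floor((start+end)/2)`,
#' to the TSS position, signed by the feature's strand: negative when the
#' region lies upstream of the TSS, positive downstream, zero at the TSS
#' itself.  The nearest feature minimizes absolute distance; ties prefer
#' the upstream candidate, then the lexicographically smaller label.
#' Regions on chromosomes with no TSS get an `NA` distance rather than an
#' error.
#'
#' @param regions an [interval_set()] of query regions.
#' @param features an [interval_set()] of 1-bp stranded TSS anchors
#'   (`end == start + 1`).
#' @return data frame with one row per region: `distance` (signed bp) and
#'   `feature` (label of the nearest TSS).
#' @export
nearest_feature_distance <- function(regions, features) {
  features <- validate_interval_set(features)
  if (nrow(features) == 0L) stop("TSS feature set is empty")
  if (any(features$end - features$start != 1))
    stop("TSS features must be 1-bp anchors (end == start + 1)")
  regions <- validate_interval_set(regions)
  mid <- floor((regions$start + regions$end) / 2)
  distance <- rep(NA_real_, nrow(regions))
  feature <- rep(NA_character_, nrow(regions))
  fsplit <- split(seq_len(nrow(features)), features$chrom)
  for (i in seq_len(nrow(regions))) {
    fi <- fsplit[[regions$chrom[i]]]
    if (is.null(fi)) next
    pos <- features$start[fi]
    d <- ifelse(features$strand[fi] == "-", pos - mid[i], mid[i] - pos)
    best <- abs(d) == min(abs(d))
    cand <- which(best)
    if (length(cand) > 1L) {
      ups <- cand[d[cand] < 0]
      if (length(ups) > 0L) cand <- ups
      cand <- cand[order(features$name[fi][cand])]
    }
    k <- cand[1L]
    distance[i] <- d[k]
    feature[i] <- features$name[fi][k]
  }
  data.frame(distance = distance, feature = feature,
             stringsAsFactors = FALSE)
}
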