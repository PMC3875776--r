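#' Randomization configuration
#'
#' Settings for width-matched random placement of intervals across a
#' genome, the permutation null of the colocalization test.
#'
#' @param mode `"genome-wide"` (default; chromosome chosen with
#'   probability proportional to the number of legal placements,
#'   `max(L - width + 1, 0)`) or `"same-chromosome"` (each interval stays
#'   on its template chromosome; for sensitivity analysis).
#' @param seed non-negative integer seed; fully determines the output for
#'   fixed inputs.
#' @param respect_excluded if `TRUE`, placements intersecting the genome
#'   model's excluded regions are rejected and resampled.
#' @param allow_self_overlap if `FALSE`, randomized intervals are
#'   resampled until mutually non-overlapping (bounded retries).  Default
#'   `TRUE`: random intervals may overlap one another.
#' @param max_retries retry budget per interval for rejection sampling.
#' @return a `randomization_config` list.
#' @export
randomization_config <- function(mode = c("genome-wide", "same-chromosome"),
                                 seed = 1L,
                                 respect_excluded = FALSE,
                                 allow_self_overlap = TRUE,
                                 max_retries = 1000L) {
  mode <- match.arg(mode)
  stopifnot(seed >= 0, seed == floor(seed), max_retries >= 1)
  structure(list(mode = mode, seed = as.integer(seed),
                 respect_excluded = respect_excluded,
                 allow_self_overlap = allow_self_overlap,
                 max_retries = as.integer(max_retries)),
            class = "randomization_config")
}

# Deterministic per-permutation substream seed, so permutation k of a run
# can be reproduced in isolation.  Kept below 2^31.
perm_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k) * 48271) %% 2147483647)
}

# Vectorized placement of one interval per width.  Chromosome chosen with
# probability proportional to the number of legal start positions for
# that width; start uniform among them.  Uses the current RNG state.
draw_placements <- function(widths, genome, chrom = NULL) {
  lens <- genome$chromosomes
  n <- length(widths)
  if (is.null(chrom)) {
    npos <- outer(widths, lens, function(w, L) pmax(L - w + 1, 0))
    tot <- rowSums(npos)
    if (any(tot == 0))
      stop("width ", max(widths), " larger than every chromosome")
    cum <- npos
    for (j in seq_along(lens)[-1L]) cum[, j] <- cum[, j] + cum[, j - 1L]
    u <- stats::runif(n) * tot
    ci <- max.col(u <= cum, ties.method = "first")
    chrom <- names(lens)[ci]
  } else {
    if (any(lens[chrom] - widths + 1 <= 0))
      stop("width exceeds its template chromosome length")
  }
  k <- unname(lens[chrom]) - widths + 1
  start <- pmin(floor(stats::runif(n) * k), k - 1)
  data.frame(chrom = unname(chrom), start = start, end = start + widths,
             stringsAsFactors = FALSE)
}

#' Place one random interval of a given width
#'
#' Draws a single placement from the genome-wide (or same-chromosome)
#' placement distribution, using and advancing the current RNG state;
#' seed the session (or use [randomize_set()]) for reproducibility.
#'
#' @param width interval width in bp (>= 1).
#' @param genome a [genome_model()].
#' @param config a [randomization_config()].
#' @param chrom chromosome to place on (required for
#'   `"same-chromosome"` mode).
#' @return a one-row [interval_set()].
#' @export
sample_placement <- function(width, genome, config = randomization_config(),
                             chrom = NULL) {
  stopifnot(width >= 1)
  if (config$mode == "same-chromosome" && is.null(chrom))
    stop("same-chromosome mode needs the template chromosome")
  use_chrom <- if (config$mode == "same-chromosome") chrom else NULL
  excl_idx <- NULL
  if (config$respect_excluded && !is.null(genome$excluded) &&
      nrow(genome$excluded) > 0L)
    excl_idx <- subject_index(genome$excluded)
  for (try in seq_len(config$max_retries)) {
    p <- draw_placements(width, genome, chrom = use_chrom)
    if (is.null(excl_idx) ||
        shared_bp(excl_idx, p$chrom, p$start, p$end) == 0) {
      return(interval_set(p$chrom, p$start, p$end))
    }
  }
  stop("could not place interval of width ", width,
       " outside excluded regions within ", config$max_retries, " tries")
}

#' Generate a width-matched random interval set
#'
#' Produces a set with exactly the template's number of intervals and its
#' exact width multiset, placed at random across the genome.  This is one
#' draw from the permutation null: 10,000 such draws against a fixed
#' subject give the null distribution of the overlap count.
#'
#' @param template an [interval_set()] whose widths (and, in
#'   same-chromosome mode, chromosomes) are preserved.
#' @param genome a [genome_model()].
#' @param config a [randomization_config()]; `config$seed` determines the
#'   output.
#' @param perm_index permutation number within a larger run; the
#'   effective seed is a documented substream of `(seed, perm_index)`, so
#'   permutation `k` of a run can be regenerated alone.
#' @return an [interval_set()] of randomized placements.
#' @export
randomize_set <- function(template, genome,
                          config = randomization_config(),
                          perm_index = 0L) {
  template <- validate_interval_set(template, genome = genome)
  if (nrow(template) == 0L) stop("template set is empty")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(perm_seed(config$seed, perm_index))
  p <- draw_randomized(template, genome, config)
  interval_set(p$chrom, p$start, p$end,
               label = paste0("randomized:", attr(template, "label")),
               source = "randomized")
}

# Core randomized draw; assumes RNG already seeded.
draw_randomized <- function(template, genome, config) {
  widths <- interval_widths(template)
  chrom <- if (config$mode == "same-chromosome") template$chrom else NULL
  p <- draw_placements(widths, genome, chrom = chrom)
  excl_idx <- NULL
  if (config$respect_excluded && !is.null(genome$excluded) &&
      nrow(genome$excluded) > 0L)
    excl_idx <- subject_index(genome$excluded)
  if (!is.null(excl_idx)) {
    for (try in seq_len(config$max_retries)) {
      bad <- shared_bp(excl_idx, p$chrom, p$start, p$end) > 0
      if (!any(bad)) break
      redo <- draw_placements(widths[bad], genome,
                              chrom = if (is.null(chrom)) NULL else chrom[bad])
      p[bad, ] <- redo
      if (try == config$max_retries)
        stop("excluded regions too dense: retry budget exhausted for width ",
             widths[which(bad)[1L]])
    }
  }
  if (!config$allow_self_overlap) p <- enforce_disjoint(p, genome, config)
  p
}

# Resample until placements are mutually non-overlapping (used only when
# allow_self_overlap = FALSE; sequential, so slower than the default path).
enforce_disjoint <- function(p, genome, config) {
  ord <- order(p$chrom, p$start)
  p <- p[ord, ]
  repeat {
    same <- c(FALSE, p$chrom[-1L] == p$chrom[-nrow(p)])
    clash <- same & c(FALSE, p$start[-1L] < p$end[-nrow(p)])
    if (!any(clash)) break
    i <- which(clash)
    for (try in seq_len(config$max_retries)) {
      redo <- draw_placements(p$end[i] - p$start[i], genome)
      p[i, c("chrom", "start", "end")] <- redo
      p <- p[order(p$chrom, p$start), ]
      same <- c(FALSE, p$chrom[-1L] == p$chrom[-nrow(p)])
      clash <- same & c(FALSE, p$start[-1L] < p$end[-nrow(p)])
      if (!any(clash)) break
      i <- which(clash)
      if (try == config$max_retries)
        stop("could not place mutually disjoint intervals")
    }
  }
  rownames(p) <- NULL
  p
}
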