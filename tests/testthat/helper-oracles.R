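# Independent brute-force oracles used to cross-check the fast engine.
# These deliberately avoid the package's stabbing index: overlap is
# computed per base over a bitmap, or by exhaustive all-pairs scans.

# Random interval set on a small genome (base-R sampling only).
random_intervals <- function(n, genome, max_width = 500) {
  lens <- genome$chromosomes
  chrom <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  w <- unname(pmin(w, lens[chrom]))
  start <- unname(floor(runif(n) * (lens[chrom] - w + 1)))
  interval_set(chrom, start, start + w)
}

# Per-base coverage bitmap of a set on one chromosome.
coverage_bitmap <- function(x, chrom, len) {
  bits <- logical(len)
  xi <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(xi)))
    bits[seq.int(xi$start[i] + 1L, xi$end[i])] <- TRUE
  bits
}

# Overlap count by bitmap: query interval counts when it covers at least
# min_overlap_bp subject bases.
brute_overlap_count <- function(query, subject, genome, min_overlap_bp = 1) {
  bitmaps <- lapply(names(genome$chromosomes), function(cn)
    coverage_bitmap(subject, cn, genome$chromosomes[[cn]]))
  names(bitmaps) <- names(genome$chromosomes)
  hits <- vapply(seq_len(nrow(query)), function(i) {
    b <- bitmaps[[query$chrom[i]]]
    sum(b[seq.int(query$start[i] + 1L, query$end[i])]) >= min_overlap_bp
  }, logical(1))
  sum(hits)
}

# Exhaustive all-pairs nearest-TSS search with the documented sign and
# tie-break conventions.
brute_nearest <- function(region, features) {
  mid <- floor((region$start + region$end) / 2)
  fi <- features[features$chrom == region$chrom, , drop = FALSE]
  if (nrow(fi) == 0L) return(list(distance = NA_real_, feature = NA_character_))
  d <- ifelse(fi$strand == "-", fi$start - mid, mid - fi$start)
  best <- which(abs(d) == min(abs(d)))
  if (length(best) > 1L) {
    ups <- best[d[best] < 0]
    if (length(ups) > 0L) best <- ups
    best <- best[order(fi$name[best])]
  }
  list(distance = d[best[1L]], feature = fi$name[best[1L]])
}

small_genome <- function() genome_model(c(chrA = 10000, chrB = 5000))
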