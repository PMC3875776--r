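#' Classify binding sites into enhancer chromatin states
#'
#' Each site is flagged for overlap with H3K4me1, H3K27ac and (when
#' given) H3K4me3 mark regions, then assigned a state:
#' `active_enhancer` when H3K4me1 and H3K27ac are both present,
#' `enhancer` when only H3K4me1 is present, otherwise `none`.  Mark
#' presence is binary peak overlap (at least `min_overlap_bp` shared
#' bases with the merged mark set); no signal-level thresholds are used.
#' When a TSS catalog is supplied, the signed distance to the nearest TSS
#' and a distal flag (strictly more than `upstream_min_bp` upstream) are
#' filled in as well.
#'
#' @param sites an [interval_set()] of binding sites; non-empty.
#' @param h3k4me1,h3k27ac [interval_set()] mark regions.
#' @param h3k4me3 optional [interval_set()] of promoter-mark regions.
#' @param tss optional [interval_set()] of 1-bp stranded TSS anchors.
#' @param min_overlap_bp minimum shared bases for mark presence.
#' @param upstream_min_bp distal threshold in bp (default 1,000).
#' @return a data frame of class `enhancer_calls`, one row per site:
#'   interval columns plus `has_H3K4me1`, `has_H3K27ac`, `has_H3K4me3`,
#'   `state`, `tss_distance`, `nearest_tss`, `is_distal`.
#' @export
classify_enhancer_states <- function(sites, h3k4me1, h3k27ac,
                                     h3k4me3 = NULL, tss = NULL,
                                     min_overlap_bp = 1L,
                                     upstream_min_bp = 1000L) {
  sites <- validate_interval_set(sites)
  if (nrow(sites) == 0L) stop("sites set is empty")
  calls <- as.data.frame(sites)
  calls$has_H3K4me1 <- overlap_flags(sites, h3k4me1, min_overlap_bp)
  calls$has_H3K27ac <- overlap_flags(sites, h3k27ac, min_overlap_bp)
  calls$has_H3K4me3 <- if (!is.null(h3k4me3))
    overlap_flags(sites, h3k4me3, min_overlap_bp) else NA
  calls$state <- ifelse(calls$has_H3K4me1 & calls$has_H3K27ac,
                        "active_enhancer",
                        ifelse(calls$has_H3K4me1, "enhancer", "none"))
  if (!is.null(tss)) {
    nd <- nearest_feature_distance(sites, tss)
    calls$tss_distance <- nd$distance
    calls$nearest_tss <- nd$feature
    calls$is_distal <- !is.na(nd$distance) & nd$distance < 0 &
      -nd$distance > upstream_min_bp
  } else {
    calls$tss_distance <- NA_real_
    calls$nearest_tss <- NA_character_
    calls$is_distal <- NA
  }
  attr(calls, "upstream_min_bp") <- as.integer(upstream_min_bp)
  class(calls) <- c("enhancer_calls", "data.frame")
  calls
}

#' Select putative distal enhancer loci
#'
#' Applies the locus-selection rule: keep sites marked by H3K4me1, not
#' marked by H3K4me3 (promoter mark absent), and located strictly more
#' than `upstream_min_bp` (default 1 kb) upstream of the nearest TSS.  A
#' site exactly at, or within, the threshold -- or downstream -- is
#' rejected.
#'
#' @param calls an `enhancer_calls` table from
#'   [classify_enhancer_states()] carrying H3K4me3 flags and TSS
#'   distances.
#' @param upstream_min_bp minimum upstream distance in bp.
#' @return an [interval_set()] of the selected loci.
#' @export
select_putative_enhancer_loci <- function(calls, upstream_min_bp = 1000L) {
  stopifnot(inherits(calls, "enhancer_calls"))
  if (all(is.na(calls$has_H3K4me3)))
    stop("calls lack H3K4me3 flags; classify with an H3K4me3 set first")
  if (all(is.na(calls$tss_distance)) && nrow(calls) > 0L)
    stop("calls lack TSS annotation; classify with a TSS catalog first")
  keep <- calls$has_H3K4me1 & !calls$has_H3K4me3 &
    !is.na(calls$tss_distance) & calls$tss_distance < 0 &
    -calls$tss_distance > upstream_min_bp
  sel <- calls[keep, , drop = FALSE]
  interval_set(sel$chrom, sel$start, sel$end, name = sel$name,
               score = sel$score, strand = sel$strand,
               label = "putative_distal_enhancers")
}

#' Rank a factor panel by mark-overlap fraction
#'
#' For each factor's binding-site set, computes the fraction of its own
#' sites overlapping the subject mark regions, then ranks factors by
#' fraction, highest first.  Ties receive the smaller rank and the next
#' rank is skipped (competition ranking).
#'
#' @param panel named list of [interval_set()] objects, one per factor.
#' @param subject an [interval_set()] of mark regions.
#' @param min_overlap_bp minimum shared bases for an overlap.
#' @return data frame with columns `factor_label`, `n_sites`,
#'   `n_overlapping`, `fraction`, `percent`, `rank`, sorted by fraction
#'   descending.
#' @export
rank_factor_overlaps <- function(panel, subject, min_overlap_bp = 1L) {
  if (length(panel) == 0L) stop("factor panel is empty")
  if (is.null(names(panel)) || any(names(panel) == ""))
    stop("panel must be a named list of interval sets")
  idx <- subject_index(subject)
  rows <- lapply(names(panel), function(lab) {
    x <- panel[[lab]]
    if (nrow(x) == 0L) stop("factor '", lab, "' has an empty site set")
    s <- count_overlapping(x, list(idx), min_overlap_bp)
    data.frame(factor_label = lab, n_sites = s$n_query,
               n_overlapping = s$n_overlapping, fraction = s$fraction,
               percent = overlap_fraction_percent(s),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$fraction, tab$factor_label), , drop = FALSE]
  # competition ranking: ties share the smaller rank, next rank skips
  tab$rank <- rank(-tab$fraction, ties.method = "min")
  rownames(tab) <- NULL
  tab
}

#' Filter a peak table by score / fold-enrichment / FDR thresholds
#'
#' Stands in for stringent peak selection upstream of colocalization
#' analysis: retains records passing *all* supplied thresholds
#' (`score >= min_score`, `fold_enrichment >= min_fold`,
#' `fdr <= max_fdr`).
#'
#' @param peaks a `peak_records` data frame (see [read_macs_peaks()]) or
#'   any data frame with `chrom`, `start`, `end` and the thresholded
#'   columns.
#' @param min_score,min_fold,max_fdr thresholds; at least one must be
#'   supplied, and a threshold on an absent column is an error.
#' @return an [interval_set()] of the retained peaks; its label records
#'   the thresholds applied.
#' @export
filter_peaks <- function(peaks, min_score = NULL, min_fold = NULL,
                         max_fdr = NULL) {
  if (is.null(min_score) && is.null(min_fold) && is.null(max_fdr))
    stop("supply at least one threshold")
  keep <- rep(TRUE, nrow(peaks))
  applied <- character()
  check <- function(field, thr, op, tag) {
    if (is.null(thr)) return(NULL)
    if (!(field %in% names(peaks)) || anyNA(peaks[[field]]))
      stop("threshold on absent or incomplete field '", field, "'")
    applied <<- c(applied, sprintf("%s%s%g", field, tag, thr))
    keep <<- keep & op(peaks[[field]], thr)
  }
  check("score", min_score, `>=`, ">=")
  check("fold_enrichment", min_fold, `>=`, ">=")
  check("fdr", max_fdr, `<=`, "<=")
  sel <- peaks[keep, , drop = FALSE]
  interval_set(sel$chrom, sel$start, sel$end,
               name = if ("name" %in% names(sel)) sel$name else NA_character_,
               score = if ("score" %in% names(sel)) sel$score else NA_real_,
               label = paste0("filtered[", paste(applied, collapse = ","), "]"),
               source = attr(peaks, "source") %||% NA_character_)
}
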