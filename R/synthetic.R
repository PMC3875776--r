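#' Specification for a synthetic colocalization fixture
#'
#' Describes a synthetic genome, mark-domain set, query set with an
#' exactly planted overlap fraction, factor panel and TSS catalog.  The
#' defaults mirror the study geometry at desk scale: 3 chromosomes
#' totaling 10 Mb, 300 mark domains of log-normal width (median 1 kb),
#' a query of 1,605 sites with planted overlap fraction 0.87, and a
#' 19-member factor panel in which the designated query factor has the
#' top planted fraction.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param n_subject number of subject (mark) domains.
#' @param subject_width_law list with `median` (bp) and `sdlog`
#'   describing a log-normal width distribution.
#' @param n_query number of query sites.
#' @param query_width_law width law for query sites.
#' @param planted_fraction target overlap fraction `f` in `[0, 1]`;
#'   exactly `round(f * n_query)` query sites will overlap the subject.
#' @param n_factors panel size for ranking fixtures.
#' @param factor_fractions named numeric vector of planted fractions, one
#'   per factor; length must equal `n_factors`.
#' @param n_genes number of TSS anchors in the catalog.
#' @param seed integer master seed; identical spec + seed gives
#'   byte-identical fixtures.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(genome = c(chr1 = 5e6, chr2 = 3e6, chr3 = 2e6),
                           n_subject = 300L,
                           subject_width_law = list(median = 1000, sdlog = 0.5),
                           n_query = 1605L,
                           query_width_law = list(median = 1000, sdlog = 0.5),
                           planted_fraction = 0.87,
                           n_factors = 19L,
                           factor_fractions = NULL,
                           n_genes = 500L,
                           seed = 1L) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            n_subject >= 1, n_query >= 1, n_genes >= 1, n_factors >= 1)
  if (is.null(factor_fractions)) {
    factor_fractions <- stats::setNames(
      c(planted_fraction,
        round(seq(0.78, 0.10, length.out = n_factors - 1L), 3)),
      c("KMT2D", sprintf("TF%02d", seq_len(n_factors - 1L))))
  }
  if (length(factor_fractions) != n_factors)
    stop("factor_fractions must have length n_factors")
  structure(list(genome = genome, n_subject = as.integer(n_subject),
                 subject_width_law = subject_width_law,
                 n_query = as.integer(n_query),
                 query_width_law = query_width_law,
                 planted_fraction = planted_fraction,
                 n_factors = as.integer(n_factors),
                 factor_fractions = factor_fractions,
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Build the genome model of a synthetic spec
#' @param spec a [synthetic_spec()].
#' @return a [genome_model()].
#' @export
generate_genome <- function(spec) genome_model(spec$genome)

# Log-normal widths (median, sdlog), integer, >= 1, capped at the longest
# chromosome with a warning when the cap bites.
draw_widths <- function(n, width_law, max_width) {
  w <- round(stats::rlnorm(n, meanlog = log(width_law$median),
                           sdlog = width_law$sdlog))
  w <- pmax(w, 1)
  if (any(w > max_width)) {
    warning("capping ", sum(w > max_width), " width(s) at the longest ",
            "chromosome (", max_width, " bp)")
    w <- pmin(w, max_width)
  }
  w
}

#' Generate a random feature set (synthetic mark domains)
#'
#' Places `n` intervals uniformly across the genome (chromosome chosen in
#' proportion to legal placements) with widths drawn from a log-normal
#' law.  Used to emulate histone-mark domain tracks.
#'
#' @param genome a [genome_model()].
#' @param n number of intervals.
#' @param width_law list with `median` (bp) and `sdlog`.
#' @param seed integer seed.
#' @param label set label.
#' @return an [interval_set()].
#' @export
generate_feature_set <- function(genome, n, width_law, seed,
                                 label = "synthetic_marks") {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w <- draw_widths(n, width_law, max(genome$chromosomes))
  p <- draw_placements(w, genome)
  interval_set(p$chrom, p$start, p$end,
               name = sprintf("feat_%05d", seq_len(n)),
               label = label, source = "synthetic")
}

#' Plant a query set with an exact overlap fraction
#'
#' Constructs `n_query` sites of which exactly `round(f * n_query)` share
#' at least one base with the merged subject: each overlapping site is
#' anchored on a uniformly chosen subject domain, and each
#' non-overlapping site is rejection-sampled into the subject's
#' complement.  [count_overlapping()] on the result therefore returns
#' exactly `round(f * n_query)` -- the fixture's enrichment is planted
#' exactly, not in expectation.
#'
#' @param subject an [interval_set()] of mark domains; non-empty.
#' @param genome a [genome_model()].
#' @param n_query number of sites.
#' @param f target overlap fraction in `[0, 1]`.
#' @param width_law log-normal width law for the sites.
#' @param seed integer seed.
#' @param max_retries rejection-sampling budget per non-overlapping site.
#' @param label set label.
#' @return an [interval_set()] of `n_query` sites.
#' @export
plant_enriched_query <- function(subject, genome, n_query, f, width_law,
                                 seed, max_retries = 1000L,
                                 label = "synthetic_query") {
  stopifnot(f >= 0, f <= 1, n_query >= 1)
  if (nrow(subject) == 0L) stop("subject set is empty")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  merged <- merge_intervals(subject)
  idx <- subject_index(merged)
  lens <- genome$chromosomes
  k <- round(f * n_query)
  w <- draw_widths(n_query, width_law, max(lens))
  chrom <- character(n_query)
  start <- numeric(n_query)
  if (k > 0L) {
    dom <- sample.int(nrow(merged), k, replace = TRUE)
    for (i in seq_len(k)) {
      d <- dom[i]
      L <- lens[[merged$chrom[d]]]
      lo <- max(0, merged$start[d] - w[i] + 1)
      hi <- min(L - w[i], merged$end[d] - 1)
      chrom[i] <- merged$chrom[d]
      start[i] <- lo + min(floor(stats::runif(1) * (hi - lo + 1)), hi - lo)
    }
  }
  if (k < n_query) {
    for (i in seq.int(k + 1L, n_query)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        p <- draw_placements(w[i], genome)
        if (shared_bp(idx, p$chrom, p$start, p$end) == 0) {
          chrom[i] <- p$chrom; start[i] <- p$start
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("complement too dense: could not place a zero-overlap site ",
             "within ", max_retries, " tries")
    }
  }
  out <- interval_set(chrom, start, start + w,
                      name = sprintf("site_%05d", seq_len(n_query)),
                      label = label, source = "synthetic")
  sort_intervals(out)
}

#' Generate a panel of factor site sets with planted fractions
#'
#' One [plant_enriched_query()] set per factor, each with its own planted
#' overlap fraction and a deterministic per-factor sub-seed.
#'
#' @param subject an [interval_set()] of mark domains.
#' @param genome a [genome_model()].
#' @param spec a [synthetic_spec()]; uses `factor_fractions`,
#'   `query_width_law` and `seed`.  Panel sets are sized
#'   `min(n_query, 400)` sites each to keep fixtures light.
#' @param n_sites sites per factor set (default 400).
#' @return named list of [interval_set()] objects.
#' @export
generate_factor_panel <- function(subject, genome, spec, n_sites = 400L) {
  fr <- spec$factor_fractions
  panel <- lapply(seq_along(fr), function(i) {
    plant_enriched_query(subject, genome, n_sites, fr[[i]],
                         spec$query_width_law,
                         seed = perm_seed(spec$seed, 100000 + i),
                         label = names(fr)[i])
  })
  stats::setNames(panel, names(fr))
}

#' Generate a stranded TSS catalog
#'
#' `n_genes` 1-bp TSS anchors at uniform positions with random strand and
#' unique gene labels.
#'
#' @param genome a [genome_model()].
#' @param n_genes number of TSS.
#' @param seed integer seed.
#' @return an [interval_set()] of 1-bp stranded anchors.
#' @export
generate_tss_catalog <- function(genome, n_genes, seed) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- draw_placements(rep(1, n_genes), genome)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  interval_set(p$chrom, p$start, p$end,
               name = sprintf("gene_%04d", seq_len(n_genes)),
               strand = strand, label = "tss", source = "synthetic")
}

#' Write a complete synthetic fixture to disk
#'
#' Generates the genome, subject domains, planted query, factor panel and
#' TSS catalog of a [synthetic_spec()] and writes them as
#' `genome.chrom.sizes`, `subject.bed`, `query.bed`, `tss.bed`,
#' `panel/<factor>.bed`, plus a `manifest.json` recording the spec, seed
#' and md5 checksum of every file.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param panel whether to write the factor panel.
#' @return the manifest, invisibly.
#' @export
simulate_fixture <- function(spec, dir, panel = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- generate_genome(spec)
  subject <- generate_feature_set(g, spec$n_subject, spec$subject_width_law,
                                  seed = perm_seed(spec$seed, 1),
                                  label = "subject")
  query <- plant_enriched_query(subject, g, spec$n_query,
                                spec$planted_fraction, spec$query_width_law,
                                seed = perm_seed(spec$seed, 2),
                                label = "query")
  tss <- generate_tss_catalog(g, spec$n_genes,
                              seed = perm_seed(spec$seed, 3))
  files <- c(genome = file.path(dir, "genome.chrom.sizes"),
             subject = file.path(dir, "subject.bed"),
             query = file.path(dir, "query.bed"),
             tss = file.path(dir, "tss.bed"))
  write_chrom_sizes(g, files[["genome"]])
  write_bed(subject, files[["subject"]])
  write_bed(query, files[["query"]])
  write_bed(tss, files[["tss"]])
  if (panel) {
    pdir <- file.path(dir, "panel")
    dir.create(pdir, showWarnings = FALSE)
    sets <- generate_factor_panel(subject, g, spec)
    pfiles <- vapply(names(sets), function(lab) {
      f <- file.path(pdir, paste0(lab, ".bed"))
      write_bed(sets[[lab]], f)
      f
    }, "")
    files <- c(files, pfiles)
  }
  manifest <- list(
    spec = unclass(spec),
    seed = spec$seed,
    files = lapply(files, function(f)
      list(path = substring(f, nchar(dir) + 2L),
           md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
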