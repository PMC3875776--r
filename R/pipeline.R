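#' Read a pipeline run configuration
#'
#' A single YAML key-value file with flat sections per subcommand
#' (`simulate`, `filter_peaks`, `enrich`, `rank`, `classify`) plus a
#' `common` section for shared settings (genome path, seed,
#' n_permutations, min_overlap_bp, chromosome-name normalization,
#' randomization mode, output directory).
#'
#' @param path path to a YAML config file.
#' @param overrides named list merged over the file values (flags win).
#' @return a `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(common = list(n_permutations = 10000L, seed = 1L,
                                 min_overlap_bp = 1L,
                                 normalize_chr = FALSE,
                                 mode = "genome-wide",
                                 outdir = "peakperm_out"))
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

log_msg <- function(outdir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  message(msg)
  cat(msg, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

# Echo the effective config into the output directory for provenance.
prepare_outdir <- function(cfg) {
  outdir <- cfg$common$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.echo.yaml"))
  outdir
}

load_inputs <- function(cfg, paths, genome) {
  norm <- isTRUE(cfg$common$normalize_chr)
  sets <- lapply(names(paths), function(nm) {
    x <- read_bed(paths[[nm]], label = nm)
    if (norm) x <- normalize_chrom_names(x, "chr")
    validate_interval_set(x, genome = genome)
  })
  stats::setNames(sets, names(paths))
}

load_genome <- function(cfg) {
  g <- read_chrom_sizes(cfg$common$genome)
  if (isTRUE(cfg$common$normalize_chr)) g <- normalize_chrom_names(g, "chr")
  g
}

#' Run the `simulate` pipeline step
#'
#' Writes the synthetic fixture described by the config's `simulate`
#' section (fields as in [synthetic_spec()]).
#'
#' @param cfg a `run_config`.
#' @return the fixture manifest, invisibly.
#' @export
run_simulate <- function(cfg) {
  outdir <- prepare_outdir(cfg)
  sim <- cfg$simulate %||% list()
  args <- sim[intersect(names(sim),
                        names(formals(synthetic_spec)))]
  if (!is.null(args$genome)) args$genome <- unlist(args$genome)
  if (is.null(args$seed)) args$seed <- cfg$common$seed
  spec <- do.call(synthetic_spec, args)
  log_msg(outdir, "simulate: seed ", spec$seed, ", n_query ", spec$n_query,
          ", planted_fraction ", spec$planted_fraction)
  simulate_fixture(spec, outdir, panel = !isFALSE(sim$panel))
}

#' Run the `enrich` pipeline step
#'
#' One permutation test per configured subject set, plus optional
#' conjunction rows (a site must overlap every named member, e.g.
#' H3K4me1 and H3K27ac).  Writes `enrichment.tsv` and `enrichment.json`
#' with identical fields.
#'
#' @param cfg a `run_config` whose `enrich` section names `query` (path),
#'   `subjects` (named map of label to BED path), optional `conjunctions`
#'   (list of character vectors of subject labels) and optional
#'   `intersect_marks` flag to evaluate conjunctions against the
#'   base-level intersection of the marks instead.
#' @return the report data frame, invisibly.
#' @export
run_enrich <- function(cfg) {
  outdir <- prepare_outdir(cfg)
  genome <- load_genome(cfg)
  en <- cfg$enrich
  query <- load_inputs(cfg, list(query = en$query), genome)$query
  subjects <- load_inputs(cfg, en$subjects, genome)
  n_perm <- cfg$common$n_permutations
  rconf <- randomization_config(mode = cfg$common$mode,
                                seed = cfg$common$seed)
  minbp <- cfg$common$min_overlap_bp
  targets <- lapply(names(subjects), function(nm) subjects[[nm]])
  names(targets) <- names(subjects)
  for (conj in en$conjunctions) {
    nm <- paste(conj, collapse = "+")
    targets[[nm]] <- if (isTRUE(en$intersect_marks)) {
      x <- Reduce(intersect_intervals, subjects[conj])
      attr(x, "label") <- nm
      x
    } else {
      unname(subjects[conj])
    }
  }
  rows <- lapply(names(targets), function(nm) {
    log_msg(outdir, "enrich: ", attr(query, "label") %||% "query", " vs ",
            nm, " (N = ", n_perm, ", seed ", rconf$seed,
            ", min_overlap ", minbp, " bp)")
    pt <- permutation_test(query, targets[[nm]], genome,
                           n_permutations = n_perm, config = rconf,
                           min_overlap_bp = minbp)
    s <- summary(pt)
    s$subject <- nm
    s
  })
  report <- do.call(rbind, rows)
  write_report(report, outdir, "enrichment")
  invisible(report)
}

#' Run the `rank` pipeline step
#'
#' Ranks every BED file in the configured panel directory by its
#' fraction of sites overlapping the subject set; writes `ranking.tsv`.
#'
#' @param cfg a `run_config` whose `rank` section names `panel_dir` and
#'   `subject`.
#' @return the ranking table, invisibly.
#' @export
run_rank <- function(cfg) {
  outdir <- prepare_outdir(cfg)
  genome <- load_genome(cfg)
  rk <- cfg$rank
  beds <- sort(list.files(rk$panel_dir, pattern = "\\.bed$",
                          full.names = TRUE))
  if (length(beds) == 0L) stop("no BED files in panel dir: ", rk$panel_dir)
  labels <- sub("\\.bed$", "", basename(beds))
  panel <- load_inputs(cfg, stats::setNames(as.list(beds), labels), genome)
  subject <- load_inputs(cfg, list(subject = rk$subject), genome)$subject
  tab <- rank_factor_overlaps(panel, subject,
                              min_overlap_bp = cfg$common$min_overlap_bp)
  log_msg(outdir, "rank: ", nrow(tab), " factors; top = ",
          tab$factor_label[1L])
  write_tsv(tab, file.path(outdir, "ranking.tsv"))
  invisible(tab)
}

#' Run the `classify` pipeline step
#'
#' Classifies sites into enhancer states and writes the calls as a TSV
#' sidecar plus BED; with `select_distal: true`, additionally applies
#' [select_putative_enhancer_loci()] and writes the selected subset.
#'
#' @param cfg a `run_config` whose `classify` section names `sites`,
#'   `h3k4me1`, `h3k27ac`, optional `h3k4me3`, `tss`, `select_distal`,
#'   `upstream_min_bp`.
#' @return the calls table, invisibly.
#' @export
run_classify <- function(cfg) {
  cl <- cfg$classify
  if (isTRUE(cl$select_distal) && is.null(cl$tss))
    stop("select_distal requires a tss input")
  outdir <- prepare_outdir(cfg)
  genome <- load_genome(cfg)
  paths <- list(sites = cl$sites, h3k4me1 = cl$h3k4me1,
                h3k27ac = cl$h3k27ac)
  if (!is.null(cl$h3k4me3)) paths$h3k4me3 <- cl$h3k4me3
  if (!is.null(cl$tss)) paths$tss <- cl$tss
  sets <- load_inputs(cfg, paths, genome)
  calls <- classify_enhancer_states(
    sets$sites, sets$h3k4me1, sets$h3k27ac,
    h3k4me3 = sets$h3k4me3, tss = sets$tss,
    min_overlap_bp = cfg$common$min_overlap_bp,
    upstream_min_bp = cl$upstream_min_bp %||% 1000L)
  write_tsv(as.data.frame(calls), file.path(outdir, "enhancer_calls.tsv"))
  bed <- interval_set(calls$chrom, calls$start, calls$end,
                      name = ifelse(is.na(calls$name),
                                    sprintf("site_%05d", seq_len(nrow(calls))),
                                    calls$name),
                      score = calls$score, strand = calls$strand)
  write_bed(bed, file.path(outdir, "enhancer_calls.bed"))
  tab <- table(calls$state)
  log_msg(outdir, "classify: ", nrow(calls), " sites (",
          paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  if (isTRUE(cl$select_distal)) {
    if (is.null(cl$tss)) stop("select_distal requires a tss input")
    sel <- select_putative_enhancer_loci(calls,
                                         cl$upstream_min_bp %||% 1000L)
    write_bed(sel, file.path(outdir, "putative_enhancers.bed"))
    log_msg(outdir, "classify: selected ", nrow(sel),
            " putative distal enhancer loci")
  }
  invisible(calls)
}

#' Run the `filter-peaks` pipeline step
#'
#' Reads a MACS-style peak table, applies the configured thresholds and
#' writes the retained peaks as BED.
#'
#' @param cfg a `run_config` whose `filter_peaks` section names `peaks`
#'   (path), optional `dialect`, `columns`, `min_score`, `min_fold`,
#'   `max_fdr`.
#' @return the filtered [interval_set()], invisibly.
#' @export
run_filter_peaks <- function(cfg) {
  outdir <- prepare_outdir(cfg)
  fp <- cfg$filter_peaks
  args <- list(path = fp$peaks)
  if (!is.null(fp$dialect)) args$dialect <- fp$dialect
  if (!is.null(fp$columns)) args$columns <- fp$columns
  peaks <- do.call(read_macs_peaks, args)
  out <- filter_peaks(peaks, min_score = fp$min_score,
                      min_fold = fp$min_fold, max_fdr = fp$max_fdr)
  log_msg(outdir, "filter-peaks: retained ", nrow(out), " of ",
          nrow(peaks), " peaks (", attr(out, "label"), ")")
  write_bed(out, file.path(outdir, "filtered_peaks.bed"))
  invisible(out)
}

# Numeric report formatting: fractions to 4 decimals, percents as
# integers, p-values in scientific notation with 4 significant digits.
format_report <- function(report) {
  out <- report
  out$fraction <- sprintf("%.4f", report$fraction)
  out$null_mean <- sprintf("%.4f", report$null_mean)
  out$null_sd <- sprintf("%.4f", report$null_sd)
  out$z <- sprintf("%.4f", report$z)
  out$p_enrich <- sprintf("%.4g", report$p_enrich)
  out$p_deplete <- sprintf("%.4g", report$p_deplete)
  out
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# TSV and JSON carry identical fields; TSV is formatted for reading,
# JSON keeps full numeric precision.
write_report <- function(report, outdir, stem) {
  write_tsv(format_report(report), file.path(outdir, paste0(stem, ".tsv")))
  jsonlite::write_json(report, file.path(outdir, paste0(stem, ".json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
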