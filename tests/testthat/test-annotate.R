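test_that("enhancer states follow the mark-combination rule", {
  g <- genome_model(c(chrA = 100000))
  me1 <- interval_set("chrA", c(1000, 5000), c(2000, 6000))
  ac <- interval_set("chrA", 5200, 5800)
  me3 <- interval_set("chrA", 9000, 9500)
  sites <- interval_set(rep("chrA", 4),
                        c(1200, 5300, 9100, 20000),
                        c(1400, 5500, 9200, 20200),
                        name = c("me1_only", "me1_ac", "me3_only", "naked"))
  calls <- classify_enhancer_states(sites, me1, ac, h3k4me3 = me3)
  expect_equal(calls$state,
               c("enhancer", "active_enhancer", "none", "none"))
  expect_equal(calls$has_H3K4me3, c(FALSE, FALSE, TRUE, FALSE))
  # states partition the sites
  expect_equal(sum(table(calls$state)), nrow(sites))
})

test_that("state partition holds on random fixtures", {
  set.seed(12)
  g <- small_genome()
  for (rep in 1:10) {
    sites <- random_intervals(80, g)
    me1 <- random_intervals(30, g)
    ac <- random_intervals(30, g)
    calls <- classify_enhancer_states(sites, me1, ac)
    n <- table(factor(calls$state,
                      c("active_enhancer", "enhancer", "none")))
    expect_equal(sum(n), 80)
    expect_equal(calls$state == "active_enhancer",
                 calls$has_H3K4me1 & calls$has_H3K27ac)
    expect_equal(calls$state == "enhancer",
                 calls$has_H3K4me1 & !calls$has_H3K27ac)
  }
})

test_that("distal enhancer selection applies the >1 kb upstream rule", {
  g <- genome_model(c(chrA = 100000))
  tss <- interval_set("chrA", 50000, 50001, name = "geneA", strand = "+")
  me1 <- interval_set("chrA", 40000, 50000)
  me3 <- interval_set("chrA", 48900, 49300)
  sites <- interval_set(rep("chrA", 4),
                        c(44550, 49450, 49050, 51950),
                        c(44650, 49550, 49150, 52050),
                        name = c("far_up", "near_up", "promoterish", "down"))
  # midpoints: 44600 (5400 up), 49500 (500 up), 49100 (900 up, H3K4me3+),
  # 52000 (2000 downstream)
  calls <- classify_enhancer_states(sites, me1,
                                    interval_set(character(), numeric(),
                                                 numeric()),
                                    h3k4me3 = me3, tss = tss)
  sel <- select_putative_enhancer_loci(calls)
  expect_equal(sel$name, "far_up")
  expect_equal(calls$tss_distance, c(-5400, -500, -900, 2000))
  # exactly 1000 bp upstream is rejected (strict inequality)
  edge <- classify_enhancer_states(
    interval_set("chrA", 48950, 49050, name = "edge"), me1,
    interval_set(character(), numeric(), numeric()),
    h3k4me3 = interval_set(character(), numeric(), numeric()), tss = tss)
  expect_equal(edge$tss_distance, -1000)
  expect_equal(nrow(select_putative_enhancer_loci(edge)), 0L)
  # missing annotation is an error
  bare <- classify_enhancer_states(sites, me1,
                                   interval_set(character(), numeric(),
                                                numeric()))
  expect_error(select_putative_enhancer_loci(bare), "H3K4me3")
})

test_that("factor ranking orders by fraction with competition ties", {
  g <- small_genome()
  set.seed(30)
  s <- random_intervals(40, g, max_width = 600)
  panel <- list(
    self = s,
    none = plant_enriched_query(s, g, 50, 0, list(median = 100, sdlog = 0.3),
                                seed = 3),
    half = plant_enriched_query(s, g, 50, 0.5, list(median = 100, sdlog = 0.3),
                                seed = 4)
  )
  tab <- rank_factor_overlaps(panel, s)
  expect_equal(tab$factor_label, c("self", "half", "none"))
  expect_equal(tab$rank, c(1L, 2L, 3L))
  expect_equal(tab$fraction, c(1.0, 0.5, 0.0))
  # duplicated factor: tied fractions share rank 1, next rank skips to 3
  tab2 <- rank_factor_overlaps(list(a = s, b = s, c = panel$none), s)
  expect_equal(tab2$rank, c(1L, 1L, 3L))
  expect_error(rank_factor_overlaps(
    list(bad = interval_set(character(), numeric(), numeric())), s), "bad")
})

test_that("a 19-member planted panel is recovered in planted order", {
  spec <- synthetic_spec(seed = 77, n_query = 150L, n_subject = 80L,
                         genome = c(chr1 = 2e6, chr2 = 1e6))
  g <- generate_genome(spec)
  s <- generate_feature_set(g, spec$n_subject, spec$subject_width_law,
                            seed = 9)
  panel <- generate_factor_panel(s, g, spec, n_sites = 150L)
  expect_length(panel, 19L)
  tab <- rank_factor_overlaps(panel, s)
  expect_equal(tab$factor_label[1], "KMT2D")
  expect_equal(tab$rank[1], 1L)
  planted <- sort(spec$factor_fractions, decreasing = TRUE)
  expect_equal(tab$factor_label, names(planted))
  expect_equal(tab$fraction, unname(round(planted * 150) / 150))
})

test_that("peak filtering applies all supplied thresholds", {
  set.seed(50)
  n <- 1000
  peaks <- data.frame(chrom = "chr1", start = seq_len(n) * 100,
                      end = seq_len(n) * 100 + 50,
                      score = round(runif(n, 0, 500), 1),
                      fold_enrichment = round(runif(n, 1, 60), 2),
                      fdr = round(runif(n, 0, 25), 3))
  class(peaks) <- c("peak_records", "data.frame")
  out <- filter_peaks(peaks, min_score = 200, min_fold = 10, max_fdr = 5)
  keep <- peaks$score >= 200 & peaks$fold_enrichment >= 10 & peaks$fdr <= 5
  expect_equal(nrow(out), sum(keep))  # independent linear scan
  expect_equal(out$start, peaks$start[keep])
  expect_match(attr(out, "label"), "score>=200")
  # thresholds below every record keep everything
  expect_equal(nrow(filter_peaks(peaks, min_score = -1)), n)
  # threshold at the maximum keeps only the argmax record(s)
  expect_equal(nrow(filter_peaks(peaks, min_score = max(peaks$score))),
               sum(peaks$score == max(peaks$score)))
  expect_error(filter_peaks(peaks), "at least one")
  peaks$fold_enrichment <- NULL
  expect_error(filter_peaks(peaks, min_fold = 5), "fold_enrichment")
})

test_that("MACS-style tables are read with dialect-aware coordinates", {
  f <- withr::local_tempfile(fileext = ".xls")
  writeLines(c("chr\tstart\tend\tscore\tfold_enrichment\tFDR",
               "chr1\t101\t200\t310.5\t22.1\t0.8",
               "chr2\t501\t700\t55.0\t3.3\t12.0"), f)
  p1 <- read_macs_peaks(f, dialect = "macs1")
  expect_equal(p1$start, c(100, 500))  # converted to 0-based half-open
  expect_equal(p1$end, c(200, 700))
  p0 <- read_macs_peaks(f, dialect = "bed0")
  expect_equal(p0$start, c(101, 501))
  expect_equal(p1$fdr, c(0.8, 12.0))
  out <- filter_peaks(p1, max_fdr = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$chrom, "chr1")
  # missing required column
  writeLines(c("chromosome\tbeg\tend", "chr1\t1\t2"), f)
  expect_error(read_macs_peaks(f), "chr")
})
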