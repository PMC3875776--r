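test_that("interval_set enforces its coordinate invariants", {
  expect_error(interval_set("chr1", -5, 10), "start")
  expect_error(interval_set("chr1", 10, 10), "end > start")
  expect_error(interval_set("chr1", 10, 5), "end > start")
  expect_error(interval_set("chr1", 1.5, 7), "integer")
  expect_error(interval_set("chr1", 0, 10, strand = "x"), "strand")
  g <- genome_model(c(chr1 = 100))
  expect_error(interval_set("chr2", 0, 10, genome = g), "absent")
  expect_error(interval_set("chr1", 0, 150, genome = g), "beyond")
  ok <- interval_set("chr1", 0, 100, genome = g)
  expect_equal(nrow(ok), 1L)
})

test_that("genome_model rejects bad chromosome tables", {
  expect_error(genome_model(c(100, 200)), "named")
  expect_error(genome_model(c(chrA = 100, chrA = 50)), "duplicate")
  expect_error(genome_model(c(chrA = 0)), "positive")
  g <- genome_model(c(chrA = 900, chrB = 100))
  expect_equal(genome_length(g), 1000)
  expect_equal(placeable_length(g), 1000)
  g2 <- genome_model(c(chrA = 900, chrB = 100),
                     excluded = interval_set("chrA", 0, 400))
  expect_equal(placeable_length(g2), 600)
})

test_that("BED round-trip is the identity on sorted records", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo",
               "# a comment",
               "chr1\t100\t250\tpeak1\t57\t+",
               "chr1\t10\t40"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 2L)
  expect_equal(x$start, c(100, 10))
  expect_equal(x$name[1], "peak1")
  expect_equal(x$score[1], 57)
  expect_equal(x$strand[1], "+")
  expect_true(is.na(x$name[2]))

  # empty file
  f0 <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), f0)
  expect_equal(nrow(read_bed(f0)), 0L)

  # random records survive write -> read exactly
  set.seed(42)
  g <- small_genome()
  s <- random_intervals(500, g)
  s$name <- sprintf("iv%03d", seq_len(nrow(s)))
  s$score <- round(runif(nrow(s), 0, 100), 0)
  s$strand <- sample(c("+", "-", "."), nrow(s), replace = TRUE)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, f2)
  back <- read_bed(f2)
  ss <- sort_intervals(s)
  expect_equal(back$chrom, ss$chrom)
  expect_equal(back$start, ss$start)
  expect_equal(back$end, ss$end)
  expect_equal(back$name, ss$name)
  expect_equal(back$score, ss$score)
  expect_equal(back$strand, ss$strand)
})

test_that("malformed BED lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\tten\t30"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t10\t20", "chr1\t50\t30"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t10"), f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr9\t10\t20"), f)
  expect_error(read_bed(f, genome = small_genome()), "chr9")
})

test_that("chrom.sizes reader validates and sums correctly", {
  f <- withr::local_tempfile(fileext = ".chrom.sizes")
  writeLines("chrA\t1000000", f)
  g <- read_chrom_sizes(f)
  expect_equal(unname(g$chromosomes["chrA"]), 1e6)

  writeLines(c("chrA\t1000", "chrA\t500"), f)
  expect_error(read_chrom_sizes(f), "duplicate")
  writeLines(c("chrA\t1000", "chrB\t-5"), f)
  expect_error(read_chrom_sizes(f), "positive")

  lens <- c(123456, 789, 3456)
  writeLines(sprintf("chr%d\t%d", 1:3, lens), f)
  expect_equal(genome_length(read_chrom_sizes(f)), sum(lens))
})

test_that("merge_intervals joins overlapping and book-ended runs", {
  m <- merge_intervals(interval_set(c("chr1", "chr1"), c(10, 15), c(20, 30)))
  expect_equal(m$start, 10)
  expect_equal(m$end, 30)
  # book-ended half-open intervals join at max_gap = 0
  m2 <- merge_intervals(interval_set(c("chr1", "chr1"), c(10, 20), c(20, 30)))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$end, 30)
  # gap of 5 joins only with max_gap >= 5
  x <- interval_set(c("chr1", "chr1"), c(10, 25), c(20, 30))
  expect_equal(nrow(merge_intervals(x, max_gap = 4)), 2L)
  expect_equal(nrow(merge_intervals(x, max_gap = 5)), 1L)
})

test_that("merge preserves covered bases exactly (bitmap oracle)", {
  set.seed(7)
  g <- small_genome()
  for (rep in 1:20) {
    x <- random_intervals(1000, g)
    m <- merge_intervals(x)
    for (cn in names(g$chromosomes)) {
      expect_identical(coverage_bitmap(m, cn, g$chromosomes[[cn]]),
                       coverage_bitmap(x, cn, g$chromosomes[[cn]]))
    }
    # merged set is strictly disjoint and sorted
    same <- m$chrom[-1L] == m$chrom[-nrow(m)]
    expect_true(all(m$start[-1L][same] > m$end[-nrow(m)][same]))
  }
})

test_that("count_overlapping follows the half-open convention", {
  q <- interval_set("chr1", 10, 20)
  expect_equal(count_overlapping(q, interval_set("chr1", 15, 30))$n_overlapping, 1L)
  # book-ended: no shared base
  expect_equal(count_overlapping(q, interval_set("chr1", 20, 30))$n_overlapping, 0L)
  # empty subject allowed, empty query is not
  empty <- interval_set(character(), numeric(), numeric())
  expect_equal(count_overlapping(q, empty)$n_overlapping, 0L)
  expect_error(count_overlapping(empty, q), "empty")
  # a query spanning two abutting subject records counts once
  s2 <- interval_set(c("chr1", "chr1"), c(8, 12), c(12, 18))
  expect_equal(count_overlapping(q, s2)$n_overlapping, 1L)
})

test_that("count_overlapping matches the brute-force oracle", {
  set.seed(13)
  g <- small_genome()
  for (rep in 1:300) {
    q <- random_intervals(sample.int(50, 1), g)
    s <- random_intervals(sample.int(50, 1), g, max_width = 800)
    minbp <- sample(c(1, 1, 1, 5, 50), 1)
    got <- count_overlapping(q, s, min_overlap_bp = minbp)
    expect_identical(got$n_overlapping,
                     brute_overlap_count(q, s, g, minbp))
    expect_equal(got$fraction, got$n_overlapping / got$n_query)
  }
})

test_that("n_overlapping is monotone non-increasing in min_overlap_bp", {
  set.seed(21)
  g <- small_genome()
  for (rep in 1:25) {
    q <- random_intervals(40, g)
    s <- random_intervals(40, g)
    counts <- vapply(c(1, 2, 5, 10, 25, 100), function(m)
      count_overlapping(q, s, min_overlap_bp = m)$n_overlapping, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("full-genome subject gives fraction 1 for any query", {
  set.seed(3)
  g <- small_genome()
  whole <- interval_set(names(g$chromosomes), 0, g$chromosomes)
  for (rep in 1:5) {
    q <- random_intervals(30, g)
    expect_equal(count_overlapping(q, whole)$fraction, 1.0)
  }
})

test_that("overlap counts agree with GenomicRanges on random instances", {
  skip_if_not_installed("GenomicRanges")
  set.seed(31)
  g <- small_genome()
  for (rep in 1:50) {
    q <- random_intervals(40, g)
    s <- random_intervals(40, g)
    gq <- GenomicRanges::GRanges(q$chrom,
                                 IRanges::IRanges(q$start + 1, q$end))
    gs <- GenomicRanges::reduce(GenomicRanges::GRanges(
      s$chrom, IRanges::IRanges(s$start + 1, s$end)))
    expect_identical(count_overlapping(q, s)$n_overlapping,
                     sum(GenomicRanges::countOverlaps(gq, gs) > 0))
  }
})

test_that("percent formatting rounds half-up", {
  s <- function(k, n) structure(list(n_query = n, n_overlapping = k,
                                     fraction = k / n, min_overlap_bp = 1L),
                                class = "overlap_summary")
  expect_equal(overlap_fraction_percent(s(1403, 1605)), 87L)
  expect_equal(overlap_fraction_percent(s(1207, 1605)), 75L)
  expect_equal(overlap_fraction_percent(s(0, 10)), 0L)
  expect_equal(overlap_fraction_percent(s(10, 10)), 100L)
  expect_equal(overlap_fraction_percent(0.125), 13L)  # half-up, not banker's
  expect_equal(overlap_fraction_percent(0.865), 87L)
})

test_that("nearest TSS distance follows the midpoint/sign conventions", {
  tss <- interval_set("chr1", 10000, 10001, name = "CARD10_like", strand = "+")
  region <- interval_set("chr1", 4550, 4650)  # midpoint 4600
  nd <- nearest_feature_distance(region, tss)
  expect_equal(nd$distance, -5400)
  expect_equal(nd$feature, "CARD10_like")
  # midpoint at the TSS
  at <- interval_set("chr1", 9950, 10050)
  expect_equal(nearest_feature_distance(at, tss)$distance, 0)
  # minus-strand TSS flips the sign: region beyond the TSS is upstream
  tssm <- interval_set("chr1", 10000, 10001, name = "g", strand = "-")
  expect_equal(nearest_feature_distance(interval_set("chr1", 11950, 12050),
                                        tssm)$distance, -2000)
  # no feature on the chromosome: flagged NA, not an error
  far <- interval_set("chr2", 0, 100)
  expect_true(is.na(nearest_feature_distance(far, tss)$distance))
})

test_that("nearest TSS agrees with the exhaustive all-pairs oracle", {
  set.seed(17)
  g <- small_genome()
  tss <- generate_tss_catalog(g, 100, seed = 5)
  regions <- random_intervals(50, g)
  got <- nearest_feature_distance(regions, tss)
  for (i in seq_len(nrow(regions))) {
    want <- brute_nearest(regions[i, ], tss)
    expect_equal(got$distance[i], want$distance)
    expect_equal(got$feature[i], want$feature)
  }
})

test_that("chromosome-name normalization adds and strips the chr prefix", {
  x <- interval_set(c("1", "chr2"), c(0, 0), c(10, 10))
  expect_equal(normalize_chrom_names(x, "chr")$chrom, c("chr1", "chr2"))
  expect_equal(normalize_chrom_names(x, "plain")$chrom, c("1", "2"))
  g <- genome_model(c(`1` = 100, `2` = 200))
  expect_equal(names(normalize_chrom_names(g, "chr")$chromosomes),
               c("chr1", "chr2"))
  # mismatched naming without normalization is an error, not zero overlap
  q <- interval_set("1", 0, 10)
  expect_error(validate_interval_set(q, genome = genome_model(c(chr1 = 100))),
               "absent")
})
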