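# Reading, filtering and combining per-CpG methylation calls.

test_that("ratios follow the pooled-count rule and the coverage filter", {
  tr <- cpg_track(tibble::tibble(chrom = "chr1", pos = c(10L, 50L, 90L),
                                 meth = c(3L, 2L, 10L),
                                 unmeth = c(2L, 2L, 0L)))
  expect_equal(tr$ratio, c(0.6, NA, 1.0))  # 2+2 = 4 reads < 5 -> NA
  expect_equal(tr$depth, c(5L, 4L, 10L))
})

test_that("opposite-strand records of one dyad collapse into one site", {
  # forward C at 100 (4 meth / 1 unmeth), reverse C at 101 (1 / 4)
  tr <- cpg_track(tibble::tibble(chrom = "chr1", pos = c(100L, 101L, 300L),
                                 meth = c(4L, 1L, 5L),
                                 unmeth = c(1L, 4L, 0L)))
  expect_equal(nrow(tr), 2)
  expect_equal(tr$pos, c(100L, 300L))
  expect_equal(tr$ratio[1], 5 / 10)
  # pre-collapsed tracks pass through unchanged (no positions 1 bp apart)
  tr2 <- cpg_track(tibble::tibble(chrom = "chr1", pos = c(100L, 102L),
                                  meth = c(5L, 5L), unmeth = c(0L, 5L)))
  expect_equal(tr2$pos, c(100L, 102L))
})

test_that("negative counts and malformed rows are rejected, unsorted input is sorted", {
  expect_error(cpg_track(tibble::tibble(chrom = "chr1", pos = 1L,
                                        meth = -1L, unmeth = 3L)),
               "negative")
  unsorted <- cpg_track(tibble::tibble(chrom = "chr1", pos = c(500L, 10L),
                                       meth = c(5L, 5L), unmeth = c(0L, 0L)))
  expect_equal(unsorted$pos, c(10L, 500L))

  bad <- tempfile(fileext = ".cov")
  writeLines(c("chr1\t11\t11\t60\t3\t2", "chr1\tnot_a_number\t12\t50\t1\t1"),
             bad)
  expect_error(read_cpg_table(bad, "bismark_cov"), "line")
})

test_that("both file dialects read to the same track, gzip included", {
  # same site: bismark is 1-based, bedgraph 0-based
  cov <- tempfile(fileext = ".cov.gz")
  readr::write_tsv(tibble::tibble(chrom = "chr1", start = c(11L, 101L),
                                  end = c(11L, 101L), pct = c(60, 100),
                                  meth = c(3L, 7L), unmeth = c(2L, 0L)),
                   cov, col_names = FALSE)
  bg <- tempfile(fileext = ".bedgraph")
  readr::write_tsv(tibble::tibble(chrom = "chr1", start = c(10L, 100L),
                                  end = c(11L, 101L),
                                  meth = c(3L, 7L), unmeth = c(2L, 0L)),
                   bg, col_names = FALSE)
  t1 <- read_cpg_table(cov, "bismark_cov")
  t2 <- read_cpg_table(bg, "bedgraph_counts")
  expect_equal(t1$pos, c(10L, 100L))
  expect_equal(t1[c("chrom", "pos", "meth", "unmeth", "ratio")],
               t2[c("chrom", "pos", "meth", "unmeth", "ratio")])
})

test_that("write/read round-trip preserves (chrom, pos, ratio)", {
  tr <- combine_replicates(list(make_track(c(0.4, 0.8)),
                                make_track(c(0.6, 0.8))),
                           mode = "average_ratios")
  path <- tempfile(fileext = ".tsv")
  write_cpg_table(tr, path)
  back <- read_cpg_table(path, "canonical")
  expect_equal(back[c("chrom", "pos", "ratio")],
               tr[c("chrom", "pos", "ratio")])
})

test_that("average_ratios averages per-replicate ratios over passing replicates", {
  a <- make_track(c(0.4, 0.5), depth = 10)
  b <- make_track(c(0.6, 0.5), depth = 10)
  comb <- combine_replicates(list(a, b), mode = "average_ratios")
  expect_equal(comb$ratio[1], 0.5)
  # k identical tracks average to any one of them
  comb3 <- combine_replicates(list(a, a, a), mode = "average_ratios")
  expect_equal(comb3$ratio, a$ratio)
  # a replicate failing coverage does not drag the site's mean
  lo <- cpg_track(tibble::tibble(chrom = "chr1", pos = 0L,
                                 meth = 0L, unmeth = 2L))
  hi <- cpg_track(tibble::tibble(chrom = "chr1", pos = 0L,
                                 meth = 8L, unmeth = 2L))
  expect_equal(combine_replicates(list(lo, hi), "average_ratios")$ratio, 0.8)
})

test_that("sum_calls pools counts before filtering and is order-invariant", {
  a <- cpg_track(tibble::tibble(chrom = "chr1", pos = c(0L, 50L),
                                meth = c(1L, 1L), unmeth = c(9L, 1L)))
  b <- cpg_track(tibble::tibble(chrom = "chr1", pos = c(0L, 50L),
                                meth = c(3L, 1L), unmeth = c(7L, 1L)))
  ab <- combine_replicates(list(a, b), mode = "sum_calls")
  expect_equal(ab$ratio[1], 4 / 20)
  expect_true(is.na(ab$ratio[2]))  # pooled 4 reads < 5 -> dropped
  ba <- combine_replicates(list(b, a), mode = "sum_calls")
  expect_equal(ab, ba, ignore_attr = TRUE)
  expect_error(combine_replicates(list(), "sum_calls"))
})

test_that("coverage_summary is the informative fraction of the universe", {
  uni <- make_universe(100)
  full <- make_track(rep(0.5, 100), pos = uni$pos)
  expect_equal(coverage_summary(full, uni), 1.0)
  # 10 of 100 sites below the read cutoff
  ratios <- rep(0.5, 100)
  partial <- full
  partial$ratio[1:10] <- NA
  expect_equal(coverage_summary(partial, uni), 0.90)
  none <- make_track(numeric(0), pos = integer(0))
  expect_equal(coverage_summary(none, uni), 0.0)
  expect_error(coverage_summary(full, uni[0, ]), "empty")
})

test_that("track_panel validates required tissues", {
  tr <- make_track(rep(0.5, 30))
  expect_error(track_panel(list(oocyte = tr, sperm = tr)), "missing")
  p <- track_panel(list(oocyte = tr, sperm = tr, blastocyst = tr,
                        placenta = tr, liver = tr))
  expect_s3_class(p, "track_panel")
  expect_equal(attr(p, "somatic"), "liver")
  expect_error(track_panel(list(oocyte = tr, sperm = tr, blastocyst = tr,
                                placenta = tr)),
               "somatic")
})
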