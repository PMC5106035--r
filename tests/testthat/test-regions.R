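# Interval algebra: merging, fusing, CpG-aware intersection.

test_that("overlapping same-state windows merge into maximal regions", {
  uni <- make_universe(200, spacing = 10L)
  calls <- tibble::tibble(
    chrom = "chr1",
    idx = c(1L, 2L, 40L),
    start = c(0L, 150L, 600L),
    end = c(300L, 450L, 900L),
    state = c("methylated", "methylated", "methylated"))
  reg <- merge_windows(calls, uni)
  expect_equal(reg$start, c(0L, 600L))
  expect_equal(reg$end, c(450L, 900L))
  # a none window between two disjoint calls breaks nothing it shouldn't
  calls2 <- tibble::tibble(chrom = "chr1", idx = 1:3,
                           start = c(0L, 310L, 600L),
                           end = c(300L, 590L, 900L),
                           state = c("methylated", "none", "methylated"))
  expect_equal(nrow(merge_windows(calls2, uni)), 2)
  expect_error(merge_windows(calls[c(3, 1, 2), ], uni), "sorted")
})

test_that("10 consecutive step-1 windows over 34 CpGs give one region of 34 CpGs", {
  uni <- make_universe(34, spacing = 50L)
  tr <- make_track(rep(1, 34), pos = uni$pos)
  calls <- classify_windows(slide_windows(tr, uni), "gamete")
  expect_equal(nrow(calls), 10)
  expect_true(all(calls$state == "methylated"))
  reg <- merge_windows(calls, uni)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_cpgs, 34L)
  expect_equal(reg$start, uni$pos[1])
  expect_equal(reg$end, uni$pos[34] + 1L)
})

test_that("fusing joins touching regions, keeps gapped ones, and is idempotent", {
  uni <- make_universe(100, spacing = 10L)
  touching <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                             end = c(100L, 200L), state = "intermediate")
  expect_equal(fuse_regions(touching, uni)$end, 200L)
  gapped <- tibble::tibble(chrom = "chr1", start = c(0L, 150L),
                           end = c(100L, 200L), state = "intermediate")
  expect_equal(nrow(fuse_regions(gapped, uni)), 2)

  set.seed(11)
  for (i in 1:20) {
    x <- random_regions(sample(1:30, 1))
    once <- fuse_regions(x)
    twice <- fuse_regions(once)
    expect_equal(once, twice)
  }
})

test_that("merge and fuse match the naive all-pairs oracle on random fixtures", {
  set.seed(23)
  for (i in 1:40) {
    x <- random_regions(sample(2:40, 1))
    got <- fuse_regions(x)[, c("chrom", "start", "end")]
    want <- tibble::as_tibble(oracle_merge(as.data.frame(x)))
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("merged output conserves CpG coverage of the input windows", {
  set.seed(31)
  uni <- make_universe(500, spacing = 20L)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    starts <- sort(sample(uni$pos, n))
    calls <- tibble::tibble(chrom = "chr1", idx = seq_len(n),
                            start = starts,
                            end = starts + sample(50:500, n, replace = TRUE),
                            state = "methylated")
    reg <- merge_windows(calls, uni)
    in_any_window <- unique(unlist(lapply(seq_len(n), function(j) {
      uni$pos[uni$pos >= calls$start[j] & uni$pos < calls$end[j]]
    })))
    expect_equal(sum(reg$n_cpgs), length(in_any_window))
    # non-overlapping per state
    if (nrow(reg) > 1) {
      expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
    }
  }
})

test_that("opposing_overlap returns the intersection with its CpG count, symmetrically", {
  # 26 CpGs at 2000, 2100, ..., 4500 — all inside [2000, 5000)
  uni <- tibble::tibble(chrom = "chr1",
                        pos = as.integer(seq(2000L, 4500L, by = 100L)))
  a <- tibble::tibble(chrom = "chr1", start = 1000L, end = 5000L)
  b <- tibble::tibble(chrom = "chr1", start = 2000L, end = 6000L)
  ab <- opposing_overlap(a, b, uni)
  expect_equal(ab$start, 2000L)
  expect_equal(ab$end, 5000L)
  expect_equal(ab$shared_cpgs, 26L)
  ba <- opposing_overlap(b, a, uni)
  expect_equal(ab, ba)

  disjoint <- opposing_overlap(a, tibble::tibble(chrom = "chr1",
                                                 start = 7000L, end = 8000L),
                               uni)
  expect_equal(nrow(disjoint), 0)

  same <- opposing_overlap(a, a, uni)
  expect_equal(same$shared_cpgs, sum(uni$pos >= 1000 & uni$pos < 5000))
})

test_that("region means average the track's informative sites inside the interval", {
  uni <- make_universe(10, spacing = 100L)
  tr <- make_track(c(rep(0.2, 5), rep(0.8, 5)), pos = uni$pos)
  reg <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L)
  expect_equal(region_means(reg, tr), 0.2)
  reg2 <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(region_means(reg2, tr), 0.5)
  # missing ratios are absent, not zero
  tr$ratio[1:5] <- NA
  expect_equal(region_means(reg2, tr), 0.8)
  expect_true(is.na(region_means(reg, tr)))
})

test_that("BED round trip preserves coordinates and state", {
  reg <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0L, 500L),
                        end = c(100L, 900L),
                        state = c("methylated", "unmethylated"),
                        mean = c(0.95, 0.05))
  path <- tempfile(fileext = ".bed")
  write_regions_bed(reg, path)
  back <- read_bed_features(path)
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
  expect_equal(back$name, reg$state)
})
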