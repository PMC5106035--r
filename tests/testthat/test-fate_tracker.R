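# Persistence tracking and fate classification of gDMRs.

test_that("partial_regions recovers a planted intermediate island", {
  uni <- make_universe(200, spacing = 50L)
  ratios <- rep(0.95, 200)
  ratios[81:140] <- 0.5  # 60-CpG island
  tr <- make_track(ratios, pos = uni$pos)
  reg <- partial_regions(tr, uni)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$state, "intermediate")
  # recovered within one window span of the planted island
  expect_lt(abs(reg$start - uni$pos[81]), 25 * 50)
  expect_lt(abs(reg$end - (uni$pos[140] + 1)), 25 * 50)

  flat_high <- make_track(rep(0.95, 200), pos = uni$pos)
  expect_equal(nrow(partial_regions(flat_high, uni)), 0)
  flat_half <- make_track(rep(0.5, 200), pos = uni$pos)
  one <- partial_regions(flat_half, uni)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_cpgs, 200L)
})

test_that("tissue regions of 500 bp or less never count toward persistence", {
  g <- tibble::tibble(chrom = "chr1", start = 1000L, end = 3000L,
                      origin = "maternal")
  short_reg <- tibble::tibble(chrom = "chr1", start = 1100L, end = 1600L,
                              state = "intermediate")  # exactly 500 bp
  long_reg <- tibble::tibble(chrom = "chr1", start = 1100L, end = 3100L,
                             state = "intermediate")
  none <- short_reg[0, ]
  pm <- persistence_matrix(g, list(blastocyst = long_reg, placenta = none,
                                   liver = short_reg))
  expect_true(pm$is_partial[pm$tissue == "blastocyst"])
  expect_false(pm$is_partial[pm$tissue == "liver"])
  # one bp longer and it counts
  pm2 <- persistence_matrix(
    g, list(blastocyst = long_reg, placenta = none,
            liver = dplyr::mutate(short_reg, end = end + 1L)))
  expect_true(pm2$is_partial[pm2$tissue == "liver"])

  expect_error(persistence_matrix(g, list(blastocyst = long_reg)),
               "placenta")
})

test_that("fate rules follow the blastocyst/placenta/somatic flag logic", {
  flags <- function(blast, plac, n_somatic, n_panel = 14) {
    somatic <- sprintf("somatic_%02d", seq_len(n_panel))
    tibble::tibble(
      gdmr_id = 1L, chrom = "chr1", start = 0L, end = 1000L,
      origin = "maternal",
      tissue = c("blastocyst", "placenta", somatic),
      is_partial = c(blast, plac,
                     seq_len(n_panel) <= n_somatic))
  }
  fate_of <- function(...) classify_fate(
    flags(...), somatic = sprintf("somatic_%02d", 1:14))$fate

  expect_equal(fate_of(TRUE, FALSE, 13), "ubiquitous_candidate")
  expect_equal(fate_of(TRUE, TRUE, 12), "ubiquitous_candidate")
  expect_equal(fate_of(TRUE, TRUE, 11), "tissue_restricted")
  expect_equal(fate_of(TRUE, TRUE, 0), "placenta_specific")
  expect_equal(fate_of(TRUE, FALSE, 0), "other")
  expect_equal(fate_of(FALSE, TRUE, 14), "reprogrammed_preimplantation")
})

test_that("fate categories are mutually exclusive and exhaustive over the flag space", {
  somatic <- sprintf("somatic_%02d", 1:14)
  combos <- expand.grid(blast = c(TRUE, FALSE), plac = c(TRUE, FALSE),
                        n_som = 0:14)
  fates <- vapply(seq_len(nrow(combos)), function(i) {
    pm <- tibble::tibble(
      gdmr_id = 1L, chrom = "chr1", start = 0L, end = 1000L,
      origin = "maternal",
      tissue = c("blastocyst", "placenta", somatic),
      is_partial = c(combos$blast[i], combos$plac[i],
                     seq_len(14) <= combos$n_som[i]))
    classify_fate(pm, somatic)$fate
  }, character(1))
  expect_true(all(fates %in% c("reprogrammed_preimplantation",
                               "ubiquitous_candidate", "placenta_specific",
                               "tissue_restricted", "other")))
  expect_length(fates, nrow(combos))  # exactly one fate per combination
  # invariants
  expect_true(all(fates[!combos$blast] == "reprogrammed_preimplantation"))
  expect_true(all(fates[combos$blast & combos$n_som >= 12] ==
                    "ubiquitous_candidate"))
  expect_true(all(fates[combos$blast & combos$plac & combos$n_som == 0] ==
                    "placenta_specific"))
})

test_that("the somatic threshold scales as ceiling(12/14 * N) for other panels", {
  somatic7 <- sprintf("s%02d", 1:7)
  pm <- tibble::tibble(
    gdmr_id = 1L, chrom = "chr1", start = 0L, end = 1000L,
    origin = "maternal",
    tissue = c("blastocyst", "placenta", somatic7),
    is_partial = c(TRUE, FALSE, seq_len(7) <= 6))
  expect_equal(classify_fate(pm, somatic7)$fate, "ubiquitous_candidate")
  pm$is_partial <- c(TRUE, FALSE, seq_len(7) <= 5)  # 5 < ceiling(6) = 6
  expect_equal(classify_fate(pm, somatic7)$fate, "tissue_restricted")
})

test_that("heatmap states reproduce per-tissue tile calls, ordered by placenta", {
  uni <- make_universe(60, spacing = 50L)
  mk <- function(r) make_track(rep(r, 60), pos = uni$pos, tissue = NULL)
  panel <- track_panel(list(oocyte = mk(0.95), sperm = mk(0.05),
                            blastocyst = mk(0.5), placenta = mk(0.5),
                            liver = mk(0.05)))
  g <- tibble::tibble(chrom = "chr1", start = 0L, end = 3000L,
                      origin = "maternal")
  hm <- fate_heatmap_states(g, panel)
  expect_equal(hm$state[hm$tissue == "placenta"], "intermediate")
  expect_equal(hm$state[hm$tissue == "liver"], "hypo")
  expect_equal(hm$state[hm$tissue == "oocyte"], "hyper")
})
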