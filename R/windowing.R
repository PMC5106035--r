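# 25-CpG sliding windows and their methylation-state classification.
#
# Windows are framed on the CpG universe (the union of CpG positions across
# the panel), not on each sample's covered sites, so that window k means the
# same genomic interval in every tissue. A sample contributes its ratio at
# the universe sites it covers; a window is informative for that sample when
# at least `informative_min` of its member CpGs carry a ratio.

#' Slide fixed-CpG windows over a track
#'
#' Builds windows of `window_cpgs` consecutive universe CpGs per chromosome
#' and summarises the track's methylation ratios within each: the number of
#' informative CpGs, their mean and their standard deviation. Mean and SD
#' are `NA` where fewer than `informative_min` member CpGs carry a ratio.
#' Windows never span chromosomes and trailing partial windows are dropped.
#'
#' @param track A track tibble ([cpg_track()]).
#' @param universe CpG frame from [cpg_universe()].
#' @param window_cpgs Window size in CpGs (default 25).
#' @param step Slide step in CpGs; 1 (default) gives maximally overlapping
#'   windows, larger values trade resolution for speed.
#' @param informative_min Minimum informative CpGs for mean/SD (default 10).
#' @param sd_type `"sample"` (n−1 denominator, default) or `"population"`.
#'   Threshold crossings near the classification boundaries can depend on
#'   this choice, so it is explicit.
#' @return A tibble with one row per window: `chrom`, `idx` (1-based index
#'   of the first member CpG in the chromosome's universe list), `start`,
#'   `end` (0-based half-open span from the first member CpG to one past the
#'   last), `n_informative`, `mean`, `sd`.
#' @export
slide_windows <- function(track, universe, window_cpgs = 25, step = 1,
                          informative_min = 10,
                          sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(window_cpgs >= 1, step >= 1,
            informative_min >= 1, informative_min <= window_cpgs)

  frame <- universe %>%
    left_join(track %>% select("chrom", "pos", "ratio"),
              by = c("chrom", "pos"))

  out <- frame %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      windows_one_chrom(d$pos, d$ratio, window_cpgs, step,
                        informative_min, sd_type)
    }) %>%
    ungroup()
  out
}

windows_one_chrom <- function(pos, ratio, w, step, inf_min, sd_type) {
  m <- length(pos)
  if (m < w) {
    return(tibble(idx = integer(), start = integer(), end = integer(),
                  n_informative = integer(), mean = double(), sd = double()))
  }
  starts <- seq.int(1L, m - w + 1L, by = step)
  ok <- !is.na(ratio)
  r0 <- ifelse(ok, ratio, 0)
  cn <- c(0L, cumsum(ok))
  cs <- c(0, cumsum(r0))
  cq <- c(0, cumsum(r0^2))
  ends <- starts + w - 1L
  n <- cn[ends + 1L] - cn[starts]
  s <- cs[ends + 1L] - cs[starts]
  q <- cq[ends + 1L] - cq[starts]
  mu <- ifelse(n >= inf_min, s / n, NA_real_)
  ss <- q - s^2 / pmax(n, 1L)
  ss <- pmax(ss, 0)  # guard against negative rounding residue
  denom <- if (sd_type == "sample") pmax(n - 1L, 1L) else pmax(n, 1L)
  sdv <- ifelse(n >= inf_min, sqrt(ss / denom), NA_real_)
  tibble(idx = starts,
         start = pos[starts],
         end = pos[ends] + 1L,
         n_informative = as.integer(n),
         mean = mu,
         sd = sdv)
}

#' Classify windows as methylated/unmethylated or intermediate
#'
#' Two classification modes reflect the two uses of the window screen.
#' In `gamete` mode a window is called `methylated` when
#' `mean − sd > meth_min` (default 0.75) and `unmethylated` when
#' `mean + sd < unmeth_max` (default 0.25): the SD term demands that the
#' state be consistent across the window's CpGs, not just on average.
#' In `intermediate` mode a window is called `intermediate` when the whole
#' `mean ± inter_sd_mult·sd` band lies strictly inside
#' (`inter_low`, `inter_high`) (defaults 0.2, 0.8 with multiplier 1.5) —
#' the methylome signature of one methylated and one unmethylated allele.
#' All comparisons are strict; a window exactly at a boundary is `none`.
#' Windows with fewer than the informative minimum are `none`.
#'
#' @param windows Output of [slide_windows()].
#' @param mode `"gamete"` or `"intermediate"`.
#' @param meth_min,unmeth_max Gamete-mode thresholds.
#' @param inter_low,inter_high,inter_sd_mult Intermediate-mode band.
#' @return `windows` with a `state` column (`"methylated"`,
#'   `"unmethylated"`, `"intermediate"` or `"none"`).
#' @export
classify_windows <- function(windows, mode = c("gamete", "intermediate"),
                             meth_min = 0.75, unmeth_max = 0.25,
                             inter_low = 0.2, inter_high = 0.8,
                             inter_sd_mult = 1.5) {
  mode <- match.arg(mode)
  if (mode == "gamete") {
    windows %>%
      mutate(state = case_when(
        is.na(.data$mean) ~ "none",
        .data$mean - .data$sd > meth_min ~ "methylated",
        .data$mean + .data$sd < unmeth_max ~ "unmethylated",
        TRUE ~ "none"))
  } else {
    windows %>%
      mutate(state = case_when(
        is.na(.data$mean) ~ "none",
        .data$mean - inter_sd_mult * .data$sd > inter_low &
          .data$mean + inter_sd_mult * .data$sd < inter_high ~ "intermediate",
        TRUE ~ "none"))
  }
}

#' Tri-state methylation call for a region mean
#'
#' Partitions mean methylation into `hypo` (< 0.20), `hyper` (> 0.80) or
#' `intermediate` — the three tile states used to render persistence
#' heatmaps.
#'
#' @param region_mean Numeric vector of mean methylation values in `[0, 1]`.
#'   `NA` propagates.
#' @return Character vector of `"hypo"`, `"hyper"`, `"intermediate"`.
#' @export
tile_state <- function(region_mean) {
  bad <- !is.na(region_mean) & (region_mean < 0 | region_mean > 1)
  if (any(bad)) {
    abort("region means must lie in [0, 1]")
  }
  case_when(
    is.na(region_mean) ~ NA_character_,
    region_mean < 0.20 ~ "hypo",
    region_mean > 0.80 ~ "hyper",
    TRUE ~ "intermediate")
}
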