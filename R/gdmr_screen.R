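# Germline DMR calling: opposing-state overlaps between sperm and oocyte
# region sets. A maternal gDMR is oocyte-methylated x sperm-unmethylated
# (Mo x Us); a paternal gDMR is sperm-methylated x oocyte-unmethylated
# (Ms x Uo). The call requires strictly more than `min_shared_cpgs` universe
# CpGs inside the intersection, and the gDMR interval is that intersection.

#' Classified methylation regions for one gamete track
#'
#' Convenience wrapper running the full window screen for one sample:
#' sliding windows over the universe frame, state classification, merging of
#' same-state windows and fusing, with per-region mean methylation attached.
#'
#' @param track A gamete (or any) track tibble.
#' @param universe CpG frame from [cpg_universe()].
#' @param mode `"gamete"` or `"intermediate"` (see [classify_windows()]).
#' @param ... Passed to [slide_windows()] and [classify_windows()]
#'   (`window_cpgs`, `step`, `informative_min`, thresholds, ...).
#' @return Region tibble with `chrom`, `start`, `end`, `state`, `n_cpgs`,
#'   `mean`.
#' @export
classified_regions <- function(track, universe, mode = "gamete", ...) {
  dots <- list(...)
  win_args <- dots[names(dots) %in% c("window_cpgs", "step",
                                      "informative_min", "sd_type")]
  cls_args <- dots[names(dots) %in% c("meth_min", "unmeth_max", "inter_low",
                                      "inter_high", "inter_sd_mult")]
  w <- do.call(slide_windows, c(list(track, universe), win_args))
  calls <- do.call(classify_windows, c(list(w, mode = mode), cls_args))
  reg <- merge_windows(calls, universe)
  reg$mean <- region_means(reg, track)
  reg
}

#' Call germline DMRs from opposing gamete region sets
#'
#' Every oocyte-methylated region intersecting a sperm-unmethylated region
#' in strictly more than `min_shared_cpgs` universe CpGs yields a maternal
#' gDMR on the intersection; symmetrically, sperm-methylated x
#' oocyte-unmethylated yields a paternal gDMR. One region overlapping two
#' opposing partners yields two gDMRs (per-overlap CpG counts are
#' preserved). Output is coordinate-sorted and deduplicated.
#'
#' @param oocyte_regions,sperm_regions Region tibbles from
#'   [classified_regions()] (states `methylated` / `unmethylated`, with a
#'   `mean` column).
#' @param universe CpG frame; must cover every chromosome appearing in the
#'   region sets.
#' @param min_shared_cpgs Overlap gate; a call needs `shared_cpgs >` this
#'   value (default 25, strict).
#' @return A gDMR tibble: `chrom`, `start`, `end`, `origin`
#'   (`"maternal"`/`"paternal"`), `shared_cpgs`, `oocyte_mean`,
#'   `sperm_mean`.
#' @export
call_gdmrs <- function(oocyte_regions, sperm_regions, universe,
                       min_shared_cpgs = 25) {
  chroms <- unique(c(oocyte_regions$chrom, sperm_regions$chrom))
  missing_chr <- setdiff(chroms, unique(universe$chrom))
  if (length(missing_chr) > 0) {
    abort(paste0("universe has no CpGs for chromosome(s): ",
                 paste(missing_chr, collapse = ", ")))
  }
  maternal <- opposing_pairs(
    oocyte_regions %>% filter(.data$state == "methylated"),
    sperm_regions %>% filter(.data$state == "unmethylated"),
    universe, min_shared_cpgs, origin = "maternal")
  paternal <- opposing_pairs(
    sperm_regions %>% filter(.data$state == "methylated"),
    oocyte_regions %>% filter(.data$state == "unmethylated"),
    universe, min_shared_cpgs, origin = "paternal")
  bind_rows(maternal, paternal) %>%
    distinct() %>%
    arrange(.data$chrom, .data$start, .data$end)
}

# All qualifying intersections of a methylated set with an opposing
# unmethylated set. `meth` regions come from the methylated gamete; which
# gamete that is decides the origin label and which mean is which.
opposing_pairs <- function(meth, unmeth, universe, min_shared_cpgs, origin) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  origin = character(), shared_cpgs = integer(),
                  oocyte_mean = double(), sperm_mean = double())
  if (nrow(meth) == 0 || nrow(unmeth) == 0) return(empty)
  lv <- unique(c(meth$chrom, unmeth$chrom))
  gr_m <- regions_to_gr(meth, levels = lv)
  gr_u <- regions_to_gr(unmeth, levels = lv)
  hits <- GenomicRanges::findOverlaps(gr_m, gr_u)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  inter <- IRanges::pintersect(gr_m[qi], gr_u[si])
  out <- gr_to_regions(inter)
  out$shared_cpgs <- count_cpgs(out, universe)
  meth_mean <- meth$mean[qi]
  unmeth_mean <- unmeth$mean[si]
  out$origin <- origin
  if (origin == "maternal") {
    out$oocyte_mean <- meth_mean
    out$sperm_mean <- unmeth_mean
  } else {
    out$sperm_mean <- meth_mean
    out$oocyte_mean <- unmeth_mean
  }
  out %>%
    filter(.data$shared_cpgs > min_shared_cpgs) %>%
    select("chrom", "start", "end", "origin", "shared_cpgs",
           "oocyte_mean", "sperm_mean")
}

#' Summarise a gDMR set per parental origin
#'
#' @param gdmrs A gDMR tibble from [call_gdmrs()].
#' @return Tibble with one row per origin (`maternal`, `paternal`):
#'   `n` regions and `span_bp` total interval length. Origins absent from
#'   the input are reported with zeros.
#' @export
screen_summary <- function(gdmrs) {
  base <- tibble(origin = c("maternal", "paternal"))
  if (nrow(gdmrs) == 0) {
    return(base %>% mutate(n = 0L, span_bp = 0L))
  }
  tallies <- gdmrs %>%
    group_by(.data$origin) %>%
    summarise(n = dplyr::n(),
              span_bp = sum(.data$end - .data$start),
              .groups = "drop")
  base %>%
    left_join(tallies, by = "origin") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           span_bp = ifelse(is.na(.data$span_bp), 0L, .data$span_bp))
}
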