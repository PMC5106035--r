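# Interval algebra on classified windows and regions.
#
# Regions are tibbles with columns chrom, start, end (0-based half-open),
# state, n_cpgs and optionally mean. CpG counting uses half-open membership:
# a universe CpG at pos belongs to a region iff start <= pos < end.
# Merging/intersection is delegated to IRanges/GenomicRanges; tests check
# the results against naive all-pairs oracles.

# tibble (0-based half-open) <-> GRanges (1-based closed). `levels` aligns
# seqlevels across objects that will be overlapped against each other.
regions_to_gr <- function(x, levels = NULL) {
  if (is.null(levels)) levels <- unique(x$chrom)
  GenomicRanges::GRanges(factor(x$chrom, levels = levels),
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

gr_to_regions <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Count universe CpGs inside regions
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param universe CpG frame from [cpg_universe()].
#' @return Integer vector: for each region, the number of universe CpGs with
#'   `start <= pos < end`.
#' @export
count_cpgs <- function(regions, universe) {
  if (nrow(regions) == 0) return(integer())
  pos_by_chrom <- split(universe$pos, universe$chrom)
  out <- integer(nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    pos <- pos_by_chrom[[ch]]
    if (is.null(pos)) { out[i] <- 0L; next }
    out[i] <- findInterval(regions$end[i] - 1L, pos) -
      findInterval(regions$start[i] - 1L, pos)
  }
  out
}

#' Mean methylation of a track over regions
#'
#' @param regions Region tibble.
#' @param track Track tibble; only sites with a ratio contribute.
#' @return Numeric vector of per-region means (`NA` where the track has no
#'   informative site in the region).
#' @export
region_means <- function(regions, track) {
  if (nrow(regions) == 0) return(double())
  inf <- track %>% filter(!is.na(.data$ratio))
  by_chrom <- split(inf[, c("pos", "ratio")], inf$chrom)
  out <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    d <- by_chrom[[ch]]
    if (is.null(d) || nrow(d) == 0) next
    cs <- c(0, cumsum(d$ratio))
    lo <- findInterval(regions$start[i] - 1L, d$pos)
    hi <- findInterval(regions$end[i] - 1L, d$pos)
    n <- hi - lo
    out[i] <- ifelse(n > 0, (cs[hi + 1L] - cs[lo + 1L]) / n, NA_real_)
  }
  out
}

#' Merge same-state windows into regions
#'
#' Maximal runs of touching-or-overlapping windows with the same state
#' become single regions spanning from the first window's start to the last
#' window's end. `none` windows break runs and produce no region.
#'
#' @param calls Classified windows ([classify_windows()]), sorted by
#'   coordinate within each chromosome.
#' @param universe CpG frame, used to count member CpGs.
#' @return A region tibble: `chrom`, `start`, `end`, `state`, `n_cpgs`,
#'   sorted, non-overlapping within each state.
#' @export
merge_windows <- function(calls, universe) {
  srt <- calls %>%
    group_by(.data$chrom) %>%
    summarise(ok = !is.unsorted(.data$start), .groups = "drop")
  if (any(!srt$ok)) abort("window calls must be sorted by coordinate")

  kept <- calls %>% filter(.data$state != "none")
  if (nrow(kept) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  state = character(), n_cpgs = integer()))
  }
  out <- kept %>%
    group_by(.data$state) %>%
    dplyr::group_modify(function(d, key) {
      gr <- GenomicRanges::reduce(regions_to_gr(d))
      gr_to_regions(gr)
    }) %>%
    ungroup() %>%
    select("chrom", "start", "end", "state") %>%
    arrange(.data$chrom, .data$start, .data$end)
  out$n_cpgs <- count_cpgs(out, universe)
  out
}

#' Fuse consecutive same-state regions
#'
#' Regions of the same state that touch or overlap are fused into one;
#' regions separated by any gap remain distinct. Idempotent.
#'
#' @param regions Region tibble with a `state` column.
#' @param universe Optional CpG frame to recompute `n_cpgs` after fusing.
#' @return A fused region tibble, sorted.
#' @export
fuse_regions <- function(regions, universe = NULL) {
  if (nrow(regions) == 0) return(regions)
  out <- regions %>%
    group_by(.data$state) %>%
    dplyr::group_modify(function(d, key) {
      gr_to_regions(GenomicRanges::reduce(regions_to_gr(d)))
    }) %>%
    ungroup() %>%
    select("chrom", "start", "end", "state") %>%
    arrange(.data$chrom, .data$start, .data$end)
  if (!is.null(universe)) out$n_cpgs <- count_cpgs(out, universe)
  out
}

#' Intersection of two regions with shared-CpG count
#'
#' The core gDMR overlap test: the genomic intersection of two regions and
#' the number of universe CpGs strictly inside it. Symmetric in `a` and `b`.
#'
#' @param a,b One-row region tibbles (or lists) with `chrom`, `start`,
#'   `end`, on the same chromosome.
#' @param universe CpG frame.
#' @return A tibble with columns `chrom`, `start`, `end`, `shared_cpgs`;
#'   zero rows when the regions are disjoint.
#' @export
opposing_overlap <- function(a, b, universe) {
  if (a$chrom[1] != b$chrom[1]) {
    abort("regions must be on the same chromosome")
  }
  s <- max(a$start[1], b$start[1])
  e <- min(a$end[1], b$end[1])
  if (e <= s) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  shared_cpgs = integer()))
  }
  res <- tibble(chrom = a$chrom[1], start = as.integer(s), end = as.integer(e))
  res$shared_cpgs <- count_cpgs(res, universe)
  res
}

#' Write regions as BED
#'
#' BED6 with the state in the name field and the region mean (when present)
#' scaled to 0–1000 in the score field. 0-based half-open, as BED requires.
#'
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  score <- if ("mean" %in% names(regions)) {
    as.integer(round(pmin(pmax(regions$mean, 0), 1) * 1000))
  } else rep(0L, nrow(regions))
  name <- if ("state" %in% names(regions)) regions$state
          else if ("origin" %in% names(regions)) regions$origin
          else rep(".", nrow(regions))
  bed <- tibble(chrom = regions$chrom, start = regions$start,
                end = regions$end, name = name, score = score,
                strand = rep(".", nrow(regions)))
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file of feature intervals
#'
#' Reads BED3+ (chrom, start, end, optional name/score/strand) into a sorted
#' region tibble. Used for user-supplied annotation tracks such as CpG
#' islands or repeats.
#'
#' @param path BED file path (may be gzipped).
#' @return Tibble with `chrom`, `start`, `end` and `name` when present.
#' @export
read_bed_features <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(raw) < 3) abort(paste0("not a BED file (fewer than 3 columns): ", path))
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.integer(raw[[2]]),
                end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out %>% arrange(.data$chrom, .data$start, .data$end)
}
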