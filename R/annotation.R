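# Genomic-feature annotation of gDMRs: per-region feature overlap and
# repeat content per 20-CpG tile.

#' Annotate regions with feature overlap
#'
#' For each region and each feature set (CpG islands, repeats, genes, ...)
#' reports whether the region overlaps the set and what fraction of the
#' region's length the set covers. Feature intervals are collapsed
#' (union) before measuring, so nested or overlapping features are not
#' double-counted.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param features Named list of feature tibbles (`chrom`, `start`, `end`),
#'   e.g. `list(cpg_island = ..., repeat = ...)`.
#' @return `regions` with, per feature set `f`, logical `f_overlap` and
#'   numeric `f_fraction` (in `[0, 1]`) columns appended.
#' @export
annotate_regions <- function(regions, features) {
  if (is.null(names(features)) || any(names(features) == "")) {
    abort("`features` must be a named list of interval tibbles")
  }
  out <- regions
  if (nrow(regions) == 0) {
    for (nm in names(features)) {
      out[[paste0(nm, "_overlap")]] <- logical()
      out[[paste0(nm, "_fraction")]] <- double()
    }
    return(out)
  }
  width <- regions$end - regions$start
  for (nm in names(features)) {
    feat <- features[[nm]]
    if (nrow(feat) == 0) {
      out[[paste0(nm, "_overlap")]] <- rep(FALSE, nrow(regions))
      out[[paste0(nm, "_fraction")]] <- rep(0, nrow(regions))
      next
    }
    lv <- unique(c(regions$chrom, feat$chrom))
    gr_r <- regions_to_gr(regions, levels = lv)
    gr_f <- GenomicRanges::reduce(regions_to_gr(feat, levels = lv))
    cov_bp <- covered_bp(gr_r, gr_f)
    out[[paste0(nm, "_overlap")]] <- cov_bp > 0
    out[[paste0(nm, "_fraction")]] <- cov_bp / width
  }
  out
}

# basepairs of each query interval covered by the (reduced) subject set
covered_bp <- function(gr_query, gr_subject_reduced) {
  hits <- GenomicRanges::findOverlaps(gr_query, gr_subject_reduced)
  bp <- rep(0L, length(gr_query))
  if (length(hits) == 0) return(bp)
  inter <- IRanges::pintersect(gr_query[S4Vectors::queryHits(hits)],
                               gr_subject_reduced[S4Vectors::subjectHits(hits)])
  per_hit <- GenomicRanges::width(inter)
  agg <- tapply(per_hit, S4Vectors::queryHits(hits), sum)
  bp[as.integer(names(agg))] <- as.integer(agg)
  bp
}

#' Repeat content per 20-CpG tile
#'
#' Splits each region into consecutive tiles of `tile_cpgs` universe CpGs
#' (trailing partial tiles are dropped) and reports the percentage of each
#' tile's genomic span covered by repeats. Tiles with repeat content below
#' 25% are labelled `unique` — DMRs in unique sequence are the candidates of
#' interest, as repeat-borne methylation differences are pervasive and
#' rarely imprint-related.
#'
#' @param regions Region tibble.
#' @param repeats Repeat interval tibble (`chrom`, `start`, `end`).
#' @param tile_cpgs CpGs per tile (default 20).
#' @param universe CpG frame.
#' @param literal_unique If `TRUE`, invert the rule and label tiles with
#'   repeat content above 25% as unique instead (an alternative reading of
#'   the convention; default `FALSE`).
#' @return Tibble with one row per tile: `region_id`, `chrom`, `start`,
#'   `end`, `n_cpgs`, `repeat_pct` (0–100), `unique_seq` (logical).
#' @export
repeat_fraction_tiles <- function(regions, repeats, tile_cpgs = 20, universe,
                                  literal_unique = FALSE) {
  empty <- tibble(region_id = integer(), chrom = character(),
                  start = integer(), end = integer(), n_cpgs = integer(),
                  repeat_pct = double(), unique_seq = logical())
  if (nrow(regions) == 0) return(empty)
  pos_by_chrom <- split(universe$pos, universe$chrom)
  tiles <- purrr::map(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    pos <- pos_by_chrom[[ch]]
    if (is.null(pos)) return(NULL)
    inside <- pos[pos >= regions$start[i] & pos < regions$end[i]]
    n_tiles <- length(inside) %/% tile_cpgs
    if (n_tiles == 0) return(NULL)
    idx <- seq_len(n_tiles * tile_cpgs)
    grp <- rep(seq_len(n_tiles), each = tile_cpgs)
    firsts <- inside[idx][!duplicated(grp)]
    lasts <- inside[idx][!duplicated(grp, fromLast = TRUE)]
    tibble(region_id = i, chrom = ch,
           start = as.integer(firsts), end = as.integer(lasts + 1L),
           n_cpgs = as.integer(tile_cpgs))
  }) %>% bind_rows()
  if (nrow(tiles) == 0) return(empty)
  cov_bp <- if (nrow(repeats) == 0) {
    rep(0L, nrow(tiles))
  } else {
    lv <- unique(c(tiles$chrom, repeats$chrom))
    covered_bp(regions_to_gr(tiles, levels = lv),
               GenomicRanges::reduce(regions_to_gr(repeats, levels = lv)))
  }
  tiles %>%
    mutate(repeat_pct = 100 * cov_bp / (.data$end - .data$start),
           unique_seq = if (literal_unique) .data$repeat_pct > 25
                        else .data$repeat_pct < 25)
}
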