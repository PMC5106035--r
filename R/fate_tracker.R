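# Tracking gDMRs through blastocyst, placenta and the somatic panel.
#
# A gDMR "persists" in a tissue when it overlaps a fused intermediate
# (partially methylated) region of that tissue — intermediate methylation
# being the methylome signature of one methylated and one unmethylated
# allele. Tissue regions shorter than `min_region_bp` are discarded before
# the overlap test (strictly "> 500 bp" by default).

#' Partially methylated regions of one tissue
#'
#' Runs the intermediate-mode window screen over a tissue track and fuses
#' consecutive qualifying windows into regions.
#'
#' @inheritParams classified_regions
#' @return Region tibble of state `"intermediate"` with `n_cpgs` and `mean`.
#' @export
partial_regions <- function(track, universe, ...) {
  reg <- classified_regions(track, universe, mode = "intermediate", ...)
  fused <- fuse_regions(reg, universe)
  fused$mean <- region_means(fused, track)
  fused
}

#' Persistence flags of gDMRs across a tissue panel
#'
#' Flags each gDMR as partially methylated (or not) in every tissue: a gDMR
#' is partial in a tissue iff it overlaps (by at least 1 bp) one of that
#' tissue's fused intermediate regions longer than `min_region_bp`.
#'
#' @param gdmrs gDMR tibble from [call_gdmrs()].
#' @param tissue_partials Named list of intermediate region tibbles, one per
#'   tissue ([partial_regions()]); must include `blastocyst` and `placenta`.
#' @param min_region_bp Minimum tissue-region length; regions of exactly
#'   this length or shorter are discarded (default 500, strict).
#' @return A long tibble: `gdmr_id` (row index into `gdmrs`), `chrom`,
#'   `start`, `end`, `origin`, `tissue`, `is_partial`.
#' @export
persistence_matrix <- function(gdmrs, tissue_partials, min_region_bp = 500) {
  if (is.null(names(tissue_partials)) || any(names(tissue_partials) == "")) {
    abort("`tissue_partials` must be a named list (tissue -> regions)")
  }
  for (core in c("blastocyst", "placenta")) {
    if (!core %in% names(tissue_partials)) {
      abort(paste0("missing tissue track: ", core))
    }
  }
  ids <- gdmrs %>%
    mutate(gdmr_id = row_number()) %>%
    select("gdmr_id", "chrom", "start", "end", "origin")
  purrr::map(names(tissue_partials), function(tis) {
    reg <- tissue_partials[[tis]] %>%
      filter(.data$end - .data$start > min_region_bp)
    flag <- if (nrow(reg) == 0 || nrow(ids) == 0) {
      rep(FALSE, nrow(ids))
    } else {
      lv <- unique(c(ids$chrom, reg$chrom))
      GenomicRanges::countOverlaps(regions_to_gr(ids, levels = lv),
                                   regions_to_gr(reg, levels = lv)) > 0
    }
    ids %>% mutate(tissue = tis, is_partial = flag)
  }) %>%
    bind_rows() %>%
    arrange(.data$gdmr_id, .data$tissue)
}

#' Classify the developmental fate of each gDMR
#'
#' Fates, in decision order:
#' \describe{
#'   \item{`reprogrammed_preimplantation`}{not partially methylated in the
#'     blastocyst — the germline difference did not survive the
#'     post-fertilization reprogramming wave.}
#'   \item{`ubiquitous_candidate`}{partial in the blastocyst and in at least
#'     `somatic_min` somatic tissues — the profile of a ubiquitous imprint.}
#'   \item{`placenta_specific`}{partial in blastocyst and placenta but in
#'     zero somatic tissues — a transient imprint maintained only in the
#'     extra-embryonic lineage.}
#'   \item{`tissue_restricted`}{partial in blastocyst and in 1 to
#'     `somatic_min − 1` somatic tissues.}
#'   \item{`other`}{partial in blastocyst only (neither placenta nor any
#'     somatic tissue).}
#' }
#' The categories are mutually exclusive and exhaustive.
#'
#' @param persistence Long flag tibble from [persistence_matrix()].
#' @param somatic Character vector of somatic tissue labels (the blastocyst
#'   and placenta are never counted as somatic).
#' @param somatic_min Somatic-tissue threshold for the ubiquitous call.
#'   Defaults to 12 for a 14-tissue panel and scales as
#'   `ceiling(12 / 14 * N)` for other panel sizes.
#' @return One row per gDMR: coordinates, `origin`, `blastocyst_partial`,
#'   `placenta_partial`, `n_somatic_partial`, `fate`.
#' @export
classify_fate <- function(persistence, somatic, somatic_min = NULL) {
  if (is.null(somatic_min)) {
    somatic_min <- as.integer(ceiling(12 / 14 * length(somatic)))
  }
  wide <- persistence %>%
    group_by(.data$gdmr_id, .data$chrom, .data$start, .data$end,
             .data$origin) %>%
    summarise(
      blastocyst_partial = any(.data$is_partial[.data$tissue == "blastocyst"]),
      placenta_partial = any(.data$is_partial[.data$tissue == "placenta"]),
      n_somatic_partial = sum(.data$is_partial[.data$tissue %in% somatic]),
      .groups = "drop")
  wide %>%
    mutate(fate = case_when(
      !.data$blastocyst_partial ~ "reprogrammed_preimplantation",
      .data$n_somatic_partial >= somatic_min ~ "ubiquitous_candidate",
      .data$placenta_partial & .data$n_somatic_partial == 0 ~ "placenta_specific",
      .data$n_somatic_partial >= 1 ~ "tissue_restricted",
      TRUE ~ "other"))
}

#' Tri-state methylation matrix of gDMRs across a panel
#'
#' The heatmap representation of persistence: each gDMR's mean methylation
#' in each tissue, partitioned into `hypo` (< 20%), `hyper` (> 80%) or
#' `intermediate`. Rows are ordered by descending placenta methylation.
#'
#' @param gdmrs gDMR tibble.
#' @param panel A [track_panel()].
#' @return Long tibble: `gdmr_id`, `chrom`, `start`, `end`, `origin`,
#'   `tissue`, `mean`, `state`, with `gdmr_id` releveled so that ids follow
#'   the placenta ordering.
#' @export
fate_heatmap_states <- function(gdmrs, panel) {
  ids <- gdmrs %>%
    mutate(gdmr_id = row_number()) %>%
    select("gdmr_id", "chrom", "start", "end", "origin")
  long <- purrr::map(names(panel), function(tis) {
    ids %>% mutate(tissue = tis,
                   mean = region_means(ids, panel[[tis]]))
  }) %>%
    bind_rows() %>%
    mutate(state = tile_state(.data$mean))
  ord <- long %>%
    filter(.data$tissue == "placenta") %>%
    arrange(dplyr::desc(.data$mean)) %>%
    pull(.data$gdmr_id)
  long %>%
    mutate(gdmr_id = factor(.data$gdmr_id, levels = ord)) %>%
    arrange(.data$gdmr_id, .data$tissue)
}

#' Run the full germline-DMR screen over a tissue panel
#'
#' End-to-end: gamete window classification, region merging, gDMR calling,
#' per-tissue intermediate regions, persistence flags and fate calls.
#'
#' @param panel A [track_panel()].
#' @param min_shared_cpgs gDMR overlap gate (default 25, strict `>`).
#' @param min_region_bp Tissue intermediate-region length gate (default 500,
#'   strict `>`).
#' @param somatic_min Somatic persistence threshold for the ubiquitous call
#'   (see [classify_fate()]).
#' @param ... Window/threshold parameters passed to [classified_regions()]
#'   and [partial_regions()].
#' @return An `imprint_screen` object: a list with `gdmrs`, `persistence`,
#'   `fates`, `gamete_regions`, `tissue_partials` and `params`. Use
#'   [tidy()] for the per-gDMR fate table, [glance()] for one-row summary
#'   counts and [ggplot2::autoplot()] for the tri-state heatmap.
#' @export
screen_imprints <- function(panel, min_shared_cpgs = 25, min_region_bp = 500,
                            somatic_min = NULL, ...) {
  stopifnot(inherits(panel, "track_panel"))
  universe <- attr(panel, "universe")
  somatic <- attr(panel, "somatic")

  oocyte_reg <- classified_regions(panel$oocyte, universe, mode = "gamete", ...)
  sperm_reg <- classified_regions(panel$sperm, universe, mode = "gamete", ...)
  gdmrs <- call_gdmrs(oocyte_reg, sperm_reg, universe,
                      min_shared_cpgs = min_shared_cpgs)

  fate_tissues <- c("blastocyst", "placenta", somatic)
  tissue_partials <- lapply(setNames(fate_tissues, fate_tissues),
                            function(tis) {
                              partial_regions(panel[[tis]], universe, ...)
                            })
  persistence <- persistence_matrix(gdmrs, tissue_partials,
                                    min_region_bp = min_region_bp)
  fates <- classify_fate(persistence, somatic, somatic_min = somatic_min)

  structure(
    list(gdmrs = gdmrs,
         persistence = persistence,
         fates = fates,
         gamete_regions = list(oocyte = oocyte_reg, sperm = sperm_reg),
         tissue_partials = tissue_partials,
         params = list(min_shared_cpgs = min_shared_cpgs,
                       min_region_bp = min_region_bp,
                       somatic_min = somatic_min %||%
                         as.integer(ceiling(12 / 14 * length(somatic))),
                       somatic = somatic),
         panel = panel),
    class = "imprint_screen")
}

#' @export
print.imprint_screen <- function(x, ...) {
  cat("<imprint_screen> ", nrow(x$gdmrs), " gDMRs (",
      sum(x$gdmrs$origin == "maternal"), " maternal, ",
      sum(x$gdmrs$origin == "paternal"), " paternal)\n", sep = "")
  if (nrow(x$fates) > 0) {
    tab <- table(x$fates$fate)
    for (f in names(tab)) cat("  ", f, ": ", tab[[f]], "\n", sep = "")
  }
  invisible(x)
}

#' Per-gDMR fate table of a screen
#'
#' @param x An `imprint_screen`.
#' @param ... Unused.
#' @return Tibble with one row per gDMR: coordinates, origin, persistence
#'   flags, somatic tally and fate.
#' @export
tidy.imprint_screen <- function(x, ...) {
  x$fates %>%
    left_join(x$gdmrs %>%
                mutate(gdmr_id = row_number()) %>%
                select("gdmr_id", "shared_cpgs", "oocyte_mean", "sperm_mean"),
              by = "gdmr_id")
}

#' One-row summary of a screen
#'
#' @param x An `imprint_screen`.
#' @param ... Unused.
#' @return One-row tibble: gDMR counts per origin, blastocyst-survival
#'   fractions per origin, and counts per fate class.
#' @export
glance.imprint_screen <- function(x, ...) {
  f <- x$fates
  surv <- function(orig) {
    n <- sum(f$origin == orig)
    if (n == 0) return(NA_real_)
    sum(f$origin == orig & f$blastocyst_partial) / n
  }
  tibble(
    n_gdmrs = nrow(x$gdmrs),
    n_maternal = sum(x$gdmrs$origin == "maternal"),
    n_paternal = sum(x$gdmrs$origin == "paternal"),
    blastocyst_survival_maternal = surv("maternal"),
    blastocyst_survival_paternal = surv("paternal"),
    n_ubiquitous = sum(f$fate == "ubiquitous_candidate"),
    n_placenta_specific = sum(f$fate == "placenta_specific"),
    n_tissue_restricted = sum(f$fate == "tissue_restricted"),
    n_reprogrammed = sum(f$fate == "reprogrammed_preimplantation"),
    n_other = sum(f$fate == "other"))
}

#' Tri-state persistence heatmap of a screen
#'
#' @param object An `imprint_screen`.
#' @param ... Unused.
#' @return A ggplot: gDMRs (rows, ordered by placenta methylation) by
#'   tissues (columns), tiles coloured hypo/intermediate/hyper.
#' @export
autoplot.imprint_screen <- function(object, ...) {
  long <- fate_heatmap_states(object$gdmrs, object$panel)
  tissue_order <- c("sperm", "oocyte", "blastocyst", "placenta",
                    setdiff(names(object$panel),
                            c("sperm", "oocyte", "blastocyst", "placenta")))
  long %>%
    mutate(tissue = factor(.data$tissue, levels = tissue_order)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$tissue, y = .data$gdmr_id,
                                 fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(hypo = "#2166AC", intermediate = "#FDDBC7",
                 hyper = "#B2182B"),
      na.value = "grey85") +
    ggplot2::labs(x = NULL, y = "gDMR (by placenta methylation)",
                  fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
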