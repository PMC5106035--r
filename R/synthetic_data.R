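# Synthetic methylome panels, annotations and allelic trajectories with a
# ground-truth manifest for every planted feature.
#
# The generator emulates the statistical structure the screen assumes:
# a genome of CpG positions shared by all tissues; a noisy hypermethylated
# sperm landscape; a bimodal oocyte landscape (domains of high and low
# methylation); a globally hypomethylated blastocyst; a heterogeneous,
# globally reduced placenta; hypermethylated somatic tissues; and planted
# opposing-gamete DMRs whose assigned fate dictates their target methylation
# in each tissue. Observation is two-stage: bounded biological noise on the
# true methylation level, then read sampling (Poisson depth, binomial
# methylated calls), so both the coverage filter and the SD-based window
# criteria are exercised.

#' Configuration for the synthetic methylome generator
#'
#' @param n_chromosomes,cpgs_per_chromosome Genome shape.
#' @param mean_spacing Mean CpG spacing in bp (spacings are 2 + rounded
#'   exponential).
#' @param noise_sd SD of the per-CpG Gaussian noise added to the true
#'   methylation level (clipped to `[0, 1]`).
#' @param mean_depth Mean read depth (Poisson).
#' @param n_somatic Number of somatic tissue tracks (default 14).
#' @param coverage_min Coverage filter handed to the tracks.
#' @param oocyte_block_cpgs Length, in CpGs, of the alternating high/low
#'   oocyte methylation domains.
#' @param split_oocyte_replicates If `TRUE`, emit the oocyte as two
#'   half-depth replicates pooled with `sum_calls`, emulating low-coverage
#'   oocyte libraries.
#' @param seed Integer seed; fully determines all generator output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_chromosomes = 2, cpgs_per_chromosome = 20000,
                             mean_spacing = 100, noise_sd = 0.02,
                             mean_depth = 20, n_somatic = 14,
                             coverage_min = 5, oocyte_block_cpgs = 500,
                             split_oocyte_replicates = FALSE, seed = 1) {
  structure(list(n_chromosomes = n_chromosomes,
                 cpgs_per_chromosome = cpgs_per_chromosome,
                 mean_spacing = mean_spacing,
                 noise_sd = noise_sd,
                 mean_depth = mean_depth,
                 n_somatic = n_somatic,
                 coverage_min = coverage_min,
                 oocyte_block_cpgs = oocyte_block_cpgs,
                 split_oocyte_replicates = split_oocyte_replicates,
                 seed = seed),
            class = "generator_config")
}

# Background true-methylation regimes, per tissue class. Each is a draw of
# per-CpG levels from a wide uniform band: wide bands give windows a large
# SD, which is what keeps ordinary background from satisfying the
# SD-gated window criteria — only planted (tightly consistent) intervals
# classify. Bands:
#   sperm / somatic  high:          U(0.60, 1.00)
#   oocyte           bimodal:       U(0.55, 0.95) / U(0.05, 0.45) domains
#   blastocyst       globally low:  U(0.00, 0.50)
#   placenta         reduced, wide: U(0.00, 0.90)
background_levels <- function(tissue_class, n, block = NULL) {
  switch(tissue_class,
    sperm = runif(n, 0.60, 1.00),
    somatic = runif(n, 0.60, 1.00),
    blastocyst = runif(n, 0.00, 0.50),
    placenta = runif(n, 0.00, 0.90),
    oocyte = {
      hi <- runif(n, 0.55, 0.95)
      lo <- runif(n, 0.05, 0.45)
      ifelse(((seq_len(n) - 1L) %/% block) %% 2L == 0L, hi, lo)
    },
    abort(paste0("unknown tissue class: ", tissue_class)))
}

#' Plant opposing-gamete DMRs on a CpG universe
#'
#' Places disjoint candidate intervals of `dmr_cpgs` consecutive CpGs at
#' regularly spaced slots across the genome and assigns each an origin and a
#' developmental fate. Fates and their per-tissue target methylation:
#' \describe{
#'   \item{`ubiquitous`}{intermediate (0.5) in blastocyst, placenta and all
#'     somatic tissues.}
#'   \item{`placenta_specific`}{intermediate in blastocyst and placenta,
#'     low (0.05) in all somatic tissues.}
#'   \item{`tissue_restricted`}{intermediate in blastocyst, placenta and the
#'     first `k_somatic` somatic tissues; low elsewhere.}
#'   \item{`reprogrammed_low` / `reprogrammed_high`}{methylation resolved to
#'     0.05 / 0.95 in blastocyst and every later tissue.}
#' }
#' Gamete targets are 0.95 in the methylated gamete and 0.05 in the other
#' (oocyte-methylated = maternal; sperm-methylated = paternal).
#'
#' @param universe CpG frame.
#' @param origins Character vector, one entry per DMR to plant
#'   (`"maternal"`/`"paternal"`).
#' @param fates Character vector, recycled against `origins`.
#' @param dmr_cpgs CpGs per planted DMR (default 60; must be >= 26 so a
#'   qualifying overlap is possible).
#' @param k_somatic Somatic-tissue count for `tissue_restricted` fates
#'   (default 5).
#' @param edge_cpgs Universe CpGs kept free at each chromosome end.
#' @return The planted-DMR manifest: `chrom`, `start`, `end`, `origin`,
#'   `fate`, `k_somatic`, `n_cpgs`.
#' @export
plant_gdmrs <- function(universe, origins, fates, dmr_cpgs = 60,
                        k_somatic = 5, edge_cpgs = 100) {
  if (dmr_cpgs < 26) abort("planted DMRs need at least 26 CpGs")
  n <- length(origins)
  fates <- rep(fates, length.out = n)
  chroms <- unique(universe$chrom)
  per_chrom <- table(factor(rep(chroms, length.out = n), levels = chroms))
  pos_by_chrom <- split(universe$pos, universe$chrom)
  out <- purrr::map(chroms, function(ch) {
    k <- per_chrom[[ch]]
    if (k == 0) return(NULL)
    pos <- pos_by_chrom[[ch]]
    m <- length(pos)
    lo <- edge_cpgs + 1L
    hi <- m - edge_cpgs - dmr_cpgs
    if (hi < lo || (hi - lo) < k * (dmr_cpgs + 50)) {
      abort("chromosome too small for the requested planted DMRs")
    }
    starts <- round(seq(lo, hi, length.out = k))
    tibble(chrom = ch,
           start = pos[starts],
           end = pos[starts + dmr_cpgs - 1L] + 1L,
           n_cpgs = as.integer(dmr_cpgs))
  }) %>% bind_rows()
  # DMR i goes to chromosome rep(chroms)[i]; reorder labels to match the
  # chromosome-grouped rows (stable, so within-chromosome order is kept)
  rep_ch <- rep(chroms, length.out = n)
  idx <- order(match(rep_ch, chroms))
  out$origin <- origins[idx]
  out$fate <- fates[idx]
  out$k_somatic <- ifelse(out$fate == "tissue_restricted", k_somatic, NA_integer_)
  out %>% select("chrom", "start", "end", "origin", "fate",
                 "k_somatic", "n_cpgs")
}

# Target true methylation of planted DMRs in one tissue.
# tissue: "oocyte", "sperm", "blastocyst", "placenta", or a somatic index.
planted_target <- function(planted, tissue, somatic_index = NA) {
  partial <- 0.5
  low <- 0.05
  high <- 0.95
  if (tissue == "oocyte") {
    return(ifelse(planted$origin == "maternal", high, low))
  }
  if (tissue == "sperm") {
    return(ifelse(planted$origin == "paternal", high, low))
  }
  if (tissue %in% c("blastocyst", "placenta")) {
    return(dplyr::case_when(
      planted$fate == "reprogrammed_low" ~ low,
      planted$fate == "reprogrammed_high" ~ high,
      TRUE ~ partial))
  }
  # somatic tissue number `somatic_index`
  dplyr::case_when(
    planted$fate == "ubiquitous" ~ partial,
    planted$fate == "reprogrammed_low" ~ low,
    planted$fate == "reprogrammed_high" ~ high,
    planted$fate == "placenta_specific" ~ low,
    planted$fate == "tissue_restricted" &
      somatic_index <= planted$k_somatic ~ partial,
    TRUE ~ low)
}

#' Generate a synthetic methylome panel with planted gDMRs
#'
#' @param config A [generator_config()].
#' @param planted Planted-DMR manifest from [plant_gdmrs()], or `NULL` for
#'   a background-only panel. Intervals must be disjoint and contain at
#'   least 26 universe CpGs each.
#' @return A list: `panel` (a [track_panel()]), `manifest` (the planted
#'   tibble), `universe`, and `oocyte_replicates` (the two pooled replicate
#'   tracks, when `split_oocyte_replicates` is set).
#' @export
generate_panel <- function(config, planted = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  # CpG universe: per-chromosome positions with ~mean_spacing bp gaps
  universe <- purrr::map(seq_len(config$n_chromosomes), function(i) {
    gaps <- 2L + as.integer(round(rexp(config$cpgs_per_chromosome,
                                       1 / (config$mean_spacing - 2))))
    tibble(chrom = sprintf("chr%d", i), pos = cumsum(gaps))
  }) %>% bind_rows()

  if (!is.null(planted) && nrow(planted) > 0) {
    ov <- GenomicRanges::findOverlaps(regions_to_gr(planted),
                                      drop.self = TRUE,
                                      drop.redundant = TRUE)
    if (length(ov) > 0) abort("planted intervals must be disjoint")
    if (any(count_cpgs(planted, universe) < 26)) {
      abort("every planted interval must contain at least 26 universe CpGs")
    }
  }

  n_cpg <- nrow(universe)
  somatic_labels <- sprintf("somatic_%02d", seq_len(config$n_somatic))

  # planted-site index and per-tissue override machinery
  planted_idx <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(universe$chrom,
                             IRanges::IRanges(universe$pos + 1L,
                                              universe$pos + 1L)),
      regions_to_gr(planted))
    planted_idx <- list(site = S4Vectors::queryHits(hits),
                        dmr = S4Vectors::subjectHits(hits))
  }

  true_levels <- function(tissue_class, tissue_name, somatic_index = NA) {
    p <- background_levels(tissue_class, n_cpg,
                           block = config$oocyte_block_cpgs)
    if (!is.null(planted_idx)) {
      tgt <- planted_target(planted, if (tissue_class == "somatic")
        "somatic" else tissue_name, somatic_index)
      p[planted_idx$site] <- tgt[planted_idx$dmr]
    }
    p
  }

  observe <- function(p, tissue, depth_mean = config$mean_depth) {
    pr <- pmin(pmax(p + rnorm(n_cpg, 0, config$noise_sd), 0), 1)
    depth <- rpois(n_cpg, depth_mean)
    meth <- rbinom(n_cpg, depth, pr)
    cpg_track(tibble(chrom = universe$chrom, pos = universe$pos,
                     meth = meth, unmeth = depth - meth),
              coverage_min = config$coverage_min, collapse_strands = FALSE,
              tissue = tissue)
  }

  tracks <- list()
  oocyte_reps <- NULL
  p_oocyte <- true_levels("oocyte", "oocyte")
  if (config$split_oocyte_replicates) {
    oocyte_reps <- list(observe(p_oocyte, "oocyte", config$mean_depth / 2),
                        observe(p_oocyte, "oocyte", config$mean_depth / 2))
    tracks$oocyte <- combine_replicates(oocyte_reps, mode = "sum_calls",
                                        coverage_min = config$coverage_min)
  } else {
    tracks$oocyte <- observe(p_oocyte, "oocyte")
  }
  tracks$sperm <- observe(true_levels("sperm", "sperm"), "sperm")
  tracks$blastocyst <- observe(true_levels("blastocyst", "blastocyst"),
                               "blastocyst")
  tracks$placenta <- observe(true_levels("placenta", "placenta"), "placenta")
  for (k in seq_len(config$n_somatic)) {
    tracks[[somatic_labels[k]]] <-
      observe(true_levels("somatic", somatic_labels[k], somatic_index = k),
              somatic_labels[k])
  }

  list(panel = track_panel(tracks, somatic = somatic_labels),
       manifest = planted,
       universe = universe,
       oocyte_replicates = oocyte_reps)
}

#' Expected fate-call label for a planted fate
#'
#' Maps the generator's fate vocabulary onto the labels [classify_fate()]
#' assigns when recovery is perfect, for manifest comparisons.
#'
#' @param fate Character vector of planted fates.
#' @return Character vector of expected `fate` labels.
#' @export
expected_fate_call <- function(fate) {
  dplyr::recode(fate,
                ubiquitous = "ubiquitous_candidate",
                placenta_specific = "placenta_specific",
                tissue_restricted = "tissue_restricted",
                reprogrammed_low = "reprogrammed_preimplantation",
                reprogrammed_high = "reprogrammed_preimplantation")
}

#' Generate synthetic allelic expression trajectories
#'
#' Stage-count templates per class, with multiplicative lognormal count
#' noise:
#' \describe{
#'   \item{`maternal_store_decay`}{totals halving every stage from
#'     `base_count`, all reads maternal.}
#'   \item{`imprinted_paternal`}{maternal-only before the activation stage,
#'     paternal-only from it onward, constant totals.}
#'   \item{`biallelic_embryonic`}{balanced maternal/paternal counts at all
#'     stages, constant totals.}
#' }
#'
#' @param n_per_class Trajectories per class.
#' @param classes Which classes to generate.
#' @param noise_sd SD of the lognormal count noise (0 = exact templates).
#' @param base_count Template total reads per stage.
#' @param activation_stage Stage of the paternal switch in the
#'   `imprinted_paternal` template.
#' @param stages Ordered stage labels.
#' @param seed Integer seed.
#' @return Long tibble: `gene`, `class_true`, `stage`, `maternal_reads`,
#'   `paternal_reads`, `informative`.
#' @export
generate_trajectories <- function(n_per_class = 100,
                                  classes = c("maternal_store_decay",
                                              "imprinted_paternal",
                                              "biallelic_embryonic"),
                                  noise_sd = 0.1, base_count = 1000,
                                  activation_stage = "8cell",
                                  stages = preimplantation_stages,
                                  seed = 1) {
  known <- c("maternal_store_decay", "imprinted_paternal",
             "biallelic_embryonic")
  bad <- setdiff(classes, known)
  if (length(bad) > 0) {
    abort(paste0("unknown trajectory class(es): ", paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  n_stage <- length(stages)
  post <- seq_len(n_stage) >= match(activation_stage, stages)
  template <- function(cls) {
    switch(cls,
      maternal_store_decay = list(m = base_count * 0.5^(seq_len(n_stage) - 1),
                                  p = rep(0, n_stage)),
      imprinted_paternal = list(m = ifelse(post, 0, base_count),
                                p = ifelse(post, base_count, 0)),
      biallelic_embryonic = list(m = rep(base_count / 2, n_stage),
                                 p = rep(base_count / 2, n_stage)))
  }
  purrr::map(classes, function(cls) {
    tpl <- template(cls)
    purrr::map(seq_len(n_per_class), function(g) {
      noise_m <- exp(rnorm(n_stage, 0, noise_sd))
      noise_p <- exp(rnorm(n_stage, 0, noise_sd))
      tibble(gene = sprintf("%s_%03d", cls, g),
             class_true = cls,
             stage = stages,
             maternal_reads = as.integer(round(tpl$m * noise_m)),
             paternal_reads = as.integer(round(tpl$p * noise_p)),
             informative = TRUE)
    }) %>% bind_rows()
  }) %>% bind_rows()
}

#' Generate synthetic annotation tracks
#'
#' @param universe CpG frame of the simulated genome.
#' @param planted Planted-DMR manifest (may be `NULL`).
#' @param island_fraction Fraction of planted DMRs covered by a CpG-island
#'   interval (default 1).
#' @param repeat_density Target fraction of the genome covered by repeats;
#'   the genome is tiled into `segment_bp` segments and each becomes a
#'   repeat independently with this probability.
#' @param segment_bp Repeat segment size (default 1000).
#' @param seed Integer seed.
#' @return List of feature tibbles: `cpg_island`, `repeats`.
#' @export
generate_annotations <- function(universe, planted = NULL,
                                 island_fraction = 1, repeat_density = 0.3,
                                 segment_bp = 1000, seed = 1) {
  set.seed(seed)
  islands <- tibble(chrom = character(), start = integer(), end = integer())
  if (!is.null(planted) && nrow(planted) > 0 && island_fraction > 0) {
    n_pick <- round(island_fraction * nrow(planted))
    pick <- sort(sample.int(nrow(planted), n_pick))
    islands <- planted[pick, c("chrom", "start", "end")]
  }
  repeats <- purrr::map(unique(universe$chrom), function(ch) {
    len <- max(universe$pos[universe$chrom == ch]) + segment_bp
    starts <- seq(0L, len - 1L, by = segment_bp)
    keep <- runif(length(starts)) < repeat_density
    tibble(chrom = ch, start = as.integer(starts[keep]),
           end = as.integer(starts[keep] + segment_bp))
  }) %>% bind_rows()
  list(cpg_island = islands, repeats = repeats)
}
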