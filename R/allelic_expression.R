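# Allele-specific expression staging across preimplantation development.
#
# Before zygotic genome activation (ZGA, major wave at the 4-8 cell stage)
# transcripts are maternal oocyte stores, so apparent maternal expression is
# uninformative about imprinting. Functional imprinted (paternal) expression
# can only be recognised at or after the activation stage.

#' Ordered preimplantation stage labels
#' @export
preimplantation_stages <- c("zygote", "2cell", "4cell", "8cell",
                            "morula", "blastocyst")

#' Allele class for one stage's read counts
#'
#' @param maternal_reads,paternal_reads Non-negative integer vectors.
#' @param min_reads Minimum total reads for the stage to be called
#'   (default 10); below it the call is `low_expression`.
#' @param mono_frac Allelic fraction at or above which expression is called
#'   monoallelic (default 0.9, inclusive `>=`).
#' @return Character vector: `"maternal_only"`, `"paternal_only"`,
#'   `"biallelic"` or `"low_expression"`.
#' @export
stage_allele_call <- function(maternal_reads, paternal_reads,
                              min_reads = 10, mono_frac = 0.9) {
  stopifnot(min_reads >= 1, mono_frac > 0.5, mono_frac <= 1)
  if (any(maternal_reads < 0, na.rm = TRUE) ||
      any(paternal_reads < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  total <- maternal_reads + paternal_reads
  case_when(
    total < min_reads ~ "low_expression",
    maternal_reads / total >= mono_frac ~ "maternal_only",
    paternal_reads / total >= mono_frac ~ "paternal_only",
    TRUE ~ "biallelic")
}

#' Classify one gene's allelic trajectory
#'
#' Trajectory classes:
#' \describe{
#'   \item{`imprinted_paternal`}{paternal-only expression at any stage at or
#'     after the activation stage; earlier maternal dominance never vetoes
#'     this, since maternal stores and embryonic paternal transcripts
#'     co-exist until late cleavage.}
#'   \item{`biallelic_embryonic`}{biallelic expression at a post-activation
#'     stage, without post-activation paternal-only evidence.}
#'   \item{`maternal_store_decay`}{maternal-only expression before
#'     activation with non-increasing stage totals and no post-activation
#'     paternal or biallelic signal — the signature of a decaying oocyte
#'     transcript store, not of embryonic transcription.}
#'   \item{`uninformative`}{anything else, including non-informative
#'     embryos (no heterozygous site / unknown paternal allele).}
#' }
#'
#' @param traj Tibble with columns `stage`, `maternal_reads`,
#'   `paternal_reads`, one row per stage, and optionally a logical
#'   `informative` column.
#' @param activation_stage Stage from which embryonic expression is judged
#'   (default `"8cell"`; `"4cell"` is the other defensible choice).
#' @param stages Ordered stage labels.
#' @inheritParams stage_allele_call
#' @return A single class string.
#' @export
classify_trajectory <- function(traj, activation_stage = "8cell",
                                stages = preimplantation_stages,
                                min_reads = 10, mono_frac = 0.9) {
  if (!activation_stage %in% stages) {
    abort(paste0("unknown activation stage: ", activation_stage))
  }
  if ("informative" %in% names(traj) && !all(traj$informative)) {
    return("uninformative")
  }
  bad <- setdiff(unique(traj$stage), stages)
  if (length(bad) > 0) {
    abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  }
  traj <- traj %>%
    mutate(stage = factor(.data$stage, levels = stages)) %>%
    arrange(.data$stage)
  calls <- stage_allele_call(traj$maternal_reads, traj$paternal_reads,
                             min_reads = min_reads, mono_frac = mono_frac)
  post <- as.integer(traj$stage) >= match(activation_stage, stages)
  if (any(calls[post] == "paternal_only")) return("imprinted_paternal")
  if (any(calls[post] == "biallelic")) return("biallelic_embryonic")
  totals <- traj$maternal_reads + traj$paternal_reads
  decaying <- length(totals) > 1 && all(diff(totals) <= 0)
  if (any(calls[!post] == "maternal_only") && decaying &&
      all(calls[post] %in% c("maternal_only", "low_expression"))) {
    return("maternal_store_decay")
  }
  "uninformative"
}

#' Classify many genes' trajectories
#'
#' @param counts Long tibble with columns `gene`, `stage`,
#'   `maternal_reads`, `paternal_reads` (and optionally `informative`).
#' @inheritParams classify_trajectory
#' @return Tibble with one row per gene: `gene`, `trajectory_class`.
#' @export
classify_trajectories <- function(counts, activation_stage = "8cell",
                                  stages = preimplantation_stages,
                                  min_reads = 10, mono_frac = 0.9) {
  counts %>%
    group_by(.data$gene) %>%
    dplyr::group_modify(function(d, key) {
      tibble(trajectory_class = classify_trajectory(
        d, activation_stage = activation_stage, stages = stages,
        min_reads = min_reads, mono_frac = mono_frac))
    }) %>%
    ungroup()
}

#' Merge single-cell allelic counts into embryo trajectories
#'
#' Single-cell RNA-seq allelic counts from the cells of one embryo are
#' summed per gene and stage to reconstruct the embryo-level trajectory.
#' Every embryo must carry a single stage label; conflicting labels within
#' one embryo are an error.
#'
#' @param per_cell Tibble with columns `gene`, `embryo`, `stage`, `cell`,
#'   `maternal_reads`, `paternal_reads`.
#' @return Tibble with one row per (gene, embryo, stage): summed counts.
#' @export
merge_cells_to_embryo <- function(per_cell) {
  conflicts <- per_cell %>%
    distinct(.data$embryo, .data$stage) %>%
    dplyr::count(.data$embryo) %>%
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0("conflicting stage labels within embryo(s): ",
                 paste(conflicts$embryo, collapse = ", ")))
  }
  per_cell %>%
    group_by(.data$gene, .data$embryo, .data$stage) %>%
    summarise(maternal_reads = sum(.data$maternal_reads),
              paternal_reads = sum(.data$paternal_reads),
              .groups = "drop")
}
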