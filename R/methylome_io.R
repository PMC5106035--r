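# Reading, validating and combining per-CpG methylation call tables.
#
# A "track" is a tibble with one row per CpG site on the forward strand:
#   chrom  character
#   pos    integer, 0-based position of the C of the CpG dyad
#   meth   integer, methylated read count
#   unmeth integer, unmethylated read count
#   depth  integer, meth + unmeth
#   ratio  double in [0,1]; NA when depth < coverage_min
# Sites are sorted by (chrom, pos) and unique within a chromosome.

#' Build a CpG methylation track from raw counts
#'
#' Validates, sorts and strand-collapses a table of per-CpG methylation
#' calls, then computes methylation ratios for sites passing the coverage
#' filter. The ratio at a site is `meth / (meth + unmeth)`, pooling reads
#' from both strands of the CpG dyad; sites with fewer than `coverage_min`
#' reads get an `NA` ratio and are treated as missing downstream.
#'
#' @param x A data frame with columns `chrom`, `pos` (0-based), `meth`,
#'   `unmeth`.
#' @param coverage_min Minimum total reads for a site to contribute a
#'   methylation ratio. Default 5, the conventional whole-genome bisulfite
#'   coverage cutoff.
#' @param collapse_strands If `TRUE` (default), a record at position `p + 1`
#'   immediately following a record at `p` is taken to be the reverse-strand
#'   C of the same CpG dyad and its counts are summed into the forward
#'   position `p`. Genuine neighbouring CpGs are always at least 2 bp apart,
#'   so this is unambiguous; files already collapsed to forward-strand
#'   positions are unaffected.
#' @param sample_id,tissue Optional labels stored as attributes.
#'
#' @return A tibble track (see Details) with attributes `sample_id`,
#'   `tissue` and `coverage_min`.
#' @export
cpg_track <- function(x, coverage_min = 5, collapse_strands = TRUE,
                      sample_id = NULL, tissue = NULL) {
  x <- as_tibble(x)
  needed <- c("chrom", "pos", "meth", "unmeth")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("track is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0 && (any(x$meth < 0, na.rm = TRUE) ||
                      any(x$unmeth < 0, na.rm = TRUE))) {
    abort("negative read counts are not a valid methylation call")
  }
  if (anyNA(x$pos) || anyNA(x$meth) || anyNA(x$unmeth)) {
    abort("NA values in position or count columns")
  }
  x <- x %>%
    mutate(chrom = as.character(.data$chrom),
           pos = as.integer(.data$pos),
           meth = as.integer(.data$meth),
           unmeth = as.integer(.data$unmeth)) %>%
    select(all_of(needed)) %>%
    arrange(.data$chrom, .data$pos)

  if (collapse_strands && nrow(x) > 1) {
    x <- collapse_dyads(x)
  }
  if (anyDuplicated(paste(x$chrom, x$pos)) > 0) {
    # duplicate forward-strand records for one site: pool their reads
    x <- x %>%
      group_by(.data$chrom, .data$pos) %>%
      summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                .groups = "drop") %>%
      arrange(.data$chrom, .data$pos)
  }
  x <- x %>%
    mutate(depth = .data$meth + .data$unmeth,
           ratio = ifelse(.data$depth >= coverage_min,
                          .data$meth / .data$depth, NA_real_))
  attr(x, "sample_id") <- sample_id
  attr(x, "tissue") <- tissue
  attr(x, "coverage_min") <- coverage_min
  x
}

# Sum a reverse-strand record at pos p+1 into the forward record at p.
# Within a run of consecutive positions records are paired (1,2), (3,4), ...
collapse_dyads <- function(x) {
  x %>%
    group_by(.data$chrom) %>%
    mutate(.run = cumsum(c(1L, diff(.data$pos)) != 1L)) %>%
    group_by(.data$chrom, .data$.run) %>%
    mutate(.pair = (row_number() + 1L) %/% 2L) %>%
    group_by(.data$chrom, .data$.run, .data$.pair) %>%
    summarise(pos = first(.data$pos),
              meth = sum(.data$meth),
              unmeth = sum(.data$unmeth),
              .groups = "drop") %>%
    select("chrom", "pos", "meth", "unmeth") %>%
    arrange(.data$chrom, .data$pos)
}

#' Read a per-CpG methylation call file
#'
#' Supported dialects:
#' \describe{
#'   \item{`bismark_cov`}{Bismark coverage format: `chrom, start, end,
#'     percent_methylation, count_methylated, count_unmethylated`, 1-based
#'     positions (converted to 0-based on read).}
#'   \item{`bedgraph_counts`}{Five columns `chrom, start, end,
#'     count_methylated, count_unmethylated`, 0-based half-open.}
#'   \item{`canonical`}{The package's own TSV written by
#'     [write_cpg_table()]: `chrom, pos, meth, unmeth, depth, ratio` with a
#'     header. Stored ratios are kept verbatim so write/read round-trips.}
#' }
#' Files may be gzip-compressed. Input need not be sorted; tracks are
#' sorted on read.
#'
#' @param path File path.
#' @param dialect One of `"bismark_cov"`, `"bedgraph_counts"`,
#'   `"canonical"`.
#' @inheritParams cpg_track
#' @return A track tibble (see [cpg_track()]).
#' @export
read_cpg_table <- function(path, dialect = c("bismark_cov", "bedgraph_counts",
                                             "canonical"),
                           coverage_min = 5, collapse_strands = TRUE,
                           sample_id = NULL, tissue = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))

  if (dialect == "canonical") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             chrom = readr::col_character(),
                             pos = readr::col_integer(),
                             meth = readr::col_integer(),
                             unmeth = readr::col_integer(),
                             depth = readr::col_integer(),
                             ratio = readr::col_double()))
    check_parse_problems(raw, path)
    tr <- cpg_track(raw[, c("chrom", "pos", "meth", "unmeth")],
                    coverage_min = coverage_min, collapse_strands = FALSE,
                    sample_id = sample_id, tissue = tissue)
    # keep stored ratios (they may be replicate averages, not count ratios)
    stored <- raw %>% arrange(.data$chrom, .data$pos)
    tr$ratio <- stored$ratio
    return(tr)
  }

  if (dialect == "bismark_cov") {
    raw <- suppressWarnings(
      readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                          "pct", "meth", "unmeth"),
                      col_types = "ciidii", show_col_types = FALSE,
                      progress = FALSE))
    check_parse_problems(raw, path)
    raw <- raw %>% mutate(pos = .data$start - 1L)
  } else {
    raw <- suppressWarnings(
      readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                          "meth", "unmeth"),
                      col_types = "ciiii", show_col_types = FALSE,
                      progress = FALSE))
    check_parse_problems(raw, path)
    raw <- raw %>% mutate(pos = .data$start)
  }
  cpg_track(raw[, c("chrom", "pos", "meth", "unmeth")],
            coverage_min = coverage_min, collapse_strands = collapse_strands,
            sample_id = sample_id, tissue = tissue)
}

check_parse_problems <- function(x, path) {
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(paste0("malformed row in ", path, " at line ", probs$row[1],
                 ": ", probs$expected[1], " expected, got ",
                 probs$actual[1]))
  }
  invisible(x)
}

#' Write a track as a canonical per-CpG TSV
#'
#' Columns: `chrom, pos, meth, unmeth, depth, ratio` (0-based positions).
#' Re-reading with [read_cpg_table()] (`dialect = "canonical"`) reproduces
#' the same `(chrom, pos, ratio)` triples.
#'
#' @param track A track tibble.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "pos", "meth", "unmeth",
                             "depth", "ratio")], path, progress = FALSE)
  invisible(path)
}

#' Combine replicate tracks for one tissue
#'
#' Two pooling rules are supported. `average_ratios` averages, per site, the
#' methylation ratios of the replicates in which that site independently
#' passed the coverage filter — the usual rule for well-covered samples.
#' `sum_calls` pools the methylated and unmethylated calls across replicates
#' first and applies the coverage filter to the pooled counts — the rule for
#' low-coverage samples (e.g. oocyte methylomes), where per-replicate
#' filtering would discard most of the genome.
#'
#' @param tracks A list of track tibbles for the same tissue.
#' @param mode `"average_ratios"` or `"sum_calls"`.
#' @param coverage_min Coverage filter applied to pooled counts
#'   (`sum_calls`) or inherited per replicate (`average_ratios`).
#' @return A single track tibble. Under `average_ratios` the `ratio` column
#'   is the replicate mean and may differ from `meth / depth` of the summed
#'   counts, which are kept for bookkeeping.
#' @export
combine_replicates <- function(tracks, mode = c("average_ratios", "sum_calls"),
                               coverage_min = 5) {
  if (!is.list(tracks) || length(tracks) == 0 || inherits(tracks, "data.frame")) {
    abort("`tracks` must be a non-empty list of track tibbles")
  }
  mode <- match.arg(mode)
  tissues <- unique(unlist(lapply(tracks, function(t) attr(t, "tissue") %||% NA)))
  tissues <- tissues[!is.na(tissues)]
  if (length(tissues) > 1) {
    abort(paste0("replicates carry different tissue labels: ",
                 paste(tissues, collapse = ", ")))
  }
  tissue <- if (length(tissues) == 1) tissues else NULL

  pooled <- bind_rows(lapply(seq_along(tracks), function(i) {
    tracks[[i]] %>% mutate(.rep = i)
  }))

  if (mode == "sum_calls") {
    out <- pooled %>%
      group_by(.data$chrom, .data$pos) %>%
      summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                .groups = "drop")
    return(cpg_track(out, coverage_min = coverage_min,
                     collapse_strands = FALSE, tissue = tissue))
  }

  out <- pooled %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
              .ratio = if (all(is.na(.data$ratio))) NA_real_
                       else mean(.data$ratio, na.rm = TRUE),
              .groups = "drop")
  tr <- cpg_track(out[, c("chrom", "pos", "meth", "unmeth")],
                  coverage_min = coverage_min, collapse_strands = FALSE,
                  tissue = tissue)
  out <- out %>% arrange(.data$chrom, .data$pos)
  tr$ratio <- out$.ratio
  tr
}

#' Union of CpG positions across tracks
#'
#' The CpG "universe" anchors window frames so that windows are comparable
#' across tissues: every sample's windows are indexed over the same ordered
#' CpG list, and per-sample informativeness is judged within that frame.
#'
#' @param ... Track tibbles, or a single list of tracks (e.g. a
#'   [track_panel()]).
#' @return A tibble with columns `chrom`, `pos`, sorted and unique.
#' @export
cpg_universe <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1 && is.list(tracks[[1]]) &&
      !inherits(tracks[[1]], "data.frame")) {
    tracks <- tracks[[1]]
  }
  if (length(tracks) == 0) abort("no tracks supplied")
  bind_rows(lapply(tracks, function(t) t[, c("chrom", "pos")])) %>%
    distinct() %>%
    arrange(.data$chrom, .data$pos)
}

#' Fraction of universe CpGs with a methylation ratio
#'
#' A QC figure: the proportion of the genome's CpG sites at which a track
#' passes the coverage filter (whole-genome bisulfite experiments typically
#' reach ~90–97%; low-input oocyte libraries much less).
#'
#' @param track A track tibble.
#' @param universe A tibble of `chrom`, `pos` (see [cpg_universe()]).
#' @return A single number in `[0, 1]`.
#' @export
coverage_summary <- function(track, universe) {
  if (nrow(universe) == 0) abort("empty CpG universe")
  covered <- track %>% filter(!is.na(.data$ratio))
  n_cov <- nrow(dplyr::semi_join(universe, covered, by = c("chrom", "pos")))
  n_cov / nrow(universe)
}

#' Assemble a tissue panel of methylome tracks
#'
#' @param tracks Named list of track tibbles. Names are tissue labels and
#'   must include `oocyte`, `sperm`, `blastocyst` and `placenta`; all other
#'   names are taken as somatic tissues unless `somatic` is given.
#' @param somatic Character vector of the somatic tissue labels. Defaults to
#'   every track that is not one of the four reserved labels.
#' @return A `track_panel`: the named list of tracks with attributes
#'   `somatic` (labels) and `universe` (the shared CpG frame).
#' @export
track_panel <- function(tracks, somatic = NULL) {
  core <- c("oocyte", "sperm", "blastocyst", "placenta")
  missing_core <- setdiff(core, names(tracks))
  if (length(missing_core) > 0) {
    abort(paste0("panel is missing track(s): ",
                 paste(missing_core, collapse = ", ")))
  }
  if (is.null(somatic)) somatic <- setdiff(names(tracks), core)
  if (length(somatic) < 1) abort("panel needs at least one somatic track")
  bad <- setdiff(somatic, names(tracks))
  if (length(bad) > 0) {
    abort(paste0("somatic label(s) with no track: ", paste(bad, collapse = ", ")))
  }
  structure(tracks,
            somatic = somatic,
            universe = cpg_universe(tracks),
            class = "track_panel")
}

#' @export
print.track_panel <- function(x, ...) {
  uni <- attr(x, "universe")
  cat("<track_panel> ", length(x), " tissues, ",
      nrow(uni), " universe CpGs on ",
      length(unique(uni$chrom)), " chromosome(s)\n", sep = "")
  cat("  tissues:", paste(names(x), collapse = ", "), "\n")
  cat("  somatic:", paste(attr(x, "somatic"), collapse = ", "), "\n")
  invisible(x)
}
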