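# Fixture builders and independent brute-force oracles. The oracles
# deliberately use direct, unoptimised computation (per-window loops,
# all-pairs interval scans, per-basepair coverage) so they share no code
# path with the implementation they check.

# track with prescribed ratios at given positions (depth chosen so that
# meth/depth reproduces `ratio` exactly when ratio has <= 2 decimals)
make_track <- function(ratios, pos = NULL, chrom = "chr1", depth = 100,
                       tissue = NULL) {
  n <- length(ratios)
  if (is.null(pos)) pos <- seq(0L, by = 50L, length.out = n)
  meth <- as.integer(round(ratios * depth))
  cpg_track(tibble::tibble(chrom = chrom, pos = as.integer(pos),
                           meth = meth, unmeth = depth - meth),
            coverage_min = 5, collapse_strands = FALSE, tissue = tissue)
}

make_universe <- function(n, chrom = "chr1", spacing = 50L, from = 0L) {
  tibble::tibble(chrom = chrom,
                 pos = seq(from, by = spacing, length.out = n))
}

# ---- window oracle: per-window recomputation from the ratio vector ----

oracle_windows <- function(pos, ratio, w = 25, step = 1, inf_min = 10,
                           mode = "gamete") {
  m <- length(pos)
  if (m < w) return(data.frame(idx = integer(), state = character()))
  starts <- seq(1L, m - w + 1L, by = step)
  out <- lapply(starts, function(i) {
    r <- ratio[i:(i + w - 1L)]
    r <- r[!is.na(r)]
    n <- length(r)
    if (n < inf_min) {
      return(data.frame(idx = i, n_informative = n, mean = NA_real_,
                        sd = NA_real_, state = "none"))
    }
    mu <- mean(r)
    s <- stats::sd(r)
    state <- if (mode == "gamete") {
      if (mu - s > 0.75) "methylated"
      else if (mu + s < 0.25) "unmethylated"
      else "none"
    } else {
      if (mu - 1.5 * s > 0.2 && mu + 1.5 * s < 0.8) "intermediate"
      else "none"
    }
    data.frame(idx = i, n_informative = n, mean = mu, sd = s, state = state)
  })
  do.call(rbind, out)
}

# ---- naive interval oracles ----

# merge touching-or-overlapping intervals by repeated all-pairs fusion
oracle_merge <- function(df) {
  rows <- split(df, seq_len(nrow(df)))
  changed <- TRUE
  while (changed && length(rows) > 1) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i >= j || is.null(rows[[i]]) || is.null(rows[[j]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom && a$start <= b$end && b$start <= a$end) {
          rows[[i]]$start <- min(a$start, b$start)
          rows[[i]]$end <- max(a$end, b$end)
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    rows <- Filter(Negate(is.null), rows)
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$end), c("chrom", "start", "end")]
}

# all-pairs intersections above a shared-CpG gate
oracle_intersections <- function(a, b, universe, min_shared) {
  res <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (e <= s) next
      pos <- universe$pos[universe$chrom == a$chrom[i]]
      shared <- sum(pos >= s & pos < e)
      if (shared > min_shared) {
        res[[length(res) + 1]] <- data.frame(chrom = a$chrom[i], start = s,
                                             end = e, shared_cpgs = shared)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), shared_cpgs = integer()))
  }
  out <- unique(do.call(rbind, res))
  out[order(out$chrom, out$start, out$end), ]
}

# per-basepair coverage of a region by a feature set
oracle_covered_bp <- function(region, features) {
  bp <- region$start:(region$end - 1L)
  covered <- rep(FALSE, length(bp))
  feats <- features[features$chrom == region$chrom, , drop = FALSE]
  for (j in seq_len(nrow(feats))) {
    covered <- covered | (bp >= feats$start[j] & bp < feats$end[j])
  }
  sum(covered)
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                           max_len = 800, state = "methylated") {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(max_len, n, replace = TRUE),
                 state = state)
}

# match planted DMRs to called gDMRs by same-origin interval overlap
planted_recall <- function(called, planted) {
  vapply(seq_len(nrow(planted)), function(i) {
    any(called$chrom == planted$chrom[i] &
          called$start < planted$end[i] &
          called$end > planted$start[i] &
          called$origin == planted$origin[i])
  }, logical(1))
}

called_precision <- function(called, planted) {
  vapply(seq_len(nrow(called)), function(i) {
    any(planted$chrom == called$chrom[i] &
          planted$start < called$end[i] &
          planted$end > called$start[i] &
          planted$origin == called$origin[i])
  }, logical(1))
}
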