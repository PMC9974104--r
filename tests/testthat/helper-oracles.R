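# Independent oracles used across tests. These are deliberately naive
# (enumeration, position-by-position coverage, hand formulas) and never call
# the code paths they check.

# All ATG->stop ORFs by scanning every start position; most 5' ATG per
# (frame, stop) kept. Returns a data frame sorted by (start, end).
brute_force_orfs <- function(seq, min_aa) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (i in seq_len(L - 5L)) {                    # 1-based ATG position
    if (substring(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= L) {
      cod <- substring(seq, j, j + 2L)
      if (cod %in% stops) {
        aa <- (j - i) / 3L
        if (aa >= min_aa) {
          found[[length(found) + 1L]] <-
            c(start = i - 1L, end = j + 2L, frame = (i - 1L) %% 3L)
        }
        break
      }
      j <- j + 3L
    }
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  df <- as.data.frame(do.call(rbind, found))
  # most 5' ATG per (frame, end)
  df <- df[order(df$start), ]
  df <- df[!duplicated(df[, c("frame", "end")]), c("start", "end")]
  df <- df[order(df$start, df$end), ]
  rownames(df) <- NULL
  df
}

# Benjamini-Hochberg step-up, written out longhand.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# Fisher exact p by enumeration over all 2x2 tables with the observed
# margins. Cells: x11 = both, x12 = a_only, x21 = b_only, x22 = neither.
fisher_enum_p <- function(both, a_only, b_only, neither,
                          alternative = "two.sided") {
  na <- both + a_only            # |A|
  nb <- both + b_only            # |B|
  N <- both + a_only + b_only + neither
  ks <- max(0L, na + nb - N):min(na, nb)
  pr <- vapply(ks, function(k) {
    exp(lchoose(nb, k) + lchoose(N - nb, na - k) - lchoose(N, na))
  }, numeric(1))
  p_obs <- pr[ks == both]
  if (alternative == "greater") {
    sum(pr[ks >= both])
  } else if (alternative == "less") {
    sum(pr[ks <= both])
  } else {
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
}

# Position-by-position intersection of peak sets on a toy chromosome.
coverage_intersect <- function(peak_sets, chrom_len) {
  cov <- rep(TRUE, chrom_len)
  for (p in peak_sets) {
    covered <- rep(FALSE, chrom_len)
    for (i in seq_len(nrow(p))) {
      a <- p$start[i] + 1L; b <- p$end[i]
      covered[a:b] <- TRUE
    }
    cov <- cov & covered
  }
  # maximal runs of TRUE -> 0-based half-open intervals
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# All-pairs window assignment check: is the peak within the gene's
# strand-aware [-up, +down) TSS window by >= 1 bp?
brute_force_assigned <- function(peak, gene, up, down) {
  if (gene$strand == "+") {
    ws <- gene$tss - up; we <- gene$tss + down
  } else {
    ws <- gene$tss - down; we <- gene$tss + up
  }
  ws <- max(ws, 0)
  peak$start < we && peak$end > ws
}

# Random amino-acid string.
random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Substitute positions `at` (1-based) of an amino-acid string with a
# different residue.
mutate_aa <- function(aa, at) {
  v <- strsplit(aa, "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in at) v[i] <- setdiff(alphabet, v[i])[1]
  paste(v, collapse = "")
}

# Small fixture shared by several test files.
small_fixture <- function(seed = 7) {
  simulate_study(fixture_config(seed = seed,
                                n_lnc_transcripts = 14,
                                n_coding_transcripts = 10,
                                n_tumor = 30, n_normal = 30,
                                n_pos_controls = 60, n_neg_controls = 200))
}
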