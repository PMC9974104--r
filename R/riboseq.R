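# Ribo-seq QC, ATG ORF enumeration, frame-bias translation calling, and
# ORF de-duplication. All transcript coordinates are 0-based half-open.

#' Reduce aligned ribosome footprints to P-site counts
#'
#' Applies a fixed P-site offset to the 5' end of each read and aggregates
#' to per-(replicate, transcript, position) counts. Reads outside the
#' accepted length range, or whose offset position falls outside the read,
#' are dropped.
#'
#' @param reads data frame with columns `replicate`, `transcript_id`,
#'   `five_prime` (0-based 5'-most transcript position) and `length`.
#' @param offset P-site offset from the 5' end (nt).
#' @param length_range two-element numeric; reads with lengths outside this
#'   closed range are dropped.
#' @return data frame (`replicate`, `transcript_id`, `position`, `count`)
#'   with attribute `n_dropped`, the number of discarded reads.
#' @export
#' @examples
#' r <- data.frame(replicate = "rep1", transcript_id = "tx1",
#'                 five_prime = c(100, 40), length = c(30, 20))
#' assign_psites(r)  # the 20-nt read is dropped; P-site at 112
assign_psites <- function(reads, offset = 12L, length_range = c(25L, 34L)) {
  cols <- c("replicate", "transcript_id", "five_prime", "length")
  stopifnot(all(cols %in% names(reads)))
  empty <- data.frame(replicate = character(), transcript_id = character(),
                      position = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  keep <- reads$length >= length_range[1] & reads$length <= length_range[2]
  pos <- reads$five_prime + offset
  bad <- pos < 0
  if (any(bad & keep)) {
    warning(sum(bad & keep), " read(s) dropped: negative P-site position")
  }
  keep <- keep & !bad
  n_dropped <- sum(!keep)
  r <- reads[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    attr(empty, "n_dropped") <- n_dropped
    return(empty)
  }
  key <- paste(r$replicate, r$transcript_id, pos[keep], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    replicate = vapply(parts, `[[`, character(1), 1L),
    transcript_id = vapply(parts, `[[`, character(1), 2L),
    position = as.integer(vapply(parts, `[[`, character(1), 3L)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$replicate, out$transcript_id, out$position), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Ribo-seq quality-control metrics
#'
#' Computes the standard ribosome-profiling QC panel: the read-length
#' histogram (when read lengths are supplied), global frame fractions of
#' P-sites over annotated CDSs, metagene profiles around annotated start and
#' stop codons, and the matrix of between-replicate Pearson correlations of
#' per-transcript summed counts.
#'
#' @param psites P-site data frame (`replicate`, `transcript_id`,
#'   `position`, `count`).
#' @param cds data frame (`transcript_id`, `cds_start`, `cds_end`) of
#'   annotated coding regions (0-based half-open); may be empty, in which
#'   case frame fractions and metagenes are omitted with a warning.
#' @param window half-width (nt) of the metagene windows.
#' @param read_lengths optional data frame (`replicate`, `length`, `count`).
#' @return object of class `riboseq_qc`: a list with `length_histogram`,
#'   `frame_fractions_global`, `metagene_start`, `metagene_stop`, and
#'   `replicate_r`.
#' @export
qc_metrics <- function(psites, cds, window = 50L, read_lengths = NULL) {
  stopifnot(all(c("replicate", "transcript_id", "position", "count") %in% names(psites)))

  length_histogram <- NULL
  if (!is.null(read_lengths) && nrow(read_lengths) > 0) {
    length_histogram <- tapply(read_lengths$count, read_lengths$length, sum)
    length_histogram <- setNames(as.integer(length_histogram),
                                 names(length_histogram))
  }

  frame_fractions <- NULL
  metagene_start <- metagene_stop <- NULL
  if (is.null(cds) || nrow(cds) == 0) {
    warning("no CDS annotations: frame fractions and metagene omitted")
  } else {
    m <- match(psites$transcript_id, cds$transcript_id)
    on_cds <- !is.na(m) &
      psites$position >= cds$cds_start[m] &
      psites$position < cds$cds_end[m]
    if (any(on_cds)) {
      fr <- (psites$position[on_cds] - cds$cds_start[m[on_cds]]) %% 3L
      tot <- tapply(psites$count[on_cds], factor(fr, levels = 0:2), sum)
      tot[is.na(tot)] <- 0
      frame_fractions <- as.numeric(tot) / sum(tot)
      names(frame_fractions) <- c("frame0", "frame1", "frame2")
    }
    offs <- seq(-window, window)
    mg <- function(anchor_pos) {
      # mean count per offset across annotated transcripts (zeros included)
      acc <- numeric(length(offs))
      m2 <- match(psites$transcript_id, cds$transcript_id)
      ok <- !is.na(m2)
      rel <- psites$position[ok] - anchor_pos[m2[ok]]
      inw <- rel >= -window & rel <= window
      if (any(inw)) {
        s <- tapply(psites$count[ok][inw],
                    factor(rel[inw], levels = offs), sum)
        s[is.na(s)] <- 0
        acc <- as.numeric(s)
      }
      n_rep <- length(unique(psites$replicate))
      setNames(acc / max(1L, nrow(cds) * max(1L, n_rep)), offs)
    }
    metagene_start <- mg(setNames(cds$cds_start, cds$transcript_id))
    metagene_stop <- mg(setNames(cds$cds_end - 3L, cds$transcript_id))
  }

  reps <- sort(unique(psites$replicate))
  txs <- sort(unique(psites$transcript_id))
  gene_counts <- matrix(0, nrow = length(txs), ncol = length(reps),
                        dimnames = list(txs, reps))
  agg <- tapply(psites$count,
                list(factor(psites$transcript_id, levels = txs),
                     factor(psites$replicate, levels = reps)), sum)
  agg[is.na(agg)] <- 0
  gene_counts[] <- agg
  replicate_r <- if (length(reps) >= 2) cor(gene_counts) else
    matrix(1, 1, 1, dimnames = list(reps, reps))

  structure(list(length_histogram = length_histogram,
                 frame_fractions_global = frame_fractions,
                 metagene_start = metagene_start,
                 metagene_stop = metagene_stop,
                 replicate_r = replicate_r),
            class = "riboseq_qc")
}

#' @export
print.riboseq_qc <- function(x, ...) {
  cat("Ribo-seq QC\n")
  if (!is.null(x$frame_fractions_global)) {
    cat("  CDS frame fractions:",
        paste(sprintf("%.3f", x$frame_fractions_global), collapse = " / "), "\n")
  }
  if (!is.null(x$replicate_r) && nrow(x$replicate_r) >= 2) {
    lo <- min(x$replicate_r[lower.tri(x$replicate_r)])
    cat("  min between-replicate Pearson r:", sprintf("%.3f", lo), "\n")
  }
  invisible(x)
}

#' Enumerate maximal ATG-to-stop ORFs in a transcript sequence
#'
#' Scans all three reading frames and reports, for every in-frame stop
#' codon, the ORF starting at the most 5' ATG after the previous in-frame
#' stop (the longest-isoform convention), provided the translated length is
#' at least `min_aa` amino acids (stop excluded).
#'
#' @param seq a single DNA string over A/C/G/T.
#' @param transcript_id identifier used to build ORF ids.
#' @param min_aa minimum amino-acid length (stop excluded).
#' @return data frame of ORF candidates (`orf_id`, `transcript_id`, `start`,
#'   `end` 0-based half-open including the stop codon, `aa_seq`).
#' @export
#' @examples
#' enumerate_atg_orfs("ATGAAATAG", "tx", min_aa = 1)  # one ORF, "MK"
enumerate_atg_orfs <- function(seq, transcript_id = "tx", min_aa = 10L) {
  stopifnot(length(seq) == 1L, is.character(seq))
  if (grepl("[^ACGT]", seq)) stop("sequence must be over {A,C,G,T}", call. = FALSE)
  L <- nchar(seq)
  stops <- stop_codons()
  rows <- list()
  for (frame in 0:2) {
    first <- frame + 1L
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 2L) next
    at <- first + 3L * (seq_len(n_cod) - 1L)
    cod <- substring(seq, at, at + 2L)
    is_stop <- cod %in% stops
    is_atg <- cod == "ATG"
    if (!any(is_stop) || !any(is_atg)) next
    stop_idx <- which(is_stop)
    atg_idx <- which(is_atg)
    prev_stop <- c(0L, stop_idx[-length(stop_idx)])
    for (k in seq_along(stop_idx)) {
      cand <- atg_idx[atg_idx > prev_stop[k] & atg_idx < stop_idx[k]]
      if (length(cand) == 0) next
      a <- cand[1]                       # most 5' ATG in this stop group
      aa_len <- stop_idx[k] - a
      if (aa_len < min_aa) next
      start0 <- at[a] - 1L
      end0 <- at[stop_idx[k]] + 2L       # 0-based exclusive end of stop codon
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = sprintf("%s:%d-%d", transcript_id, start0, end0),
        transcript_id = transcript_id,
        start = start0, end = end0,
        aa_seq = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(orf_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  nt <- Biostrings::DNAStringSet(substring(seq, out$start + 1L, out$end - 3L))
  out$aa_seq <- as.character(Biostrings::translate(nt))
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Enumerate ATG ORFs across a set of transcripts
#'
#' @param sequences named character vector of transcript sequences.
#' @param min_aa minimum amino-acid length.
#' @return row-bound [enumerate_atg_orfs()] results.
#' @export
enumerate_atg_orfs_set <- function(sequences, min_aa = 10L) {
  res <- lapply(names(sequences), function(tx) {
    enumerate_atg_orfs(sequences[[tx]], transcript_id = tx, min_aa = min_aa)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call translated ORFs by an exact binomial frame-bias test
#'
#' For each candidate ORF, P-sites falling within `[start, end)` (pooled
#' across replicates) are binned by frame relative to the ORF start. Under
#' no translation the frame-0 share is 1/3; the reported p-value is the
#' one-sided exact binomial tail `P(X >= x0 | n, 1/3)` on the frame-0 count.
#' Benjamini-Hochberg q-values are computed across tested candidates only;
#' candidates with fewer than `min_psites` P-sites are reported untested
#' (`NA` p and q). Overlapping candidates are each tested independently.
#'
#' @param psites P-site data frame (`replicate`, `transcript_id`,
#'   `position`, `count`).
#' @param candidates ORF candidate data frame from [enumerate_atg_orfs()].
#' @param min_psites minimum pooled P-sites for an ORF to be tested.
#' @param alpha significance level recorded for downstream calls.
#' @return data frame of ORF calls: candidate columns plus `n_psites`,
#'   `frame0_fraction`, `frame1_fraction`, `frame2_fraction`, `p_value`,
#'   `q_value`, `tested`, `called` (tested and `q_value < alpha`).
#' @export
call_translated_orfs <- function(psites, candidates, min_psites = 10L,
                                 alpha = 0.05) {
  stopifnot(min_psites >= 1)
  n <- nrow(candidates)
  n_psites <- integer(n)
  f0 <- f1 <- f2 <- integer(n)
  sp <- split(seq_len(nrow(psites)), psites$transcript_id)
  for (i in seq_len(n)) {
    idx <- sp[[candidates$transcript_id[i]]]
    if (is.null(idx)) next
    pos <- psites$position[idx]
    cnt <- psites$count[idx]
    inorf <- pos >= candidates$start[i] & pos < candidates$end[i]
    if (!any(inorf)) next
    fr <- (pos[inorf] - candidates$start[i]) %% 3L
    n_psites[i] <- sum(cnt[inorf])
    f0[i] <- sum(cnt[inorf][fr == 0L])
    f1[i] <- sum(cnt[inorf][fr == 1L])
    f2[i] <- sum(cnt[inorf][fr == 2L])
  }
  tested <- n_psites >= min_psites
  p <- rep(NA_real_, n)
  p[tested] <- pbinom(f0[tested] - 1L, n_psites[tested], 1 / 3,
                      lower.tail = FALSE)
  q <- rep(NA_real_, n)
  q[tested] <- p.adjust(p[tested], method = "BH")
  out <- candidates
  out$n_psites <- n_psites
  out$frame0_fraction <- ifelse(n_psites > 0, f0 / n_psites, NA_real_)
  out$frame1_fraction <- ifelse(n_psites > 0, f1 / n_psites, NA_real_)
  out$frame2_fraction <- ifelse(n_psites > 0, f2 / n_psites, NA_real_)
  out$p_value <- p
  out$q_value <- q
  out$tested <- tested
  out$called <- tested & !is.na(q) & q < alpha
  out
}

#' De-duplicate highly similar ORFs
#'
#' Greedy clustering by global amino-acid identity: ORFs are visited in
#' order of decreasing P-site support (ties broken by lexicographic
#' `orf_id`); each joins the first existing cluster whose representative
#' shares identity at or above `identity_threshold`, otherwise it founds a
#' new cluster. Identity is matches over global-alignment length
#' (gap-inclusive).
#'
#' @param calls ORF call data frame with `orf_id`, `aa_seq` and `n_psites`.
#' @param identity_threshold fraction in (0, 1].
#' @return the representative rows of `calls`, with a `cluster_size` column.
#' @export
deduplicate_orfs <- function(calls, identity_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(calls) <= 1) {
    if (nrow(calls) == 1) calls$cluster_size <- 1L
    return(calls)
  }
  ord <- order(-calls$n_psites, calls$orf_id)
  calls <- calls[ord, ]
  reps <- integer(0)            # row indices of representatives
  sizes <- integer(0)
  aa <- Biostrings::AAStringSet(calls$aa_seq)
  for (i in seq_len(nrow(calls))) {
    joined <- FALSE
    for (k in seq_along(reps)) {
      if (aa_identity(aa[[i]], aa[[reps[k]]]) >= identity_threshold) {
        sizes[k] <- sizes[k] + 1L
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      sizes <- c(sizes, 1L)
    }
  }
  out <- calls[reps, ]
  out$cluster_size <- sizes
  rownames(out) <- NULL
  out
}

# Global pairwise amino-acid identity: matches / alignment length (with gaps).
aa_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(list(a)), b,
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1
  )
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}
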