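#' Simulate ribosome-profiling P-site counts
#'
#' Draws P-sites for every transcript in the synthetic transcriptome. Planted
#' lncRNA ORFs and annotated coding CDSs receive 3-nt periodic signal: a
#' P-site lands in frame 0 (relative to the ORF start) with probability
#' `periodicity + (1 - periodicity)/3` and in frames 1/2 with equal shares of
#' the remainder, at a uniformly chosen codon. Non-planted lncRNAs receive
#' frame-uniform background at positions uniform over the transcript.
#' Per-transcript rates are Gamma-distributed around the configured depth and
#' shared across replicates; replicate counts are independent Poisson draws
#' given those rates (a negative-binomial marginal with size `nb_size`).
#'
#' @param config a [fixture_config()].
#' @param transcriptome a [gen_transcriptome()] result.
#' @return list with `psites` (data frame: `replicate`, `transcript_id`,
#'   `position` 0-based, `count`) and `read_lengths` (data frame:
#'   `replicate`, `length`, `count`; lengths peak at 30 nt).
#' @export
gen_rpf <- function(config, transcriptome) {
  stopifnot(inherits(config, "fixture_config"),
            inherits(transcriptome, "transcriptome"))
  if (config$rpf_depth == 0 && nrow(transcriptome$orfs) > 0) {
    warning("rpf_depth is 0 with planted ORFs present; returning empty table")
    empty <- data.frame(replicate = character(), transcript_id = character(),
                        position = integer(), count = integer(),
                        stringsAsFactors = FALSE)
    return(list(psites = empty,
                read_lengths = data.frame(replicate = character(),
                                          length = integer(), count = integer())))
  }

  with_seed(stage_seed(config$seed, "rpf"), {
    p0 <- config$periodicity + (1 - config$periodicity) / 3
    pframe <- c(p0, (1 - p0) / 2, (1 - p0) / 2)
    n_rep <- config$n_rpf_replicates
    size <- config$nb_size

    # periodic regions: planted lncRNA ORFs plus coding CDSs
    periodic <- rbind(
      transcriptome$orfs[, c("transcript_id", "start", "end")],
      if (nrow(transcriptome$cds) > 0) {
        data.frame(transcript_id = transcriptome$cds$transcript_id,
                   start = transcriptome$cds$cds_start,
                   end = transcriptome$cds$cds_end,
                   stringsAsFactors = FALSE)
      }
    )
    bg_tx <- setdiff(
      transcriptome$transcripts$transcript_id[transcriptome$transcripts$type == "lncRNA"],
      transcriptome$orfs$transcript_id
    )
    tx_len <- setNames(transcriptome$transcripts$length,
                       transcriptome$transcripts$transcript_id)

    lam_per <- if (nrow(periodic) > 0) {
      rgamma(nrow(periodic), shape = size, rate = size / max(config$rpf_depth, 1e-9))
    } else numeric()
    lam_bg <- if (length(bg_tx) > 0 && config$background_depth > 0) {
      rgamma(length(bg_tx), shape = size, rate = size / config$background_depth)
    } else rep(0, length(bg_tx))

    out <- vector("list", n_rep)
    len_rows <- vector("list", n_rep)
    len_support <- 25:34
    len_w <- c(1, 2, 4, 7, 10, 12, 8, 4, 2, 1)  # peaked at 30 nt

    for (r in seq_len(n_rep)) {
      rep_id <- sprintf("rep%d", r)
      tx_all <- character(0); pos_all <- integer(0)

      if (nrow(periodic) > 0) {
        n_i <- rpois(nrow(periodic), lam_per)
        idx <- rep.int(seq_len(nrow(periodic)), n_i)
        if (length(idx) > 0) {
          n_codons <- (periodic$end - periodic$start) %/% 3L
          codon <- floor(runif(length(idx)) * n_codons[idx])
          frame <- sample.int(3L, length(idx), replace = TRUE, prob = pframe) - 1L
          pos <- periodic$start[idx] + 3L * as.integer(codon) + frame
          tx_all <- c(tx_all, periodic$transcript_id[idx])
          pos_all <- c(pos_all, as.integer(pos))
        }
      }
      if (length(bg_tx) > 0) {
        n_b <- rpois(length(bg_tx), lam_bg)
        idxb <- rep.int(seq_along(bg_tx), n_b)
        if (length(idxb) > 0) {
          posb <- floor(runif(length(idxb)) * tx_len[bg_tx][idxb])
          tx_all <- c(tx_all, bg_tx[idxb])
          pos_all <- c(pos_all, as.integer(posb))
        }
      }

      if (length(tx_all) > 0) {
        key <- paste(tx_all, pos_all, sep = "\r")
        tab <- table(key)
        parts <- strsplit(names(tab), "\r", fixed = TRUE)
        out[[r]] <- data.frame(
          replicate = rep_id,
          transcript_id = vapply(parts, `[[`, character(1), 1L),
          position = as.integer(vapply(parts, `[[`, character(1), 2L)),
          count = as.integer(tab),
          stringsAsFactors = FALSE
        )
      }
      n_reads <- length(tx_all)
      lens <- sample(len_support, n_reads, replace = TRUE, prob = len_w)
      lt <- table(factor(lens, levels = len_support))
      len_rows[[r]] <- data.frame(replicate = rep_id,
                                  length = len_support,
                                  count = as.integer(lt),
                                  stringsAsFactors = FALSE)
    }

    psites <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(psites)) {
      psites <- data.frame(replicate = character(), transcript_id = character(),
                           position = integer(), count = integer(),
                           stringsAsFactors = FALSE)
    }
    psites <- psites[order(psites$replicate, psites$transcript_id, psites$position), ]
    rownames(psites) <- NULL
    list(psites = psites, read_lengths = do.call(rbind, len_rows))
  })
}
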