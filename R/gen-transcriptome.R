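#' Generate a synthetic transcriptome with planted cryptic ORFs
#'
#' Builds lncRNA and protein-coding transcripts on a single synthetic
#' chromosome. A configurable fraction of lncRNAs carries one planted
#' ATG...stop ORF at a recorded position; an in-frame stop codon is placed
#' immediately upstream of the planted ATG so the planted start is the most
#' 5' ATG of its (frame, stop) group and is recoverable by
#' [enumerate_atg_orfs()]. Coding transcripts carry an annotated CDS used by
#' the ribo-seq QC metagene. Gene models are non-overlapping, strand-aware
#' intervals with a two-exon structure.
#'
#' All coordinates are 0-based half-open within the transcript (ORFs, CDS)
#' or the chromosome (gene models).
#'
#' @param config a [fixture_config()].
#' @return an object of class `transcriptome`: a list with `sequences`
#'   (named character vector), `transcripts`, `orfs` (planted ORFs),
#'   `cds`, `gene_models`, and `exons` data frames.
#' @export
gen_transcriptome <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n_lnc <- config$n_lnc_transcripts
  n_cod <- config$n_coding_transcripts
  if (n_lnc + n_cod < 1) stop("zero transcripts requested", call. = FALSE)

  with_seed(stage_seed(config$seed, "transcriptome"), {
    bases <- c("A", "C", "G", "T")
    sense <- sense_codons()
    stops <- stop_codons()

    lnc_ids <- if (n_lnc > 0) sprintf("LNC%03d", seq_len(n_lnc)) else character()
    cod_ids <- if (n_cod > 0) sprintf("PCG%03d", seq_len(n_cod)) else character()
    gene_ids <- c(lnc_ids, cod_ids)
    tx_ids <- paste0(gene_ids, ".t1")

    n_planted <- round(config$planted_orf_fraction * n_lnc)
    planted_idx <- if (n_planted > 0) sort(sample.int(n_lnc, n_planted)) else integer()

    seqs <- character(n_lnc + n_cod)
    orf_rows <- vector("list", n_lnc)
    cds_rows <- vector("list", n_cod)

    # One transcript: random background with an ORF spliced in at `s` (0-based),
    # guarded by an in-frame stop immediately upstream.
    build_with_orf <- function(aa_len) {
      orf_nt <- 3L * aa_len + 3L
      utr5 <- sample(60:240, 1L)
      utr3 <- sample(60:240, 1L)
      s <- utr5 + 3L                         # leave room for the guard stop
      len <- s + orf_nt + utr3
      x <- sample(bases, len, replace = TRUE)
      x[(s - 2L):s] <- strsplit(sample(stops, 1L), "")[[1]]   # guard, 1-based s-2..s
      orf <- c("ATG",
               sample(sense, aa_len - 1L, replace = TRUE),
               sample(stops, 1L))
      x[(s + 1L):(s + orf_nt)] <- unlist(strsplit(orf, ""))
      list(seq = paste(x, collapse = ""), start0 = s, end0 = s + orf_nt)
    }

    for (i in seq_len(n_lnc)) {
      if (i %in% planted_idx) {
        aa_len <- sample(30:100, 1L)
        b <- build_with_orf(aa_len)
        seqs[i] <- b$seq
        orf_rows[[i]] <- data.frame(
          orf_id = sprintf("%s:%d-%d", tx_ids[i], b$start0, b$end0),
          transcript_id = tx_ids[i],
          start = b$start0, end = b$end0,
          stringsAsFactors = FALSE
        )
      } else {
        len <- sample(400:900, 1L)
        seqs[i] <- paste(sample(bases, len, replace = TRUE), collapse = "")
      }
    }
    for (j in seq_len(n_cod)) {
      aa_len <- sample(80:200, 1L)
      b <- build_with_orf(aa_len)
      seqs[n_lnc + j] <- b$seq
      cds_rows[[j]] <- data.frame(
        transcript_id = tx_ids[n_lnc + j],
        cds_start = b$start0, cds_end = b$end0,
        stringsAsFactors = FALSE
      )
    }
    names(seqs) <- tx_ids

    transcripts <- data.frame(
      transcript_id = tx_ids,
      gene_id = gene_ids,
      type = c(rep("lncRNA", n_lnc), rep("coding", n_cod)),
      length = nchar(seqs),
      stringsAsFactors = FALSE
    )

    # Genomic layout: one gene per 70-kb slot (adjacent TSSs are then always
    # > 60 kb apart, so -30 kb/+10 kb TSS windows of different genes never
    # overlap and planted peak geometry stays gene-specific), two exons split
    # by a 2-kb intron.
    n_genes <- length(gene_ids)
    spacing <- 70000L
    gstart <- 10000L + spacing * (seq_len(n_genes) - 1L)
    intron_len <- 2000L
    glen <- transcripts$length + intron_len
    gend <- gstart + glen
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_models <- data.frame(
      gene_id = gene_ids,
      chrom = "chrS",
      strand = strand,
      start = gstart, end = gend,
      tss = ifelse(strand == "+", gstart, gend - 1L),
      tts = ifelse(strand == "+", gend - 1L, gstart),
      stringsAsFactors = FALSE
    )

    exon1_len <- pmax(1L, transcripts$length %/% 2L)
    exons <- rbind(
      data.frame(gene_id = gene_ids, start = gstart, end = gstart + exon1_len,
                 stringsAsFactors = FALSE),
      data.frame(gene_id = gene_ids,
                 start = gstart + exon1_len + intron_len,
                 end = gend, stringsAsFactors = FALSE)
    )
    exons <- exons[order(match(exons$gene_id, gene_ids), exons$start), ]
    rownames(exons) <- NULL

    orfs <- do.call(rbind, orf_rows[!vapply(orf_rows, is.null, logical(1))])
    if (is.null(orfs)) {
      orfs <- data.frame(orf_id = character(), transcript_id = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
    }
    cds <- do.call(rbind, cds_rows)
    if (is.null(cds)) {
      cds <- data.frame(transcript_id = character(), cds_start = integer(),
                        cds_end = integer(), stringsAsFactors = FALSE)
    }
    rownames(orfs) <- rownames(cds) <- NULL

    structure(
      list(sequences = seqs, transcripts = transcripts, orfs = orfs,
           cds = cds, gene_models = gene_models, exons = exons,
           chrom_length = 10000L + spacing * n_genes + 150000L),
      class = "transcriptome"
    )
  })
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("Synthetic transcriptome: ", nrow(x$transcripts), " transcripts (",
      sum(x$transcripts$type == "lncRNA"), " lncRNA, ",
      sum(x$transcripts$type == "coding"), " coding), ",
      nrow(x$orfs), " planted ORFs\n", sep = "")
  invisible(x)
}

#' Write transcript sequences to a FASTA file
#'
#' @param transcriptome a [gen_transcriptome()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  dna <- Biostrings::DNAStringSet(transcriptome$sequences)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}
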