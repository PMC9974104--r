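#' Simulate two ChIP peak sets and dependency scores with planted co-binding
#'
#' For each candidate gene a role decides its regulatory fixture: co-bound
#' targets receive one peak from each factor at the same locus inside their
#' strand-aware TSS window (-30 kb/+10 kb by default conventions of
#' [assign_peaks_to_genes()]) and passing (< -0.2) gene-effect scores in both
#' simulated cell lines; decoys get a peak from one factor only, a common
#' peak placed in a gene-free region outside every window, failing effect
#' scores, or no peaks at all.
#'
#' @param config a [fixture_config()].
#' @param gene_models gene-model data frame (`gene_id`, `chrom`, `strand`,
#'   `tss`, ...) as produced by [gen_transcriptome()].
#' @param candidate_gene_ids genes to plant roles for; default: all genes in
#'   `gene_models`.
#' @param roles optional data frame (`gene_id`, `peak_mode` in
#'   `in_window`/`single_factor`/`outside_window`/`none`, `effect_pass`
#'   logical) overriding the default role assignment (a
#'   `co_bound_fraction` share of co-bound targets, decoy modes cycled over
#'   the rest).
#' @param upstream,downstream TSS window extents used for placement.
#' @return list with `peaks_a`, `peaks_b` (BED-like data frames, 0-based
#'   half-open), `gene_effects` (data frame `gene_id`, `line1`, `line2`),
#'   `co_bound_target_ids`, and the `roles` used.
#' @export
gen_regulatory <- function(config, gene_models, candidate_gene_ids = NULL,
                           roles = NULL, upstream = 30000L, downstream = 10000L) {
  stopifnot(inherits(config, "fixture_config"))
  if (is.null(candidate_gene_ids)) candidate_gene_ids <- gene_models$gene_id
  stopifnot(all(candidate_gene_ids %in% gene_models$gene_id))

  with_seed(stage_seed(config$seed, "regulatory"), {
    n <- length(candidate_gene_ids)
    if (is.null(roles)) {
      n_co <- max(1L, round(config$co_bound_fraction * n))
      co <- sort(sample(candidate_gene_ids, min(n_co, n)))
      rest <- setdiff(candidate_gene_ids, co)
      decoy_modes <- c("single_factor", "outside_window", "in_window", "none")
      roles <- rbind(
        data.frame(gene_id = co, peak_mode = "in_window", effect_pass = TRUE,
                   stringsAsFactors = FALSE),
        if (length(rest) > 0) {
          m <- decoy_modes[(seq_along(rest) - 1L) %% 4L + 1L]
          data.frame(gene_id = rest, peak_mode = m,
                     # the "in_window" decoys fail on the dependency score
                     effect_pass = m != "in_window",
                     stringsAsFactors = FALSE)
        }
      )
    }
    stopifnot(all(c("gene_id", "peak_mode", "effect_pass") %in% names(roles)))
    gm <- gene_models[match(roles$gene_id, gene_models$gene_id), ]
    w <- config$peak_width

    win_start <- ifelse(gm$strand == "+", gm$tss - upstream, gm$tss - downstream)
    win_end <- ifelse(gm$strand == "+", gm$tss + downstream, gm$tss + upstream)
    win_start <- pmax(win_start, 0L)

    pa <- list(); pb <- list()
    # gene-free tail of the chromosome, beyond every TSS window
    tail0 <- max(gm$tss) + upstream + 5000L
    n_out <- 0L
    for (i in seq_len(nrow(roles))) {
      mode <- roles$peak_mode[i]
      if (mode == "none") next
      if (mode == "outside_window") {
        s <- tail0 + 1000L * n_out
        n_out <- n_out + 1L
      } else {
        s <- floor(runif(1, win_start[i], win_end[i] - w - 200L))
      }
      s <- as.integer(s)
      pa[[length(pa) + 1L]] <- data.frame(
        chrom = gm$chrom[i], start = s, end = s + w,
        name = sprintf("peakA_%s", roles$gene_id[i]),
        score = round(runif(1, 50, 1000)), strand = ".",
        stringsAsFactors = FALSE)
      if (mode != "single_factor") {
        jit <- as.integer(sample(-100:100, 1L))
        pb[[length(pb) + 1L]] <- data.frame(
          chrom = gm$chrom[i], start = s + jit, end = s + jit + w,
          name = sprintf("peakB_%s", roles$gene_id[i]),
          score = round(runif(1, 50, 1000)), strand = ".",
          stringsAsFactors = FALSE)
      }
    }
    empty_bed <- data.frame(chrom = character(), start = integer(),
                            end = integer(), name = character(),
                            score = numeric(), strand = character(),
                            stringsAsFactors = FALSE)
    peaks_a <- if (length(pa)) do.call(rbind, pa) else empty_bed
    peaks_b <- if (length(pb)) do.call(rbind, pb) else empty_bed
    peaks_a <- peaks_a[order(peaks_a$start), ]; rownames(peaks_a) <- NULL
    peaks_b <- peaks_b[order(peaks_b$start), ]; rownames(peaks_b) <- NULL

    pass <- roles$effect_pass
    gene_effects <- data.frame(
      gene_id = roles$gene_id,
      line1 = runif(nrow(roles), -1.0, -0.25),
      line2 = ifelse(pass, runif(nrow(roles), -1.0, -0.25),
                     runif(nrow(roles), -0.15, 0.2)),
      stringsAsFactors = FALSE
    )

    co_bound <- sort(roles$gene_id[roles$peak_mode == "in_window" & roles$effect_pass])
    list(peaks_a = peaks_a, peaks_b = peaks_b, gene_effects = gene_effects,
         co_bound_target_ids = co_bound, roles = roles)
  })
}

#' Write a peak data frame as BED6
#'
#' @param peaks data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` columns (0-based half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  n <- nrow(peaks)
  bed <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else sprintf("region_%d", seq_len(n)),
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else ".",
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
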