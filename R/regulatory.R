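# Peak genomic-category annotation, cross-dataset peak intersection,
# strand-aware peak-to-gene window assignment, and the final multi-evidence
# target triage. Peaks and windows are 0-based half-open data frames;
# IRanges does the interval arithmetic internally, per chromosome.

# Per-chromosome IRanges views of a 0-based half-open peak data frame.
# (IRanges is 1-based closed; the +1 shift converts on the way in/out.)
df_to_ir <- function(peaks, chrom) {
  keep <- peaks$chrom == chrom
  IRanges::IRanges(start = peaks$start[keep] + 1L, end = peaks$end[keep])
}

ir_to_df <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

#' Annotate peaks with a genomic category
#'
#' Categorizes each peak by its midpoint with the precedence
#' promoter-proximal (within `margin` of a TSS) > TTS-proximal (within
#' `margin` of a TTS) > exonic > intronic > distal intergenic (further than
#' `margin` from any TSS/TTS and outside gene bodies). Peaks on chromosomes
#' absent from the gene models are `unplaced` (with a warning). When no exon
#' table is supplied, gene-body midpoints are annotated exonic.
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`).
#' @param gene_models data frame (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tts`).
#' @param exons optional data frame (`gene_id`, `start`, `end`).
#' @param margin proximal distance (nt), default 3 kb.
#' @return character vector of categories, one per peak.
#' @export
annotate_peak_category <- function(peaks, gene_models, exons = NULL,
                                   margin = 3000L) {
  n <- nrow(peaks)
  out <- character(n)
  mid <- (peaks$start + peaks$end) %/% 2L
  known <- peaks$chrom %in% gene_models$chrom
  if (any(!known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from gene models")
  }
  for (i in seq_len(n)) {
    if (!known[i]) { out[i] <- "unplaced"; next }
    gm <- gene_models[gene_models$chrom == peaks$chrom[i], ]
    m <- mid[i]
    if (min(abs(m - gm$tss)) <= margin) { out[i] <- "promoter"; next }
    if (min(abs(m - gm$tts)) <= margin) { out[i] <- "tts_proximal"; next }
    body <- which(gm$start <= m & m < gm$end)
    if (length(body) > 0) {
      g <- gm$gene_id[body[1]]
      in_exon <- if (is.null(exons)) TRUE else {
        ex <- exons[exons$gene_id == g, ]
        any(ex$start <= m & m < ex$end)
      }
      out[i] <- if (in_exon) "exonic" else "intronic"
      next
    }
    out[i] <- "distal_intergenic"
  }
  out
}

#' Coordinate intersection of two or more peak sets
#'
#' A position belongs to the common set iff it is covered by at least one
#' peak in every input set; the result is the maximal such intervals.
#'
#' @param peak_sets list of >= 2 peak data frames (`chrom`, `start`, `end`).
#' @return data frame of common intervals (0-based half-open).
#' @export
intersect_peak_sets <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 2)
  if (any(vapply(peak_sets, nrow, integer(1)) == 0)) {
    warning("an input peak set is empty; the common set is empty")
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  chroms <- sort(Reduce(intersect, lapply(peak_sets, function(p) unique(p$chrom))))
  out <- lapply(chroms, function(ch) {
    irs <- lapply(peak_sets, function(p) IRanges::reduce(df_to_ir(p, ch)))
    ir_to_df(Reduce(IRanges::intersect, irs), ch)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Flag peaks sharing at least one base with a common set
#'
#' Venn-style peak-level overlap: a peak of a set is "shared" iff it
#' overlaps the coordinate-common set by >= `min_overlap` bases.
#'
#' @param peaks peak data frame.
#' @param common common-interval data frame (e.g. from
#'   [intersect_peak_sets()]).
#' @param min_overlap minimum shared bases (default 1).
#' @return logical vector, one per row of `peaks`.
#' @export
peaks_shared_with <- function(peaks, common, min_overlap = 1L) {
  if (nrow(peaks) == 0) return(logical(0))
  out <- rep(FALSE, nrow(peaks))
  if (nrow(common) == 0) return(out)
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    ov <- IRanges::countOverlaps(df_to_ir(peaks, ch), df_to_ir(common, ch),
                                 minoverlap = min_overlap)
    out[idx] <- ov > 0
  }
  out
}

#' Strand-aware window around each TSS
#'
#' On the + strand the window is `[tss - upstream, tss + downstream)`; on
#' the - strand, where upstream runs rightward, it is
#' `[tss - downstream, tss + upstream)`. Windows are clipped at position 0
#' (with a warning). With `strand_aware = FALSE` all genes use the + strand
#' convention.
#'
#' @param gene_models gene-model data frame.
#' @param upstream,downstream window extents (nt).
#' @param strand_aware logical.
#' @return data frame (`gene_id`, `chrom`, `start`, `end`).
#' @export
tss_windows <- function(gene_models, upstream = 30000L, downstream = 10000L,
                        strand_aware = TRUE) {
  stopifnot(upstream >= 0, downstream >= 0)
  minus <- strand_aware & gene_models$strand == "-"
  start <- ifelse(minus, gene_models$tss - downstream,
                  gene_models$tss - upstream)
  end <- ifelse(minus, gene_models$tss + upstream,
                gene_models$tss + downstream)
  if (any(start < 0)) {
    warning(sum(start < 0), " window(s) clipped at position 0")
    start <- pmax(start, 0L)
  }
  data.frame(gene_id = gene_models$gene_id, chrom = gene_models$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Assign peaks to genes by TSS-window overlap
#'
#' A peak is assigned to a gene iff it overlaps the gene's strand-aware
#' `[-upstream, +downstream)` TSS window by at least one base; a peak may be
#' assigned to several genes.
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`).
#' @param gene_models gene-model data frame.
#' @param upstream,downstream window extents (nt); defaults -30 kb/+10 kb.
#' @param strand_aware logical; see [tss_windows()].
#' @return data frame (`gene_id`, `peak_index`, `chrom`, `start`, `end`),
#'   one row per (gene, overlapping peak).
#' @export
assign_peaks_to_genes <- function(peaks, gene_models,
                                  upstream = 30000L, downstream = 10000L,
                                  strand_aware = TRUE) {
  win <- tss_windows(gene_models, upstream, downstream, strand_aware)
  empty <- data.frame(gene_id = character(), peak_index = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(win) == 0) return(empty)
  out <- lapply(intersect(unique(win$chrom), unique(peaks$chrom)), function(ch) {
    wi <- which(win$chrom == ch); pi <- which(peaks$chrom == ch)
    hits <- IRanges::findOverlaps(df_to_ir(win, ch), df_to_ir(peaks, ch))
    qi <- wi[S4Vectors::queryHits(hits)]
    si <- pi[S4Vectors::subjectHits(hits)]
    data.frame(gene_id = win$gene_id[qi],
               peak_index = si,
               chrom = peaks$chrom[si],
               start = peaks$start[si],
               end = peaks$end[si],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(empty)
  rownames(res) <- NULL
  res
}

#' Multi-evidence target triage
#'
#' Combines the four lines of evidence into the final target list: a gene is
#' nominated iff it is (1) co-upregulated by both factors, (2) tumor
#' upregulated, (3) harbors at least one common binding site within its TSS
#' window, and (4) has a gene-effect score below `effect_threshold`
#' (strict `<`) in every required cell line. Final targets are ordered by
#' ascending mean gene effect (strongest dependency first).
#'
#' @param co_up_genes,tumor_up_genes character vectors of gene ids.
#' @param common_peak_assignment [assign_peaks_to_genes()] result for the
#'   common peak set.
#' @param gene_effects data frame with `gene_id` and one numeric column per
#'   cell line.
#' @param effect_threshold dependency threshold (default -0.2).
#' @param required_lines cell-line column names that must all pass.
#' @param candidates genes to evaluate; default: the union of all inputs.
#' @return object of class `triage_report`: list with `trail` (per-gene
#'   flags), `final_targets`, and the thresholds used.
#' @export
triage_targets <- function(co_up_genes, tumor_up_genes,
                           common_peak_assignment, gene_effects,
                           effect_threshold = -0.2,
                           required_lines = setdiff(names(gene_effects), "gene_id"),
                           candidates = NULL) {
  if (length(required_lines) == 0) {
    stop("`required_lines` must name at least one cell line", call. = FALSE)
  }
  if (!all(required_lines %in% names(gene_effects))) {
    stop("required line(s) missing from `gene_effects`: ",
         paste(setdiff(required_lines, names(gene_effects)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(candidates)) {
    candidates <- sort(unique(c(co_up_genes, tumor_up_genes,
                                common_peak_assignment$gene_id,
                                gene_effects$gene_id)))
  }
  m <- match(candidates, gene_effects$gene_id)
  eff <- as.matrix(gene_effects[m, required_lines, drop = FALSE])
  missing_eff <- is.na(m)
  if (any(missing_eff)) {
    warning(sum(missing_eff),
            " candidate(s) lack gene-effect scores; dependency flag set FALSE")
  }
  dep <- !missing_eff &
    apply(eff < effect_threshold, 1, function(v) all(!is.na(v)) && all(v))

  trail <- data.frame(
    gene_id = candidates,
    co_upregulated_by_both = candidates %in% co_up_genes,
    tumor_upregulated = candidates %in% tumor_up_genes,
    has_common_binding_site_in_window = candidates %in% common_peak_assignment$gene_id,
    dependency_in_both_lines = dep,
    mean_effect = rowMeans(eff),
    stringsAsFactors = FALSE
  )
  pass <- trail$co_upregulated_by_both & trail$tumor_upregulated &
    trail$has_common_binding_site_in_window & trail$dependency_in_both_lines
  final <- trail$gene_id[pass][order(trail$mean_effect[pass])]

  structure(list(trail = trail, final_targets = final,
                 effect_threshold = effect_threshold,
                 required_lines = required_lines),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  t <- x$trail
  cat("Target triage: ", nrow(t), " candidates\n", sep = "")
  cat("  co-upregulated: ", sum(t$co_upregulated_by_both),
      "; tumor-up: ", sum(t$tumor_upregulated),
      "; common site in window: ", sum(t$has_common_binding_site_in_window),
      "; dependency in all lines: ", sum(t$dependency_in_both_lines),
      "\n", sep = "")
  cat("  final targets (", length(x$final_targets), "): ",
      paste(x$final_targets, collapse = ", "), "\n", sep = "")
  invisible(x)
}
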