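# Pooled CRISPR screen analysis: normalization, per-guide depletion
# statistics against the negative-control empirical null, ORF-level hit
# calling, and positive-control QC.

#' Normalize an sgRNA count matrix
#'
#' The default `control-median` method scales each sample so that its median
#' negative-control count equals the across-sample geometric mean of those
#' medians; `total` scales total counts the same way. Normalization is
#' idempotent.
#'
#' @param counts non-negative count matrix, guides x samples, with guide ids
#'   as row names.
#' @param library sgRNA library data frame (`sgrna_id`, `target_orf_id`,
#'   `class`); required for `control-median`.
#' @param method `"control-median"` or `"total"`.
#' @return list with `norm` (matrix) and `size_factors` (named vector).
#' @export
normalize_counts <- function(counts, library = NULL,
                             method = c("control-median", "total")) {
  method <- match.arg(method)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "),
         call. = FALSE)
  }
  if (method == "control-median") {
    if (is.null(library)) stop("`library` required for control-median", call. = FALSE)
    neg <- library$sgrna_id[library$class == "negative_control"]
    neg <- intersect(neg, rownames(counts))
    if (length(neg) == 0) {
      stop("control-median normalization needs >= 1 negative-control sgRNA",
           call. = FALSE)
    }
    ref <- apply(counts[neg, , drop = FALSE], 2, median)
  } else {
    ref <- colSums(counts)
  }
  if (any(ref == 0)) {
    stop("zero reference statistic in sample(s): ",
         paste(colnames(counts)[ref == 0], collapse = ", "), call. = FALSE)
  }
  sf <- ref / geometric_mean(ref)
  norm <- sweep(counts, 2, sf, "/")
  list(norm = norm, size_factors = sf)
}

#' Per-sgRNA log2 fold change and empirical depletion p-value
#'
#' The log2 fold change is `log2((mean day21 + pseudocount) / (mean day0 +
#' pseudocount))`, with replicate means taken before the ratio. The one-sided
#' depletion p-value is empirical against the negative-control lfc
#' distribution with the add-one correction:
#' `p = (1 + #{negative controls with lfc <= observed}) / (1 + m)`,
#' where `m` is the number of negative controls. Ties count.
#'
#' @param norm_counts normalized count matrix (guides x samples).
#' @param library sgRNA library data frame.
#' @param day0_cols,day21_cols column names or indices for the two
#'   timepoints; by default columns are matched by a `day0`/`day21` prefix.
#' @param pseudocount added to both means before the ratio.
#' @return data frame (`sgrna_id`, `target_orf_id`, `class`, `lfc`,
#'   `p_value`).
#' @export
sgrna_stats <- function(norm_counts, library,
                        day0_cols = grep("^day0", colnames(norm_counts)),
                        day21_cols = grep("^day21", colnames(norm_counts)),
                        pseudocount = 1) {
  if (length(day0_cols) == 0 || length(day21_cols) == 0) {
    stop("both timepoints must be present", call. = FALSE)
  }
  lib <- library[match(rownames(norm_counts), library$sgrna_id), ]
  if (anyNA(lib$sgrna_id)) stop("count matrix contains guides missing from the library",
                                call. = FALSE)
  m0 <- rowMeans(norm_counts[, day0_cols, drop = FALSE])
  m21 <- rowMeans(norm_counts[, day21_cols, drop = FALSE])
  lfc <- log2((m21 + pseudocount) / (m0 + pseudocount))

  neg_lfc <- lfc[lib$class == "negative_control"]
  m <- length(neg_lfc)
  if (m == 0) stop("no negative controls: empirical p undefined", call. = FALSE)
  # tie-inclusive rank via sorted controls
  sorted <- sort(neg_lfc)
  p <- (1 + findInterval(lfc, sorted)) / (1 + m)

  data.frame(sgrna_id = lib$sgrna_id,
             target_orf_id = lib$target_orf_id,
             class = lib$class,
             lfc = lfc, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call ORF-level screen hits
#'
#' A guide is significantly depleted iff `lfc <= lfc_threshold` (inclusive)
#' and `p_value < p_threshold` (strict); an ORF is a hit iff at least
#' `min_sgrnas` of its targeting guides are significantly depleted.
#'
#' @param stats per-guide statistics from [sgrna_stats()].
#' @param library sgRNA library data frame (defines the ORF universe; ORFs
#'   with no guide in `stats` are reported with zero and a warning).
#' @param lfc_threshold,p_threshold,min_sgrnas hit-calling thresholds.
#' @return data frame (`orf_id`, `n_sgrnas`, `n_sig_depleted`, `is_hit`).
#' @export
call_hits <- function(stats, library,
                      lfc_threshold = -log2(1.5), p_threshold = 0.05,
                      min_sgrnas = 2L) {
  orfs <- unique(library$target_orf_id[library$class == "targeting"])
  orfs <- orfs[!is.na(orfs)]
  st <- stats[stats$class == "targeting" & !is.na(stats$target_orf_id), ]
  sig <- st$lfc <= lfc_threshold & st$p_value < p_threshold
  n_all <- table(factor(st$target_orf_id, levels = orfs))
  n_sig <- table(factor(st$target_orf_id[sig], levels = orfs))
  if (any(n_all == 0)) {
    warning(sum(n_all == 0), " ORF(s) have no targeting sgRNAs in `stats`")
  }
  data.frame(orf_id = orfs,
             n_sgrnas = as.integer(n_all),
             n_sig_depleted = as.integer(n_sig),
             is_hit = as.integer(n_sig) >= min_sgrnas,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Positive-control screen QC
#'
#' Reports per-class median lfc and a one-sided rank-sum test that
#' positive-control lfcs are lower than negative-control lfcs; the screen
#' passes QC when that p-value is below `pass_alpha`.
#'
#' @param stats per-guide statistics from [sgrna_stats()].
#' @param pass_alpha p-value threshold for the pass flag.
#' @return list with `median_lfc` (by class), `rank_sum_p`, `pass`, and
#'   `evaluable`.
#' @export
positive_control_qc <- function(stats, pass_alpha = 0.01) {
  pos <- stats$lfc[stats$class == "positive_control"]
  neg <- stats$lfc[stats$class == "negative_control"]
  med <- tapply(stats$lfc, stats$class, median)
  if (length(pos) == 0 || length(neg) == 0) {
    return(list(median_lfc = med, rank_sum_p = NA_real_, pass = NA,
                evaluable = FALSE))
  }
  p <- wilcox.test(pos, neg, alternative = "less", exact = FALSE)$p.value
  list(median_lfc = med, rank_sum_p = p, pass = p < pass_alpha,
       evaluable = TRUE)
}
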