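# Two-group differential expression with BH-FDR, threshold-based gene
# selection, log-rank survival association, and Fisher set-overlap tests.

#' Two-group differential expression
#'
#' Per-gene log2 fold change (group2 minus group1 mean on the log2 scale)
#' with a Wilcoxon rank-sum test (default) or Welch t-test, and
#' Benjamini-Hochberg FDR across all genes. Genes constant across all
#' samples get `p = 1` by convention and are flagged.
#'
#' @param expr matrix, genes x samples, on the log2 scale.
#' @param groups character/factor of length `ncol(expr)` with exactly two
#'   levels; the second level (alphabetical, or factor order) is the
#'   numerator of the fold change.
#' @param test `"wilcox"` or `"welch"`.
#' @return data frame (`gene_id`, `lfc`, `p_value`, `fdr`, `constant`).
#' @export
differential_expression <- function(expr, groups, test = c("wilcox", "welch")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples", call. = FALSE)
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  x1 <- expr[, groups == g1, drop = FALSE]
  x2 <- expr[, groups == g2, drop = FALSE]
  lfc <- rowMeans(x2) - rowMeans(x1)
  constant <- apply(expr, 1, function(v) length(unique(v)) == 1L)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    if (constant[i]) return(1)
    if (test == "wilcox") {
      suppressWarnings(wilcox.test(x2[i, ], x1[i, ], exact = FALSE)$p.value)
    } else {
      t.test(x2[i, ], x1[i, ])$p.value
    }
  }, numeric(1))
  data.frame(gene_id = rownames(expr), lfc = lfc, p_value = p,
             fdr = p.adjust(p, method = "BH"), constant = constant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold-based gene selection from a DE result
#'
#' Applies the printed inequalities exactly: the fold-change bound is
#' inclusive (`>=`, or `<=` for down), the FDR bound strict (`<`).
#'
#' @param de [differential_expression()] result.
#' @param lfc_min non-negative log2 fold-change magnitude bound.
#' @param fdr_max FDR bound (strict).
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @return character vector of selected gene ids.
#' @export
#' @examples
#' de <- data.frame(gene_id = c("a", "b"), lfc = c(0.30, 0.20),
#'                  p_value = c(0.001, 0.001), fdr = c(0.005, 0.001))
#' select_genes(de, log2(1.2), 0.01, "up")  # "a" only
select_genes <- function(de, lfc_min, fdr_max,
                         direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(lfc_min), is.finite(fdr_max), lfc_min >= 0)
  keep <- switch(direction,
    up = de$lfc >= lfc_min,
    down = de$lfc <= -lfc_min,
    both = abs(de$lfc) >= lfc_min
  )
  de$gene_id[keep & de$fdr < fdr_max]
}

#' Log-rank association between survival and dichotomized expression
#'
#' Splits samples into high (`>=` cut) and low strata on `expression` and
#' performs the standard two-group log-rank test.
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1 observed, 0 censored).
#' @param expression numeric vector aligned with `time`.
#' @param split cut point; default the median of `expression`.
#' @return list with `statistic` (chi-square, 1 df), `p_value`, `n_high`,
#'   `n_low`.
#' @export
logrank_by_expression <- function(time, event, expression, split = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(expression))
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  if (is.null(split)) split <- median(expression)
  stratum <- ifelse(expression >= split, "high", "low")
  if (length(unique(stratum)) < 2) {
    stop("one stratum is empty (all-equal expression?); choose another split",
         call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)),
       n_high = sum(stratum == "high"),
       n_low = sum(stratum == "low"))
}

#' Fisher exact test for the overlap of two gene sets
#'
#' Builds the 2x2 membership table of `set_a` and `set_b` over an explicit
#' `universe` and applies Fisher's exact test. The odds ratio is the sample
#' odds ratio with a Haldane 0.5 correction applied to all cells when any
#' cell is zero.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible elements.
#' @param alternative `"two.sided"` (default), `"greater"` (enrichment) or
#'   `"less"`.
#' @return list with counts `both`, `a_only`, `b_only`, `neither`,
#'   `odds_ratio`, `p_value`, `alternative`.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("universe must be nonempty", call. = FALSE)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) + length(out_b) > 0) {
    stop("elements outside the universe: ",
         paste(head(unique(c(out_a, out_b)), 10), collapse = ", "),
         call. = FALSE)
  }
  ina <- universe %in% set_a
  inb <- universe %in% set_b
  both <- sum(ina & inb); a_only <- sum(ina & !inb)
  b_only <- sum(!ina & inb); neither <- sum(!ina & !inb)
  tab <- matrix(c(both, a_only, b_only, neither), nrow = 2)
  p <- fisher.test(tab, alternative = alternative)$p.value
  cells <- c(both, a_only, b_only, neither)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(both = both, a_only = a_only, b_only = b_only, neither = neither,
       odds_ratio = or, p_value = p, alternative = alternative)
}
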