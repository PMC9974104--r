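# AP-MS interactor filtering and expression-based prioritization.

#' Aggregate per-run AP-MS unique-peptide counts
#'
#' Collapses bait and control run matrices to one evidence row per protein.
#' The default aggregation is the maximum across runs (the most permissive
#' reading of "identified in the AP-MS"); `"sum"` is available.
#'
#' @param bait,control integer matrices, proteins x runs, same row order.
#' @param method `"max"` or `"sum"`.
#' @return data frame (`protein_id`, `unique_peptides_bait`,
#'   `unique_peptides_control`).
#' @export
aggregate_apms_runs <- function(bait, control, method = c("max", "sum")) {
  method <- match.arg(method)
  stopifnot(identical(rownames(bait), rownames(control)))
  f <- if (method == "max") function(m) apply(m, 1, max) else rowSums
  data.frame(protein_id = rownames(bait),
             unique_peptides_bait = as.integer(f(bait)),
             unique_peptides_control = as.integer(f(control)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter bait-specific AP-MS interactors
#'
#' Retains proteins with at least `min_bait` unique peptides in the bait
#' purification and at most `max_control` in the control purification
#' (defaults: >= 2 and exactly 0, the bait-vs-GFP specificity rule).
#'
#' @param evidence data frame from [aggregate_apms_runs()] (or with the same
#'   columns).
#' @param min_bait minimum bait unique peptides (inclusive).
#' @param max_control maximum control unique peptides (inclusive).
#' @return character vector of retained protein ids.
#' @export
#' @examples
#' ev <- data.frame(protein_id = c("A", "B", "C"),
#'                  unique_peptides_bait = c(3, 2, 1),
#'                  unique_peptides_control = c(0, 1, 0))
#' filter_interactors(ev)  # "A"
filter_interactors <- function(evidence, min_bait = 2L, max_control = 0L) {
  stopifnot(all(c("protein_id", "unique_peptides_bait",
                  "unique_peptides_control") %in% names(evidence)),
            all(evidence$unique_peptides_bait >= 0),
            all(evidence$unique_peptides_control >= 0))
  keep <- evidence$unique_peptides_bait >= min_bait &
    evidence$unique_peptides_control <= max_control
  evidence$protein_id[keep]
}

#' Prioritize interactors by tumor upregulation
#'
#' Intersects an interactor set with the genes passing the expression filter
#' (`lfc >= lfc_min`, `fdr < fdr_max`, upregulated) and ranks the survivors
#' by descending fold change. Interactors without a DE record are excluded
#' with a warning.
#'
#' @param interactors character vector of protein ids.
#' @param de [differential_expression()] result.
#' @param mapping optional data frame (`protein_id`, `gene_id`); by default
#'   protein ids are used as gene ids.
#' @param lfc_min,fdr_max expression thresholds.
#' @return data frame (`protein_id`, `gene_id`, `lfc`, `fdr`), ranked by
#'   descending `lfc`.
#' @export
prioritize_interactors <- function(interactors, de, mapping = NULL,
                                   lfc_min = 1, fdr_max = 0.01) {
  if (length(interactors) == 0) {
    return(data.frame(protein_id = character(), gene_id = character(),
                      lfc = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(mapping)) {
    mapping <- data.frame(protein_id = interactors, gene_id = interactors,
                          stringsAsFactors = FALSE)
  }
  gm <- mapping$gene_id[match(interactors, mapping$protein_id)]
  missing_map <- is.na(gm)
  idx <- match(gm, de$gene_id)
  missing_de <- !missing_map & is.na(idx)
  if (any(missing_map | missing_de)) {
    warning(sum(missing_map | missing_de),
            " interactor(s) without a DE record were excluded")
  }
  ok <- !missing_map & !missing_de
  res <- data.frame(protein_id = interactors[ok],
                    gene_id = gm[ok],
                    lfc = de$lfc[idx[ok]],
                    fdr = de$fdr[idx[ok]],
                    stringsAsFactors = FALSE)
  res <- res[res$lfc >= lfc_min & res$fdr < fdr_max, , drop = FALSE]
  res <- res[order(-res$lfc), , drop = FALSE]
  rownames(res) <- NULL
  res
}
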