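#' Simulate a tumor/normal expression cohort with survival
#'
#' Log2-scale expression is Gaussian around gene-specific baselines; planted
#' tumor-upregulated genes are shifted by `planted_lfc` in tumor samples.
#' Overall-survival times for tumor samples are exponential, with the hazard
#' multiplied by `hazard_ratio` for tumors in the above-median expression
#' stratum of a designated prognostic gene, and administratively censored at
#' `censor_horizon`.
#'
#' @param config a [fixture_config()].
#' @param gene_ids genes to simulate.
#' @param tumor_up_gene_ids genes planted as tumor-upregulated; default: a
#'   random 30% of `gene_ids`.
#' @param prognostic_gene gene whose median split drives the survival hazard;
#'   default: the first tumor-up gene (or the first gene when none).
#' @return list with `expr` (genes x samples log2 matrix), `labels`
#'   (data frame `sample_id`, `group` tumor/normal), `survival` (data frame
#'   `sample_id`, `time`, `event`; tumor samples only),
#'   `tumor_up_gene_ids`, `prognostic_gene`.
#' @export
gen_cohort <- function(config, gene_ids,
                       tumor_up_gene_ids = NULL,
                       prognostic_gene = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$n_tumor < 2 || config$n_normal < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (length(gene_ids) < 1) stop("no genes supplied", call. = FALSE)

  with_seed(stage_seed(config$seed, "cohort"), {
    if (is.null(tumor_up_gene_ids)) {
      n_up <- max(1L, round(0.3 * length(gene_ids)))
      tumor_up_gene_ids <- sort(sample(gene_ids, n_up))
    }
    stopifnot(all(tumor_up_gene_ids %in% gene_ids))
    if (is.null(prognostic_gene)) {
      prognostic_gene <- if (length(tumor_up_gene_ids) > 0) tumor_up_gene_ids[1] else gene_ids[1]
    }
    stopifnot(prognostic_gene %in% gene_ids)

    n_t <- config$n_tumor; n_n <- config$n_normal
    samples <- c(sprintf("tumor_%03d", seq_len(n_t)),
                 sprintf("normal_%03d", seq_len(n_n)))
    group <- c(rep("tumor", n_t), rep("normal", n_n))

    g <- length(gene_ids)
    baseline <- rnorm(g, mean = 5, sd = 1.5)
    expr <- matrix(rnorm(g * (n_t + n_n), mean = baseline, sd = 1),
                   nrow = g, dimnames = list(gene_ids, samples))
    up <- gene_ids %in% tumor_up_gene_ids
    expr[up, group == "tumor"] <- expr[up, group == "tumor"] + config$planted_lfc

    pg <- expr[prognostic_gene, group == "tumor"]
    high <- pg >= median(pg)
    hz <- config$baseline_hazard * ifelse(high, config$hazard_ratio, 1)
    raw <- rexp(n_t, rate = hz)
    time <- pmin(raw, config$censor_horizon)
    event <- as.integer(raw < config$censor_horizon)
    survival <- data.frame(sample_id = samples[group == "tumor"],
                           time = time, event = event,
                           stringsAsFactors = FALSE)

    list(expr = expr,
         labels = data.frame(sample_id = samples, group = group,
                             stringsAsFactors = FALSE),
         survival = survival,
         tumor_up_gene_ids = tumor_up_gene_ids,
         prognostic_gene = prognostic_gene)
  })
}
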