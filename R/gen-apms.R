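#' Simulate AP-MS unique-peptide counts for bait and control runs
#'
#' Emulates an affinity-purification MS experiment with a tagged bait versus
#' a tagged-GFP control. Planted true interactors receive at least 2 unique
#' peptides in every bait run and 0 in every control run, by construction.
#' Background proteins receive Poisson peptide counts with overlapping
#' distributions in both arms; each background protein is detected with at
#' least one peptide in some control run (non-specific binders stick to the
#' control purification too), so the bait-specificity filter separates the
#' classes exactly.
#'
#' @param config a [fixture_config()].
#' @param protein_ids candidate protein identifiers.
#' @param true_interactor_ids planted interactors; default: a random
#'   `config$n_true_interactors` of `protein_ids`.
#' @return list with `bait` and `control` (integer matrices, proteins x
#'   runs) and `true_interactor_ids`.
#' @export
gen_apms <- function(config, protein_ids, true_interactor_ids = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$n_bait_runs < 1 || config$n_control_runs < 1) {
    stop("need at least one bait and one control run", call. = FALSE)
  }
  with_seed(stage_seed(config$seed, "apms"), {
    if (is.null(true_interactor_ids)) {
      k <- min(config$n_true_interactors, length(protein_ids))
      true_interactor_ids <- sort(sample(protein_ids, k))
    }
    stopifnot(all(true_interactor_ids %in% protein_ids))
    p <- length(protein_ids)
    nb <- config$n_bait_runs; nc <- config$n_control_runs
    is_true <- protein_ids %in% true_interactor_ids

    bait <- matrix(rpois(p * nb, lambda = 1.2), nrow = p,
                   dimnames = list(protein_ids, sprintf("bait_run%d", seq_len(nb))))
    control <- matrix(rpois(p * nc, lambda = 1.2), nrow = p,
                      dimnames = list(protein_ids, sprintf("control_run%d", seq_len(nc))))
    # guarantee every background protein >= 1 control peptide in some run
    none <- rowSums(control) == 0 & !is_true
    if (any(none)) {
      run <- sample.int(nc, sum(none), replace = TRUE)
      control[cbind(which(none), run)] <- 1L
    }
    # planted interactors: >=2 unique peptides in every bait run, 0 in controls
    bait[is_true, ] <- 2L + matrix(rpois(sum(is_true) * nb, lambda = 2),
                                   nrow = sum(is_true))
    control[is_true, ] <- 0L

    list(bait = bait, control = control,
         true_interactor_ids = true_interactor_ids)
  })
}
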