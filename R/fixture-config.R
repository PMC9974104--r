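#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic multi-omics study: transcriptome
#' layout, ribosome-profiling signal, pooled CRISPR screen, tumor/normal
#' expression cohort with survival, AP-MS runs, and the regulatory (ChIP
#' peak + dependency score) layer. Identical configuration and seed always
#' reproduce byte-identical fixtures.
#'
#' Defaults mirror the study design the pipeline emulates: a pooled screen
#' library with 636 positive- and 1,064 negative-control sgRNAs, three
#' ribo-seq replicates, ~500x screen coverage with 3-fold depletion of
#' essential-ORF guides, and a tumor/normal cohort with a 2 log2-unit planted
#' up-shift for tumor-upregulated lncRNA genes.
#'
#' @param seed integer master seed; all fixture randomness derives from it.
#' @param n_lnc_transcripts,n_coding_transcripts number of lncRNA and
#'   protein-coding transcripts on the synthetic chromosome.
#' @param planted_orf_fraction fraction of lncRNAs carrying a planted
#'   translated ORF.
#' @param periodicity probability mass moved onto frame 0 beyond the uniform
#'   1/3 for P-sites on planted ORFs (0 = frame-uniform, 1 = perfectly
#'   periodic).
#' @param rpf_depth mean number of P-sites per planted ORF per replicate.
#' @param n_rpf_replicates ribo-seq replicates.
#' @param background_depth mean P-sites on a non-planted lncRNA (frame-uniform
#'   background).
#' @param sgrnas_per_orf targeting guides per screened ORF.
#' @param n_targeting_sgrnas optional total targeting-guide count; when given,
#'   guides are spread round-robin over ORFs so the total matches exactly
#'   (some ORFs get one more guide than others).
#' @param n_neg_controls,n_pos_controls control guide counts.
#' @param essential_fraction fraction of screened ORFs planted as fitness
#'   dependencies.
#' @param depletion_fold factor (>= 1) by which day-21 abundance of
#'   essential-ORF and positive-control guides is reduced.
#' @param screen_depth mean day-0 count per guide.
#' @param nb_size negative-binomial size (dispersion) for counts; smaller is
#'   more overdispersed.
#' @param n_screen_replicates replicates per screen timepoint.
#' @param n_tumor,n_normal cohort group sizes.
#' @param planted_lfc log2 shift of planted tumor-up genes in tumors.
#' @param hazard_ratio hazard multiplier for tumors in the above-median
#'   expression stratum of the prognostic gene.
#' @param baseline_hazard exponential event hazard per month for the
#'   low-expression stratum.
#' @param censor_horizon administrative censoring time (months).
#' @param n_bait_runs,n_control_runs AP-MS run counts.
#' @param n_background_proteins AP-MS background proteins detected in both
#'   arms.
#' @param n_true_interactors planted bait-specific interactors.
#' @param co_bound_fraction fraction of candidate protein-coding genes planted
#'   as co-bound regulatory targets.
#' @param peak_width width (bp) of generated ChIP peaks.
#'
#' @return an object of class `fixture_config` (a validated list).
#' @export
#' @examples
#' cfg <- fixture_config(seed = 1, n_lnc_transcripts = 10)
#' cfg$periodicity
fixture_config <- function(seed,
                           n_lnc_transcripts = 80L,
                           n_coding_transcripts = 20L,
                           planted_orf_fraction = 0.5,
                           periodicity = 0.8,
                           rpf_depth = 80,
                           n_rpf_replicates = 3L,
                           background_depth = 15,
                           sgrnas_per_orf = 5L,
                           n_targeting_sgrnas = NULL,
                           n_neg_controls = 1064L,
                           n_pos_controls = 636L,
                           essential_fraction = 0.1,
                           depletion_fold = 3,
                           screen_depth = 500,
                           nb_size = 30,
                           n_screen_replicates = 2L,
                           n_tumor = 50L,
                           n_normal = 50L,
                           planted_lfc = 2,
                           hazard_ratio = 2,
                           baseline_hazard = 0.02,
                           censor_horizon = 120,
                           n_bait_runs = 2L,
                           n_control_runs = 2L,
                           n_background_proteins = 40L,
                           n_true_interactors = 8L,
                           co_bound_fraction = 0.3,
                           peak_width = 400L) {
  assert_count(seed, "seed")
  assert_count(n_lnc_transcripts, "n_lnc_transcripts")
  assert_count(n_coding_transcripts, "n_coding_transcripts")
  if (n_lnc_transcripts + n_coding_transcripts < 1) {
    stop("at least one transcript must be requested", call. = FALSE)
  }
  assert_fraction(planted_orf_fraction, "planted_orf_fraction")
  assert_fraction(periodicity, "periodicity")
  assert_fraction(essential_fraction, "essential_fraction")
  assert_fraction(co_bound_fraction, "co_bound_fraction")
  if (depletion_fold < 1) stop("`depletion_fold` must be >= 1", call. = FALSE)
  assert_count(sgrnas_per_orf, "sgrnas_per_orf", min = 1L)
  assert_count(n_neg_controls, "n_neg_controls")
  assert_count(n_pos_controls, "n_pos_controls")
  assert_count(n_rpf_replicates, "n_rpf_replicates", min = 1L)
  assert_count(n_screen_replicates, "n_screen_replicates", min = 1L)
  if (rpf_depth < 0) stop("`rpf_depth` must be >= 0", call. = FALSE)
  if (!is.null(n_targeting_sgrnas)) assert_count(n_targeting_sgrnas, "n_targeting_sgrnas", min = 1L)

  cfg <- list(
    seed = as.integer(seed),
    n_lnc_transcripts = as.integer(n_lnc_transcripts),
    n_coding_transcripts = as.integer(n_coding_transcripts),
    planted_orf_fraction = planted_orf_fraction,
    periodicity = periodicity,
    rpf_depth = rpf_depth,
    n_rpf_replicates = as.integer(n_rpf_replicates),
    background_depth = background_depth,
    sgrnas_per_orf = as.integer(sgrnas_per_orf),
    n_targeting_sgrnas = if (is.null(n_targeting_sgrnas)) NULL else as.integer(n_targeting_sgrnas),
    n_neg_controls = as.integer(n_neg_controls),
    n_pos_controls = as.integer(n_pos_controls),
    essential_fraction = essential_fraction,
    depletion_fold = depletion_fold,
    screen_depth = screen_depth,
    nb_size = nb_size,
    n_screen_replicates = as.integer(n_screen_replicates),
    n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal),
    planted_lfc = planted_lfc,
    hazard_ratio = hazard_ratio,
    baseline_hazard = baseline_hazard,
    censor_horizon = censor_horizon,
    n_bait_runs = as.integer(n_bait_runs),
    n_control_runs = as.integer(n_control_runs),
    n_background_proteins = as.integer(n_background_proteins),
    n_true_interactors = as.integer(n_true_interactors),
    co_bound_fraction = co_bound_fraction,
    peak_width = as.integer(peak_width)
  )
  class(cfg) <- "fixture_config"
  cfg
}

#' @export
print.fixture_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  transcripts: ", x$n_lnc_transcripts, " lncRNA / ",
      x$n_coding_transcripts, " coding; planted ORF fraction ",
      x$planted_orf_fraction, "\n", sep = "")
  cat("  ribo-seq: periodicity ", x$periodicity, ", depth ", x$rpf_depth,
      ", ", x$n_rpf_replicates, " replicates\n", sep = "")
  cat("  screen: ", x$sgrnas_per_orf, " guides/ORF, +", x$n_pos_controls,
      "/-", x$n_neg_controls, " controls, depletion fold ", x$depletion_fold,
      "\n", sep = "")
  cat("  cohort: ", x$n_tumor, " tumor / ", x$n_normal,
      " normal, planted lfc ", x$planted_lfc, ", HR ", x$hazard_ratio,
      "\n", sep = "")
  invisible(x)
}
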