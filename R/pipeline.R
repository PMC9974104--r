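# End-to-end orchestration: ribo-seq -> screen -> expression/survival ->
# AP-MS -> regulatory triage, with materialized intermediates and a run
# report recording counts and assumptions.

#' Pipeline thresholds (defaults are the published analysis values)
#'
#' @param screen_lfc_threshold,screen_p_threshold,screen_min_sgrnas screen
#'   hit rule: guide `lfc <= -log2(1.5)`, empirical `p < 0.05`, at least 2
#'   depleted guides.
#' @param lnc_up_lfc,lnc_up_fdr tumor-vs-normal upregulation filter
#'   (`lfc >= log2(1.2)`, `FDR < 0.01`).
#' @param kd_de_lfc,kd_de_fdr knockout/knockdown DE thresholds
#'   (`|lfc| >= log2(1.5)`, `FDR < 0.05`).
#' @param apms_lfc,apms_fdr AP-MS candidate expression filter
#'   (`lfc >= 1`, `FDR < 0.01`).
#' @param window_upstream,window_downstream TSS window (-30 kb/+10 kb).
#' @param effect_threshold dependency score bound (< -0.2).
#' @param min_psites,alpha,psite_offset,min_aa,identity_threshold ribo-seq
#'   calling parameters.
#' @return a named list of class `cryptorf_thresholds`.
#' @export
cryptorf_thresholds <- function(screen_lfc_threshold = -log2(1.5),
                                screen_p_threshold = 0.05,
                                screen_min_sgrnas = 2L,
                                lnc_up_lfc = log2(1.2),
                                lnc_up_fdr = 0.01,
                                kd_de_lfc = log2(1.5),
                                kd_de_fdr = 0.05,
                                apms_lfc = 1,
                                apms_fdr = 0.01,
                                window_upstream = 30000L,
                                window_downstream = 10000L,
                                effect_threshold = -0.2,
                                min_psites = 10L,
                                alpha = 0.05,
                                psite_offset = 12L,
                                min_aa = 10L,
                                identity_threshold = 0.9) {
  if (screen_lfc_threshold > 0) {
    stop("`screen_lfc_threshold` must be <= 0 (depletion)", call. = FALSE)
  }
  if (effect_threshold > 0) {
    stop("`effect_threshold` must be <= 0 (dependency)", call. = FALSE)
  }
  structure(list(
    screen_lfc_threshold = screen_lfc_threshold,
    screen_p_threshold = screen_p_threshold,
    screen_min_sgrnas = as.integer(screen_min_sgrnas),
    lnc_up_lfc = lnc_up_lfc, lnc_up_fdr = lnc_up_fdr,
    kd_de_lfc = kd_de_lfc, kd_de_fdr = kd_de_fdr,
    apms_lfc = apms_lfc, apms_fdr = apms_fdr,
    window_upstream = as.integer(window_upstream),
    window_downstream = as.integer(window_downstream),
    effect_threshold = effect_threshold,
    min_psites = as.integer(min_psites), alpha = alpha,
    psite_offset = as.integer(psite_offset),
    min_aa = as.integer(min_aa),
    identity_threshold = identity_threshold
  ), class = "cryptorf_thresholds")
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage on a synthetic fixture: ribo-seq QC and translated
#' ORF calling with de-duplication; screen normalization, per-guide
#' statistics, hit calling and positive-control QC; tumor-vs-normal DE with
#' upregulated-gene selection and the survival log-rank association; AP-MS
#' interactor filtering and expression prioritization; and the regulatory
#' common-peak / TSS-window / dependency triage. Intermediates are written
#' as TSV/JSON when `output_dir` is given.
#'
#' @param fixture a [simulate_study()] result, or a [fixture_config()]
#'   (then the fixture is generated first).
#' @param thresholds a [cryptorf_thresholds()] list.
#' @param output_dir optional directory for materialized stage outputs.
#' @return object of class `cryptorf_run`; see Details. The `report`
#'   component records per-stage record counts, the assumption flags, and
#'   the seed.
#' @export
run_cryptorf <- function(fixture, thresholds = cryptorf_thresholds(),
                         output_dir = NULL) {
  if (inherits(fixture, "fixture_config")) fixture <- simulate_study(fixture)
  stopifnot(inherits(fixture, "study_fixture"),
            inherits(thresholds, "cryptorf_thresholds"))
  th <- thresholds
  tr <- fixture$transcriptome

  # --- stage 1: ribo-seq ---------------------------------------------------
  qc <- qc_metrics(fixture$rpf$psites, tr$cds,
                   read_lengths = fixture$rpf$read_lengths)
  lnc_seqs <- tr$sequences[tr$transcripts$transcript_id[tr$transcripts$type == "lncRNA"]]
  candidates <- enumerate_atg_orfs_set(lnc_seqs, min_aa = th$min_aa)
  orf_calls <- call_translated_orfs(fixture$rpf$psites, candidates,
                                    min_psites = th$min_psites,
                                    alpha = th$alpha)
  translated <- deduplicate_orfs(orf_calls[orf_calls$called, , drop = FALSE],
                                 identity_threshold = th$identity_threshold)

  # --- stage 2: CRISPR screen ---------------------------------------------
  nc <- normalize_counts(fixture$screen$counts, fixture$screen$library)
  stats <- sgrna_stats(nc$norm, fixture$screen$library)
  hits <- call_hits(stats, fixture$screen$library,
                    lfc_threshold = th$screen_lfc_threshold,
                    p_threshold = th$screen_p_threshold,
                    min_sgrnas = th$screen_min_sgrnas)
  pc_qc <- positive_control_qc(stats)
  hit_orfs <- hits$orf_id[hits$is_hit]
  # restrict to ORFs with translation support from stage 1
  hit_orfs_translated <- intersect(hit_orfs, translated$orf_id)

  # --- stage 3: expression and survival ------------------------------------
  de <- differential_expression(fixture$cohort$expr,
                                fixture$cohort$labels$group)
  tumor_up_sel <- select_genes(de, th$lnc_up_lfc, th$lnc_up_fdr, "up")
  tx2gene <- setNames(tr$transcripts$gene_id, tr$transcripts$transcript_id)
  orf2gene <- function(orf_ids) {
    unname(tx2gene[sub(":.*$", "", orf_ids)])
  }
  candidate_orfs <- hit_orfs_translated[
    orf2gene(hit_orfs_translated) %in% tumor_up_sel]
  surv <- fixture$cohort$survival
  prog_expr <- fixture$cohort$expr[fixture$cohort$prognostic_gene,
                                   surv$sample_id]
  survival_assoc <- logrank_by_expression(surv$time, surv$event, prog_expr)

  # --- stage 4: interactome -------------------------------------------------
  evidence <- aggregate_apms_runs(fixture$apms$bait, fixture$apms$control)
  interactors <- filter_interactors(evidence)
  prioritized <- prioritize_interactors(interactors, de,
                                        lfc_min = th$apms_lfc,
                                        fdr_max = th$apms_fdr)

  # --- stage 5: regulatory triage ------------------------------------------
  common <- intersect_peak_sets(list(fixture$regulatory$peaks_a,
                                     fixture$regulatory$peaks_b))
  pcg_models <- tr$gene_models[
    tr$gene_models$gene_id %in%
      tr$transcripts$gene_id[tr$transcripts$type == "coding"], ]
  assignment <- assign_peaks_to_genes(common, pcg_models,
                                      upstream = th$window_upstream,
                                      downstream = th$window_downstream)
  triage <- triage_targets(
    co_up_genes = fixture$co_up_gene_ids,
    tumor_up_genes = tumor_up_sel,
    common_peak_assignment = assignment,
    gene_effects = fixture$regulatory$gene_effects,
    effect_threshold = th$effect_threshold,
    candidates = pcg_models$gene_id
  )

  report <- list(
    seed = fixture$config$seed,
    assumptions = c(
      "sgRNA p-values: empirical one-sided tail vs negative-control lfc, add-one corrected",
      "DE test: Wilcoxon rank-sum, two-sided; BH FDR across all genes",
      "AP-MS peptide aggregation across runs: maximum",
      "survival dichotomization: median split of prognostic-gene expression",
      "TSS windows: transcription-direction-relative (-30 kb/+10 kb)"
    ),
    counts = list(
      n_lnc_transcripts = sum(tr$transcripts$type == "lncRNA"),
      n_orf_candidates = nrow(candidates),
      n_orfs_tested = sum(orf_calls$tested),
      n_orfs_called = sum(orf_calls$called),
      n_translated_dedup = nrow(translated),
      n_sgrnas = nrow(fixture$screen$library),
      n_orf_hits = length(hit_orfs),
      n_hits_translated = length(hit_orfs_translated),
      n_tumor_up_selected = length(tumor_up_sel),
      n_candidate_orfs = length(candidate_orfs),
      n_interactors = length(interactors),
      n_prioritized_interactors = nrow(prioritized),
      n_common_peaks = nrow(common),
      n_triage_candidates = nrow(triage$trail),
      n_final_targets = length(triage$final_targets)
    )
  )

  run <- structure(list(
    fixture = fixture, thresholds = th, qc = qc,
    orf_calls = orf_calls, translated = translated,
    screen_stats = stats, hits = hits, positive_control_qc = pc_qc,
    candidate_orfs = candidate_orfs,
    de = de, tumor_up_genes = tumor_up_sel, survival = survival_assoc,
    interactors = interactors, prioritized_interactors = prioritized,
    common_peaks = common, assignment = assignment, triage = triage,
    final_targets = triage$final_targets, report = report
  ), class = "cryptorf_run")

  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

#' @export
print.cryptorf_run <- function(x, ...) {
  cn <- x$report$counts
  cat("cryptorf pipeline run (seed ", x$report$seed, ")\n", sep = "")
  cat("  ORF candidates ", cn$n_orf_candidates, " -> called ",
      cn$n_orfs_called, " -> de-duplicated ", cn$n_translated_dedup, "\n", sep = "")
  cat("  screen hits ", cn$n_orf_hits, " -> translated hits ",
      cn$n_hits_translated, " -> tumor-up candidate ORFs ",
      cn$n_candidate_orfs, "\n", sep = "")
  cat("  interactors ", cn$n_interactors, " -> prioritized ",
      cn$n_prioritized_interactors, "\n", sep = "")
  cat("  triage candidates ", cn$n_triage_candidates, " -> final targets ",
      cn$n_final_targets, ": ", paste(x$final_targets, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Materialize pipeline outputs
#'
#' Writes every stage product under `dir`: TSVs for tabular results, BED for
#' common peaks, JSON for the QC, survival, and run report.
#'
#' @param run a [run_cryptorf()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  js <- function(x, name) {
    jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  tsv(run$orf_calls, "orf_calls.tsv")
  tsv(run$translated, "translated_orfs.tsv")
  tsv(run$screen_stats, "sgrna_stats.tsv")
  tsv(run$hits, "orf_hits.tsv")
  tsv(run$de, "differential_expression.tsv")
  tsv(run$prioritized_interactors, "prioritized_interactors.tsv")
  tsv(run$assignment, "common_peak_assignment.tsv")
  tsv(run$triage$trail, "triage_trail.tsv")
  write_bed(run$common_peaks, file.path(dir, "common_peaks.bed"))
  js(list(frame_fractions = run$qc$frame_fractions_global,
          replicate_r = run$qc$replicate_r), "riboseq_qc.json")
  js(run$survival, "survival_logrank.json")
  js(list(final_targets = run$final_targets), "final_targets.json")
  js(run$report, "run_report.json")
  invisible(dir)
}

#' Relative expression by the 2^-ddCT method
#'
#' `ddCT = (CT_target,treated - CT_ref,treated) -
#'         (CT_target,control - CT_ref,control)`; the fold change is
#' `2^-ddCT`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   threshold-cycle values.
#' @return fold change(s).
#' @export
#' @examples
#' ddct_fold_change(24, 20, 25, 20)  # 2
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Xenograft tumor volume
#'
#' `volume = L * W^2 / 2`, in the cube of the input unit, with `L` the
#' longest and `W` the perpendicular diameter.
#'
#' @param L longest diameter.
#' @param W perpendicular diameter.
#' @return volume(s).
#' @export
#' @examples
#' tumor_volume(10, 5)  # 125
tumor_volume <- function(L, W) {
  if (any(L < 0) || any(W < 0)) stop("diameters must be non-negative", call. = FALSE)
  if (any(W > L)) warning("W > L: check diameter order")
  L * W^2 / 2
}
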