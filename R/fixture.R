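#' Simulate a complete synthetic study with coherent planted ground truth
#'
#' Runs every generator and wires their planted effects together so the full
#' pipeline is exercised end to end: planted translated ORFs on lncRNAs feed
#' the screen; essential-ORF host genes are planted tumor-upregulated in the
#' cohort; a designated prognostic lncRNA gene drives survival; AP-MS
#' proteins map to the coding genes; and protein-coding driver genes are
#' planted to pass all four triage conditions (co-upregulated by both
#' factors, tumor-upregulated, common binding site in the TSS window,
#' dependency in both cell lines) while every decoy is constructed to fail
#' exactly one of them.
#'
#' @param config a [fixture_config()].
#' @return an object of class `study_fixture`: a list with components
#'   `config`, `transcriptome`, `rpf`, `screen`, `cohort`, `apms`,
#'   `regulatory`, `co_up_gene_ids`, and `ground_truth` (a list of
#'   `translated_orf_ids`, `essential_orf_ids`, `tumor_up_gene_ids`,
#'   `true_interactor_ids`, `co_bound_target_ids`).
#' @export
#' @examples
#' fx <- simulate_study(fixture_config(seed = 1, n_lnc_transcripts = 12,
#'                                     n_coding_transcripts = 8))
#' fx$ground_truth$co_bound_target_ids
simulate_study <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  tr <- gen_transcriptome(config)
  rpf <- gen_rpf(config, tr)

  screen <- gen_screen(config, tr$orfs$orf_id)

  tx2gene <- setNames(tr$transcripts$gene_id, tr$transcripts$transcript_id)
  lnc_genes <- tr$transcripts$gene_id[tr$transcripts$type == "lncRNA"]
  pcg_genes <- tr$transcripts$gene_id[tr$transcripts$type == "coding"]

  ess_hosts <- sort(unique(unname(
    tx2gene[tr$orfs$transcript_id[tr$orfs$orf_id %in% screen$essential_orf_ids]]
  )))

  plan <- with_seed(stage_seed(config$seed, "pipeline"), {
    n_pcg <- length(pcg_genes)
    n_drv <- max(1L, round(config$co_bound_fraction * n_pcg))
    drivers <- sort(sample(pcg_genes, min(n_drv, n_pcg)))
    rest <- setdiff(pcg_genes, drivers)
    # each decoy fails exactly one triage condition
    fail <- c("peak", "tumor_up", "effect", "co_up")[(seq_along(rest) - 1L) %% 4L + 1L]
    peak_alt <- c("single_factor", "outside_window", "none")

    roles <- rbind(
      data.frame(gene_id = drivers, peak_mode = "in_window", effect_pass = TRUE,
                 stringsAsFactors = FALSE),
      if (length(rest) > 0) data.frame(
        gene_id = rest,
        peak_mode = ifelse(fail == "peak",
                           peak_alt[(seq_along(rest) - 1L) %% 3L + 1L],
                           "in_window"),
        effect_pass = fail != "effect",
        stringsAsFactors = FALSE)
    )
    co_up <- sort(c(drivers, rest[fail != "co_up"]))
    tumor_up_pcg <- sort(c(drivers, rest[fail != "tumor_up"]))

    extra_lnc <- setdiff(lnc_genes, ess_hosts)
    n_extra <- round(0.2 * length(extra_lnc))
    tumor_up_lnc <- sort(c(ess_hosts,
                           if (n_extra > 0) sample(extra_lnc, n_extra)))
    true_int <- sort(sample(pcg_genes, min(config$n_true_interactors, n_pcg)))
    list(drivers = drivers, roles = roles, co_up = co_up,
         tumor_up = c(tumor_up_lnc, tumor_up_pcg), true_int = true_int)
  })

  prognostic <- if (length(ess_hosts) > 0) ess_hosts[1] else plan$tumor_up[1]
  cohort <- gen_cohort(config, c(lnc_genes, pcg_genes),
                       tumor_up_gene_ids = plan$tumor_up,
                       prognostic_gene = prognostic)
  apms <- gen_apms(config, pcg_genes, true_interactor_ids = plan$true_int)
  regulatory <- gen_regulatory(config, tr$gene_models,
                               candidate_gene_ids = pcg_genes,
                               roles = plan$roles)

  structure(list(
    config = config,
    transcriptome = tr,
    rpf = rpf,
    screen = screen,
    cohort = cohort,
    apms = apms,
    regulatory = regulatory,
    co_up_gene_ids = plan$co_up,
    ground_truth = list(
      translated_orf_ids = sort(tr$orfs$orf_id),
      essential_orf_ids = screen$essential_orf_ids,
      tumor_up_gene_ids = sort(plan$tumor_up),
      true_interactor_ids = apms$true_interactor_ids,
      co_bound_target_ids = plan$drivers
    )
  ), class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  gt <- x$ground_truth
  cat("Synthetic study fixture (seed ", x$config$seed, ")\n", sep = "")
  cat("  planted: ", length(gt$translated_orf_ids), " translated ORFs, ",
      length(gt$essential_orf_ids), " essential ORFs, ",
      length(gt$tumor_up_gene_ids), " tumor-up genes, ",
      length(gt$true_interactor_ids), " interactors, ",
      length(gt$co_bound_target_ids), " driver genes\n", sep = "")
  invisible(x)
}
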