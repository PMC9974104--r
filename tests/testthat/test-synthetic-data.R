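# The generators: seed determinism, planted structure, and the statistical
# properties the downstream stages rely on.

test_that("generators are pure functions of (config, seed)", {
  cfg <- fixture_config(seed = 3, n_lnc_transcripts = 10, n_coding_transcripts = 5)
  t1 <- gen_transcriptome(cfg)
  t2 <- gen_transcriptome(cfg)
  expect_identical(t1, t2)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_transcriptome_fasta(t1, f1); write_transcriptome_fasta(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_identical(gen_rpf(cfg, t1), gen_rpf(cfg, t1))
  expect_identical(gen_screen(cfg, t1$orfs$orf_id),
                   gen_screen(cfg, t1$orfs$orf_id))
  expect_identical(gen_cohort(cfg, t1$transcripts$gene_id),
                   gen_cohort(cfg, t1$transcripts$gene_id))
  expect_identical(gen_apms(cfg, t1$transcripts$gene_id),
                   gen_apms(cfg, t1$transcripts$gene_id))

  r1 <- gen_regulatory(cfg, t1$gene_models)
  r2 <- gen_regulatory(cfg, t1$gene_models)
  expect_identical(r1, r2)
  b1 <- tempfile(fileext = ".bed"); b2 <- tempfile(fileext = ".bed")
  write_bed(r1$peaks_a, b1); write_bed(r2$peaks_a, b2)
  expect_identical(readBin(b1, "raw", file.size(b1)),
                   readBin(b2, "raw", file.size(b2)))
})

test_that("planted ORFs are well-formed ATG...stop frames at recorded positions", {
  cfg <- fixture_config(seed = 11, n_lnc_transcripts = 25,
                        n_coding_transcripts = 0, planted_orf_fraction = 1)
  tr <- gen_transcriptome(cfg)
  expect_equal(nrow(tr$orfs), 25)
  for (i in seq_len(nrow(tr$orfs))) {
    s <- tr$sequences[[tr$orfs$transcript_id[i]]]
    a <- tr$orfs$start[i]; b <- tr$orfs$end[i]
    expect_equal((b - a) %% 3, 0)
    expect_equal(substring(s, a + 1, a + 3), "ATG")
    expect_true(substring(s, b - 2, b) %in% c("TAA", "TAG", "TGA"))
    # translated length is span/3 - 1 (stop excluded)
    aa <- length(Biostrings::translate(Biostrings::DNAString(
      substring(s, a + 1, b - 3))))
    expect_equal(aa, (b - a) / 3 - 1)
  }
})

test_that("zero transcripts is a configuration error", {
  expect_error(fixture_config(seed = 1, n_lnc_transcripts = 0,
                              n_coding_transcripts = 0),
               "at least one transcript")
  expect_error(fixture_config(seed = 1, depletion_fold = 0.5),
               "depletion_fold")
})

test_that("P-site frame distribution follows the periodicity parameter", {
  base <- list(seed = 5, n_coding_transcripts = 0, planted_orf_fraction = 1,
               rpf_depth = 60, n_rpf_replicates = 1)
  frame0_frac <- function(periodicity, n_lnc) {
    cfg <- do.call(fixture_config, c(base, list(periodicity = periodicity,
                                                n_lnc_transcripts = n_lnc)))
    tr <- gen_transcriptome(cfg)
    ps <- gen_rpf(cfg, tr)$psites
    m <- match(ps$transcript_id, tr$orfs$transcript_id)
    inorf <- ps$position >= tr$orfs$start[m] & ps$position < tr$orfs$end[m]
    fr <- (ps$position[inorf] - tr$orfs$start[m][inorf]) %% 3
    c(sum(ps$count[inorf][fr == 0]), sum(ps$count[inorf]))
  }
  # periodicity 1: every planted-ORF P-site in frame 0
  x <- frame0_frac(1, 20)
  expect_equal(x[1], x[2])
  # periodicity 0: frame-0 share ~ 1/3, within 3 binomial s.e. (n >= 10,000)
  x <- frame0_frac(0, 200)
  expect_gt(x[2], 10000)
  se <- sqrt((1 / 3) * (2 / 3) / x[2])
  expect_lt(abs(x[1] / x[2] - 1 / 3), 3 * se)
})

test_that("screen library mirrors the published class composition exactly", {
  cfg <- fixture_config(seed = 2, n_targeting_sgrnas = 3913,
                        n_pos_controls = 636, n_neg_controls = 1064)
  orfs <- sprintf("ORF%03d", 1:758)
  sc <- gen_screen(cfg, orfs)
  expect_equal(unname(table(sc$library$class)[c("targeting", "positive_control",
                                                "negative_control")]),
               c(3913, 636, 1064), ignore_attr = TRUE)
  # referential integrity: every targeting guide points at a screened ORF
  tg <- sc$library$target_orf_id[sc$library$class == "targeting"]
  expect_true(all(tg %in% orfs))
  expect_true(all(is.na(sc$library$target_orf_id[sc$library$class != "targeting"])))
})

test_that("without depletion, essential and negative guides are indistinguishable", {
  cfg <- fixture_config(seed = 9, depletion_fold = 1, n_neg_controls = 500,
                        essential_fraction = 0.5, sgrnas_per_orf = 5)
  sc <- gen_screen(cfg, sprintf("ORF%03d", 1:100))
  nc <- normalize_counts(sc$counts, sc$library)
  st <- sgrna_stats(nc$norm, sc$library)
  ess <- st$lfc[!is.na(st$target_orf_id) &
                  st$target_orf_id %in% sc$essential_orf_ids]
  neg <- st$lfc[st$class == "negative_control"]
  expect_gt(wilcox.test(ess, neg)$p.value, 0.01)
})

test_that("cohort: null lfc centers at zero and group-size contract holds", {
  cfg <- fixture_config(seed = 13, planted_lfc = 0, n_tumor = 40, n_normal = 40)
  genes <- sprintf("G%03d", 1:60)
  ch <- gen_cohort(cfg, genes)
  expect_identical(ch, gen_cohort(cfg, genes))  # incl. the survival table
  grp <- ch$labels$group
  lfc <- rowMeans(ch$expr[ch$tumor_up_gene_ids, grp == "tumor", drop = FALSE]) -
    rowMeans(ch$expr[ch$tumor_up_gene_ids, grp == "normal", drop = FALSE])
  se <- 1 * sqrt(1 / 40 + 1 / 40) / sqrt(length(lfc))
  expect_lt(abs(mean(lfc)), 3 * se)
  expect_error(gen_cohort(fixture_config(seed = 1, n_tumor = 1), genes),
               "at least 2")
})

test_that("AP-MS construction separates true interactors from background", {
  cfg <- fixture_config(seed = 21, n_true_interactors = 6)
  prot <- sprintf("P%02d", 1:40)
  ap <- gen_apms(cfg, prot)
  is_true <- prot %in% ap$true_interactor_ids
  expect_true(all(apply(ap$bait[is_true, , drop = FALSE], 1, min) >= 2))
  expect_true(all(ap$control[is_true, ] == 0))
  # background proteins always show up in the control purification
  expect_true(all(rowSums(ap$control[!is_true, , drop = FALSE]) >= 1))
  expect_identical(ap, gen_apms(cfg, prot))
})

test_that("regulatory fixture plants co-binding inside windows and decoys outside", {
  cfg <- fixture_config(seed = 17, n_lnc_transcripts = 2,
                        n_coding_transcripts = 20)
  tr <- gen_transcriptome(cfg)
  reg <- gen_regulatory(cfg, tr$gene_models,
                        candidate_gene_ids = tr$gene_models$gene_id[-(1:2)])
  common <- intersect_peak_sets(list(reg$peaks_a, reg$peaks_b))
  asg <- assign_peaks_to_genes(common, tr$gene_models)
  # every co-bound target has a common interval inside its window
  expect_true(all(reg$co_bound_target_ids %in% asg$gene_id))
  # single-factor decoys never appear in the common-set assignment
  single <- reg$roles$gene_id[reg$roles$peak_mode == "single_factor"]
  expect_length(intersect(single, asg$gene_id), 0)
  # outside-window decoys have common peaks, but not within any window
  outside <- reg$roles$gene_id[reg$roles$peak_mode == "outside_window"]
  expect_length(intersect(outside, asg$gene_id), 0)
})
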