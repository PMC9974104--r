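# Peak categorization, coordinate intersection, strand-aware window
# assignment (each against positional brute force), and the triage rule.

toy_models <- function() {
  # one + strand gene [10000, 30000) with an intron [11000, 19000)
  data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
             start = 10000L, end = 30000L, tss = 10000L, tts = 29999L,
             stringsAsFactors = FALSE)
}

toy_exons <- function() {
  data.frame(gene_id = "G1", start = c(10000L, 19000L),
             end = c(11000L, 30000L))
}

test_that("peak categories follow the midpoint precedence rules", {
  gm <- toy_models(); ex <- toy_exons()
  peak <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  # midpoint 5,000 nt beyond the TTS, outside all bodies -> distal intergenic
  expect_equal(annotate_peak_category(peak(34899, 35099), gm, ex), "distal_intergenic")
  # midpoint inside the intron
  expect_equal(annotate_peak_category(peak(14900, 15100), gm, ex), "intronic")
  # midpoint 2,999 nt upstream of the TSS -> promoter (<= 3 kb inclusive)
  expect_equal(annotate_peak_category(peak(6901, 7101), gm, ex), "promoter")
  # midpoint 3,001 nt upstream -> not promoter
  expect_equal(annotate_peak_category(peak(6899, 7099), gm, ex), "distal_intergenic")
  # unknown chromosome -> unplaced, with a warning
  expect_warning(
    cat1 <- annotate_peak_category(data.frame(chrom = "chrZ", start = 1,
                                              end = 100), gm, ex),
    "absent")
  expect_equal(cat1, "unplaced")
})

test_that("every fixture peak receives exactly one category", {
  cfg <- fixture_config(seed = 6, n_lnc_transcripts = 5, n_coding_transcripts = 10)
  tr <- gen_transcriptome(cfg)
  reg <- gen_regulatory(cfg, tr$gene_models)
  cats <- annotate_peak_category(reg$peaks_a, tr$gene_models, tr$exons)
  expect_length(cats, nrow(reg$peaks_a))
  expect_true(all(cats %in% c("promoter", "tts_proximal", "exonic",
                              "intronic", "distal_intergenic")))
})

test_that("coordinate intersection matches interval algebra and brute force", {
  p <- function(...) data.frame(chrom = "chr1", start = c(...)[c(TRUE, FALSE)],
                                end = c(...)[c(FALSE, TRUE)])
  out <- intersect_peak_sets(list(p(100, 200), p(150, 250)))
  expect_equal(out[, c("start", "end")], data.frame(start = 150, end = 200),
               ignore_attr = TRUE)
  s <- p(10, 40, 100, 130)
  expect_equal(intersect_peak_sets(list(s, s, s))[, c("start", "end")],
               s[, c("start", "end")], ignore_attr = TRUE)
  expect_equal(nrow(intersect_peak_sets(list(p(0, 10), p(20, 30)))), 0)
  expect_warning(out <- intersect_peak_sets(list(p(0, 10), p(0, 10)[0, ])),
                 "empty")
  expect_equal(nrow(out), 0)

  # random sets vs position-by-position coverage; associativity/commutativity
  set.seed(77)
  rand_set <- function() {
    n <- sample(1:6, 1)
    s <- sort(sample(0:9900, n))
    data.frame(chrom = "toy", start = s, end = pmin(s + sample(50:400, n,
                                                               replace = TRUE),
                                                    10000L))
  }
  for (i in 1:40) {
    sets <- replicate(3, rand_set(), simplify = FALSE)
    mine <- intersect_peak_sets(sets)
    oracle <- coverage_intersect(sets, 10000L)
    expect_equal(mine[, c("start", "end")], oracle, ignore_attr = TRUE)
    perm <- intersect_peak_sets(sets[c(3, 1, 2)])
    expect_equal(mine[, c("start", "end")], perm[, c("start", "end")])
  }
})

test_that("window assignment is strand-aware and matches brute force", {
  gm <- data.frame(gene_id = c("P", "M"), chrom = "chr1",
                   strand = c("+", "-"), start = c(100000L, 100000L),
                   end = c(103000L, 103000L),
                   tss = c(100000L, 100000L), tts = c(102999L, 102999L),
                   stringsAsFactors = FALSE)
  peak <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  # + strand, window [70000, 110000)
  expect_true("P" %in% assign_peaks_to_genes(peak(71000, 71500), gm)$gene_id)
  expect_false("P" %in% assign_peaks_to_genes(peak(111000, 112000), gm)$gene_id)
  # - strand: upstream runs rightward, window [90000, 130000)
  expect_true("M" %in% assign_peaks_to_genes(peak(125000, 126000), gm)$gene_id)
  expect_false("M" %in% assign_peaks_to_genes(peak(65000, 66000), gm)$gene_id)
  # strand-agnostic mode treats every gene as + strand
  expect_false("M" %in% assign_peaks_to_genes(peak(125000, 126000), gm,
                                              strand_aware = FALSE)$gene_id)

  set.seed(55)
  for (i in 1:200) {
    tss <- sample(30000:70000, 1)
    g <- data.frame(gene_id = "G", chrom = "c", strand = sample(c("+", "-"), 1),
                    start = tss, end = tss + 1000L, tss = tss,
                    tts = tss + 999L, stringsAsFactors = FALSE)
    s <- sample(0:100000, 1)
    pk <- data.frame(chrom = "c", start = s, end = s + sample(100:2000, 1))
    mine <- "G" %in% assign_peaks_to_genes(pk, g, 30000, 10000)$gene_id
    expect_equal(mine, brute_force_assigned(pk, g, 30000, 10000))
  }
})

test_that("windows clip at zero with a warning", {
  gm <- data.frame(gene_id = "E", chrom = "c", strand = "+", start = 5000L,
                   end = 6000L, tss = 5000L, tts = 5999L)
  expect_warning(w <- tss_windows(gm), "clipped")
  expect_equal(w$start, 0L)
})

test_that("triage requires all four flags and strict dependency in every line", {
  eff <- data.frame(gene_id = c("g1", "g2", "g3"),
                    line1 = c(-0.5, -0.5, -0.3),
                    line2 = c(-0.3, -0.1, -0.25))
  asg <- data.frame(gene_id = c("g1", "g2", "g3"), peak_index = 1L,
                    chrom = "c", start = 0L, end = 10L)
  rep <- triage_targets(co_up_genes = c("g1", "g2", "g3"),
                        tumor_up_genes = c("g1", "g2", "g3"),
                        common_peak_assignment = asg, gene_effects = eff)
  tr <- rep$trail
  expect_true(tr$dependency_in_both_lines[tr$gene_id == "g1"])
  expect_false(tr$dependency_in_both_lines[tr$gene_id == "g2"])  # -0.1 fails
  # ordering: strongest mean dependency first
  expect_equal(rep$final_targets, c("g1", "g3"))
  # a gene failing any single flag is excluded
  rep2 <- triage_targets(co_up_genes = c("g2", "g3"),
                         tumor_up_genes = c("g1", "g2", "g3"),
                         common_peak_assignment = asg, gene_effects = eff)
  expect_equal(rep2$final_targets, "g3")
  expect_error(triage_targets("g1", "g1", asg, eff, required_lines = character()),
               "at least one cell line")
  # boundary: a score exactly at the threshold fails (strict <)
  eff$line2[1] <- -0.2
  rep3 <- triage_targets("g1", "g1", asg, eff)
  expect_false(rep3$trail$dependency_in_both_lines[rep3$trail$gene_id == "g1"])
})

test_that("standalone regulatory fixture triage recovers the planted co-bound set", {
  cfg <- fixture_config(seed = 29, n_lnc_transcripts = 2,
                        n_coding_transcripts = 24)
  tr <- gen_transcriptome(cfg)
  pcg <- tr$gene_models$gene_id[-(1:2)]
  reg <- gen_regulatory(cfg, tr$gene_models, candidate_gene_ids = pcg)
  common <- intersect_peak_sets(list(reg$peaks_a, reg$peaks_b))
  asg <- assign_peaks_to_genes(common,
                               tr$gene_models[tr$gene_models$gene_id %in% pcg, ])
  rep <- triage_targets(co_up_genes = pcg, tumor_up_genes = pcg,
                        common_peak_assignment = asg,
                        gene_effects = reg$gene_effects)
  expect_setequal(rep$final_targets, reg$co_bound_target_ids)
})

test_that("planted co-binding is detectable by the one-sided Fisher overlap", {
  cfg <- fixture_config(seed = 41, n_lnc_transcripts = 2,
                        n_coding_transcripts = 40, co_bound_fraction = 0.4)
  tr <- gen_transcriptome(cfg)
  pcg <- tr$gene_models$gene_id[-(1:2)]
  reg <- gen_regulatory(cfg, tr$gene_models, candidate_gene_ids = pcg)
  gm <- tr$gene_models[tr$gene_models$gene_id %in% pcg, ]
  in_a <- unique(assign_peaks_to_genes(reg$peaks_a, gm)$gene_id)
  in_b <- unique(assign_peaks_to_genes(reg$peaks_b, gm)$gene_id)
  r <- fisher_overlap(in_a, in_b, pcg, alternative = "greater")
  expect_lt(r$p_value, 0.01)
})
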