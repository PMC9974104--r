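# P-site assignment, QC metrics, ORF enumeration against a brute-force
# oracle, the exact frame-bias test, and greedy de-duplication.

test_that("P-site assignment applies the offset and the length filter", {
  r <- data.frame(replicate = "rep1", transcript_id = "tx1",
                  five_prime = c(100, 40, 100), length = c(30, 20, 30))
  ps <- assign_psites(r, offset = 12)
  expect_equal(ps$position, 112)
  expect_equal(ps$count, 2)              # two identical 30-nt reads collapse
  expect_equal(attr(ps, "n_dropped"), 1) # the 20-nt read

  empty <- assign_psites(r[0, ])
  expect_equal(nrow(empty), 0)
  expect_warning(
    ps2 <- assign_psites(data.frame(replicate = "r", transcript_id = "t",
                                    five_prime = -20, length = 30)),
    "negative")
  expect_equal(nrow(ps2), 0)
})

test_that("QC: identical replicates correlate perfectly and metagene peaks at the start", {
  cds <- data.frame(transcript_id = c("t1", "t2"),
                    cds_start = c(30L, 60L), cds_end = c(120L, 180L))
  one <- data.frame(replicate = "rep1",
                    transcript_id = c("t1", "t1", "t2"),
                    position = c(30L, 45L, 60L), count = c(10L, 5L, 8L))
  two <- one; two$replicate <- "rep2"
  qc <- qc_metrics(rbind(one, two), cds)
  expect_equal(unname(qc$replicate_r["rep1", "rep2"]), 1.0)
  expect_true(all(diag(qc$replicate_r) == 1))
  # all P-sites at CDS starts or in frame 0 -> metagene max at offset 0
  expect_equal(names(which.max(qc$metagene_start)), "0")
  expect_equal(unname(qc$frame_fractions_global), c(1, 0, 0))
})

test_that("perfect periodicity yields frame fractions (1, 0, 0) on the fixture", {
  cfg <- fixture_config(seed = 4, n_lnc_transcripts = 0,
                        n_coding_transcripts = 10, periodicity = 1,
                        n_rpf_replicates = 2)
  tr <- gen_transcriptome(cfg)
  rpf <- gen_rpf(cfg, tr)
  qc <- qc_metrics(rpf$psites, tr$cds, read_lengths = rpf$read_lengths)
  expect_equal(unname(qc$frame_fractions_global), c(1, 0, 0))
  expect_equal(names(which.max(qc$length_histogram)), "30")
  expect_warning(qc_metrics(rpf$psites, tr$cds[0, ]), "no CDS annotations")
})

test_that("ORF enumeration matches hand cases and the most-5'-ATG convention", {
  o <- enumerate_atg_orfs("ATGAAATAG", min_aa = 1)
  expect_equal(nrow(o), 1)
  expect_equal(o$aa_seq, "MK")
  expect_equal(c(o$start, o$end), c(0, 9))

  expect_equal(nrow(enumerate_atg_orfs("CCCCCCCCC", min_aa = 1)), 0)

  o <- enumerate_atg_orfs("ATGATGTGA", min_aa = 1)
  expect_equal(nrow(o), 1)
  expect_equal(o$start, 0)   # most 5' ATG per (frame, stop)
})

test_that("ORF enumeration equals brute force on random sequences", {
  set.seed(42)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    mine <- enumerate_atg_orfs(s, min_aa = 3)
    oracle <- brute_force_orfs(s, min_aa = 3)
    expect_equal(mine[, c("start", "end")], oracle, ignore_attr = TRUE)
  }
})

test_that("the frame-bias p-value is the exact one-sided binomial tail", {
  cand <- data.frame(orf_id = "o1", transcript_id = "t", start = 0L,
                     end = 90L, aa_seq = NA_character_)
  make_ps <- function(f0, f1, f2) {
    pos <- c(3 * seq_len(f0) - 3, 3 * seq_len(f1) - 2, 3 * seq_len(f2) - 1)
    data.frame(replicate = "rep1", transcript_id = "t",
               position = as.integer(pos), count = 1L)
  }
  # all 30 in frame 0 -> p = (1/3)^30
  calls <- call_translated_orfs(make_ps(30, 0, 0), cand, min_psites = 10)
  expect_equal(calls$p_value, (1 / 3)^30)
  # 20 of 30 -> direct tail summation oracle
  calls <- call_translated_orfs(make_ps(20, 5, 5), cand, min_psites = 10)
  oracle <- sum(vapply(20:30, function(k) {
    choose(30, k) * (1 / 3)^k * (2 / 3)^(30 - k)
  }, numeric(1)))
  expect_equal(calls$p_value, oracle, tolerance = 1e-12)
  # under-supported ORFs are reported untested and excluded from BH
  two <- rbind(cand, within(cand, orf_id <- "o2"))
  ps <- make_ps(20, 5, 5)
  calls <- call_translated_orfs(ps[1:3, ], two, min_psites = 10)
  expect_true(all(is.na(calls$p_value)))
  expect_true(all(!calls$tested))
})

test_that("BH q-values are computed across tested candidates only", {
  cands <- data.frame(orf_id = c("a", "b", "c"),
                      transcript_id = c("t1", "t2", "t3"),
                      start = 0L, end = 90L, aa_seq = NA_character_)
  ps <- rbind(
    data.frame(replicate = "r", transcript_id = "t1",
               position = as.integer(3 * (0:29)), count = 1L),      # strong
    data.frame(replicate = "r", transcript_id = "t2",
               position = as.integer(c(3 * (0:9), 3 * (0:9) + 1)), count = 1L),
    data.frame(replicate = "r", transcript_id = "t3",
               position = 0:2, count = 1L)                          # untested
  )
  calls <- call_translated_orfs(ps, cands, min_psites = 10)
  tested_p <- calls$p_value[calls$tested]
  expect_equal(calls$q_value[calls$tested], p.adjust(tested_p, "BH"))
  expect_true(is.na(calls$q_value[calls$orf_id == "c"]))
})

test_that("de-duplication follows the greedy representative rule", {
  A <- random_aa(100)
  B <- mutate_aa(A, 1:4)        # 96% identical to A
  C <- mutate_aa(B, 50:53)      # 96% to B, 92% to A
  calls <- data.frame(orf_id = c("A", "B", "C"),
                      aa_seq = c(A, B, C),
                      n_psites = c(30L, 20L, 10L),
                      stringsAsFactors = FALSE)
  # identical sequences collapse to the better-supported one
  dup <- calls[c(1, 1), ]; dup$orf_id <- c("x", "y")
  dup$n_psites <- c(5L, 9L)
  out <- deduplicate_orfs(dup, 0.9)
  expect_equal(out$orf_id, "y")
  expect_equal(out$cluster_size, 2L)
  # unrelated sequences are both retained
  out <- deduplicate_orfs(data.frame(orf_id = c("u", "v"),
                                     aa_seq = c(random_aa(80), random_aa(80)),
                                     n_psites = c(3L, 2L)), 0.9)
  expect_equal(nrow(out), 2)
  # chain: B joins A's cluster; C fails against representative A -> 2 clusters
  out <- deduplicate_orfs(calls, 0.95)
  expect_equal(sort(out$orf_id), c("A", "C"))
  expect_equal(out$cluster_size[out$orf_id == "A"], 2L)
})
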