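#' Simulate a pooled CRISPR knockout screen
#'
#' Builds an sgRNA library over the supplied ORFs (plus positive- and
#' negative-control guides) and draws day-0/day-21 counts. Day-0 abundance is
#' negative-binomial around the configured depth (Gamma guide rates shared
#' across replicates, Poisson replicate draws). Guides of planted essential
#' ORFs and positive controls have their day-21 rate divided by
#' `depletion_fold`; negative controls are unscaled.
#'
#' When `config$n_targeting_sgrnas` is set, the total targeting-guide count
#' matches it exactly: guides are spread round-robin so each ORF receives
#' `floor(N/n)` or `ceiling(N/n)` guides.
#'
#' @param config a [fixture_config()].
#' @param orf_ids character vector of screened ORF identifiers.
#' @return list with `library` (data frame: `sgrna_id`, `target_orf_id`
#'   (`NA` for controls), `class` in targeting/positive_control/
#'   negative_control), `counts` (integer matrix, guides x samples; columns
#'   `day0_rep*`, `day21_rep*`), and `essential_orf_ids`.
#' @export
gen_screen <- function(config, orf_ids) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$depletion_fold < 1) stop("`depletion_fold` must be >= 1", call. = FALSE)
  if (length(orf_ids) < 1) stop("no ORFs to screen", call. = FALSE)

  with_seed(stage_seed(config$seed, "screen"), {
    n_orf <- length(orf_ids)
    if (!is.null(config$n_targeting_sgrnas)) {
      n_t <- config$n_targeting_sgrnas
      per <- rep(n_t %/% n_orf, n_orf)
      extra <- n_t %% n_orf
      if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    } else {
      per <- rep(config$sgrnas_per_orf, n_orf)
    }
    target <- rep(orf_ids, times = per)
    t_ids <- unlist(lapply(seq_len(n_orf), function(i) {
      sprintf("sg_%s_%d", orf_ids[i], seq_len(per[i]))
    }), use.names = FALSE)

    lib <- rbind(
      data.frame(sgrna_id = t_ids, target_orf_id = target,
                 class = "targeting", stringsAsFactors = FALSE),
      if (config$n_pos_controls > 0)
        data.frame(sgrna_id = sprintf("sg_pos_%04d", seq_len(config$n_pos_controls)),
                   target_orf_id = NA_character_, class = "positive_control",
                   stringsAsFactors = FALSE),
      if (config$n_neg_controls > 0)
        data.frame(sgrna_id = sprintf("sg_neg_%04d", seq_len(config$n_neg_controls)),
                   target_orf_id = NA_character_, class = "negative_control",
                   stringsAsFactors = FALSE)
    )
    rownames(lib) <- NULL

    n_ess <- round(config$essential_fraction * n_orf)
    essential <- if (n_ess > 0) sort(sample(orf_ids, n_ess)) else character()

    depleted <- (lib$class == "positive_control") |
      (!is.na(lib$target_orf_id) & lib$target_orf_id %in% essential)

    m <- nrow(lib)
    size <- config$nb_size
    lam0 <- rgamma(m, shape = size, rate = size / config$screen_depth)
    lam21 <- lam0 / ifelse(depleted, config$depletion_fold, 1)

    n_rep <- config$n_screen_replicates
    counts <- matrix(0L, nrow = m, ncol = 2L * n_rep,
                     dimnames = list(lib$sgrna_id,
                                     c(sprintf("day0_rep%d", seq_len(n_rep)),
                                       sprintf("day21_rep%d", seq_len(n_rep)))))
    for (r in seq_len(n_rep)) {
      counts[, r] <- rpois(m, lam0)
      counts[, n_rep + r] <- rpois(m, lam21)
    }

    list(library = lib, counts = counts, essential_orf_ids = essential)
  })
}
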