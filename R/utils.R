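# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of their
#' configuration and never perturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a named stage, derived from the master seed.
# Stays well below .Machine$integer.max for small master seeds.
stage_seed <- function(seed, stage) {
  offsets <- c(
    transcriptome = 11L, rpf = 23L, screen = 37L, cohort = 41L,
    apms = 53L, regulatory = 67L, pipeline = 79L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

geometric_mean <- function(x) exp(mean(log(x)))

stop_codons <- function() c("TAA", "TAG", "TGA")

# All 61 sense codons (no stops).
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cods, stop_codons())
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(x)
}
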