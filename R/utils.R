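# internal helpers shared across modules

# Stage identifiers for deterministic child-seed derivation: every stochastic
# stage draws from seed + 1000 * stage_id so stages are independently
# reproducible from one master seed.
.stage_ids <- c(
  genotypes = 1L, methylation = 2L, expression = 3L, gwas = 4L,
  folds = 5L, covariates = 6L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(.stage_ids))
  (as.integer(seed) + 1000L * .stage_ids[[stage]]) %% .Machine$integer.max
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s%g, %g%s, got %s",
      name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
      paste(format(x), collapse = ", ")
    ), class = "mwascan_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "mwascan_config_error")
  }
  invisible(as.integer(x))
}

# Multivariate normal log-density via Cholesky; mean zero.
mvn_logdensity <- function(z, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  quad <- sum(backsolve(ch, z, transpose = TRUE)^2)
  -0.5 * (length(z) * log(2 * pi) + logdet + quad)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Two-sided normal p-value on the log-safe scale.
z_to_p <- function(z) 2 * pnorm(-abs(z))

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
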