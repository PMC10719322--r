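#' Fine-mapping configuration
#'
#' Controls the Bayesian fine-mapping of associated CpG sites within an LD
#' block: a per-site causal prior, a prior variance scale on causal effects,
#' the maximum number of simultaneous causal sites enumerated, and the
#' credible level.
#'
#' @param prior_p Per-site prior probability of being causal.
#' @param prior_var Prior variance scale `v` of a causal effect on the
#'   Z-score scale.
#' @param max_causal Largest causal configuration enumerated.
#' @param rho Credible level of the reported credible set.
#' @param ridge_eps Ridge added to the predicted-correlation matrix when its
#'   smallest eigenvalue falls below `1e-8`.
#' @return A list of class `"finemap_config"`.
#' @export
finemap_config <- function(prior_p = 1e-3, prior_var = 40, max_causal = 3,
                           rho = 0.9, ridge_eps = 1e-6) {
  assert_fraction(prior_p, "prior_p", lo_open = TRUE, hi_open = TRUE)
  assert_fraction(rho, "rho", lo_open = TRUE)
  if (prior_var <= 0) abort("`prior_var` must be positive",
                            class = "mwascan_config_error")
  structure(list(prior_p = prior_p, prior_var = prior_var,
                 max_causal = assert_count(max_causal, "max_causal"),
                 rho = rho, ridge_eps = ridge_eps),
            class = "finemap_config")
}

#' Assign significant association records to LD blocks
#'
#' Each record is assigned to the unique block with `start <= pos < end`
#' (0-based half-open, matching LDetect-style BED input). Records falling in
#' no block are placed in singleton pseudo-blocks with a warning. Within a
#' block, the predicted-correlation matrix Omega is the sample correlation of
#' the models' predicted methylation computed on the LD reference panel.
#'
#' @param assoc Association records (needs feature_id, panel, chrom, pos, z);
#'   usually the significant rows of a [mwas_scan()] result.
#' @param weights Weight tibble covering the records' models.
#' @param ld An [ld_reference()].
#' @param blocks Tibble from [read_ld_blocks()] (block_id, chrom, start,
#'   end).
#' @return A list of block objects: block_id, chrom, start, end, `members`
#'   (tibble sorted by position: feature_id, panel, pos, z) and `omega`.
#' @export
build_blocks <- function(assoc, weights, ld, blocks) {
  assoc <- as_tibble(assoc)
  hit <- assoc |>
    left_join(blocks, by = "chrom", relationship = "many-to-many") |>
    filter(is.na(.data$start) | (.data$pos - 1 >= .data$start &
                                   .data$pos - 1 < .data$end)) |>
    distinct(.data$feature_id, .data$panel, .keep_all = TRUE)
  assigned <- assoc |>
    left_join(hit |> select("feature_id", "panel", "block_id"),
              by = c("feature_id", "panel"))
  orphan <- is.na(assigned$block_id)
  if (any(orphan)) {
    warn(sprintf("%d record(s) in no LD block; using singleton pseudo-blocks",
                 sum(orphan)))
    assigned$block_id[orphan] <-
      sprintf("singleton_%s_%s", assigned$feature_id[orphan],
              assigned$panel[orphan])
  }

  pred <- function(fid, pan) {
    w <- weights |> filter(.data$cpg_id == fid, .data$panel == pan)
    ml_idx <- match(w$variant_id, ld$geno$variants$variant_id)
    if (anyNA(ml_idx)) abort(sprintf("model %s/%s has variants missing from LD panel",
                                     pan, fid))
    d <- ld$geno$dosage[, ml_idx, drop = FALSE]
    storage.mode(d) <- "double"
    flip <- w$effect_allele == ld$geno$variants$ref[ml_idx]
    if (any(flip)) d[, flip] <- 2 - d[, flip]
    as.vector(d %*% w$weight)
  }

  split(assigned, assigned$block_id) |>
    imap(function(mem, bid) {
      mem <- mem |> arrange(.data$pos, .data$feature_id, .data$panel)
      P <- vapply(seq_len(nrow(mem)),
                  function(i) pred(mem$feature_id[i], mem$panel[i]),
                  numeric(nrow(ld$geno$dosage)))
      omega <- suppressWarnings(cor(P))
      omega[!is.finite(omega)] <- 0
      diag(omega) <- 1
      blk <- blocks |> filter(.data$block_id == bid)
      list(block_id = bid,
           chrom = mem$chrom[1],
           start = if (nrow(blk)) blk$start[1] else NA_real_,
           end = if (nrow(blk)) blk$end[1] else NA_real_,
           members = mem |> select("feature_id", "panel", "pos", "z"),
           omega = omega)
    }) |>
    unname()
}

# All causal configurations of k sites up to size max_causal, as a list of
# integer index vectors; the first element is the null configuration.
enumerate_configs <- function(k, max_causal) {
  configs <- list(integer(0))
  for (m in seq_len(min(max_causal, k))) {
    configs <- c(configs,
                 apply(combn(k, m), 2, identity, simplify = FALSE))
  }
  configs
}

#' Posterior probabilities over causal configurations in one LD block
#'
#' For every configuration `c` of at most `max_causal` causal sites (plus
#' the null configuration), the marginal likelihood of the observed Z-scores
#' is the zero-mean multivariate normal density with covariance
#' `Omega + v * Omega diag(c) Omega`; the prior is
#' `prior_p^|c| (1 - prior_p)^(k - |c|)`. Posteriors are normalized over the
#' enumerated set, with the null configuration always participating.
#'
#' @param z Numeric vector of member Z-scores.
#' @param omega Predicted-correlation matrix (unit diagonal).
#' @param config A [finemap_config()].
#' @return Tibble: config_id, members (list of member indices), size,
#'   posterior. Posteriors sum to one.
#' @export
config_posteriors <- function(z, omega, config = finemap_config()) {
  k <- length(z)
  stopifnot(nrow(omega) == k, ncol(omega) == k)
  if (any(!is.finite(z))) abort("non-finite z-scores")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) omega <- omega + config$ridge_eps * diag(k)

  configs <- enumerate_configs(k, config$max_causal)
  v <- config$prior_var
  logpost <- map_dbl(configs, function(cset) {
    m <- length(cset)
    cov_c <- omega
    if (m > 0) {
      oc <- omega[, cset, drop = FALSE]
      cov_c <- cov_c + v * tcrossprod(oc)   # Omega diag(c) Omega, Omega symmetric
    }
    ll <- mvn_logdensity(z, cov_c)
    if (is.na(ll)) return(-Inf)
    ll + m * log(config$prior_p) + (k - m) * log(1 - config$prior_p)
  })
  if (all(!is.finite(logpost))) {
    abort("no configuration has a proper likelihood (non-PSD covariance)",
          class = "mwascan_finemap_error")
  }
  post <- exp(logpost - log_sum_exp(logpost[is.finite(logpost)]))
  post[!is.finite(post)] <- 0
  tibble(
    config_id = map_chr(configs, function(s)
      if (!length(s)) "null" else paste(s, collapse = "+")),
    members = configs,
    size = lengths(configs),
    posterior = post / sum(post)
  )
}

#' Extract per-site PIPs and the rho-level credible set
#'
#' The posterior inclusion probability of site `i` is the summed posterior
#' of all configurations containing it. Sites are ranked by PIP descending
#' (ties broken by genomic position ascending) and the credible set is the
#' smallest prefix whose normalized PIP mass reaches `rho`. The
#' `null_in_credible` flag records whether the null configuration's
#' posterior exceeds `1 - rho`, i.e. whether the credible mass cannot
#' exclude "no causal site here".
#'
#' @param posteriors Output of [config_posteriors()].
#' @param members Tibble of block members (feature_id, panel, pos, z) in the
#'   order underlying the configuration indices.
#' @param config A [finemap_config()].
#' @return Tibble: feature_id, panel, pos, z, pip, in_credible_set,
#'   null_in_credible.
#' @export
credible_set <- function(posteriors, members, config = finemap_config()) {
  k <- nrow(members)
  pip <- map_dbl(seq_len(k), function(i)
    sum(posteriors$posterior[map_lgl(posteriors$members, ~ i %in% .x)]))
  null_post <- posteriors$posterior[posteriors$size == 0]
  null_post <- if (length(null_post)) null_post[1] else 0
  out <- members |>
    mutate(pip = pip, null_in_credible = null_post > (1 - config$rho))
  if (all(pip <= 0)) {
    return(out |> mutate(in_credible_set = FALSE, null_in_credible = TRUE))
  }
  ord <- order(-out$pip, out$pos)
  mass <- cumsum(out$pip[ord]) / sum(out$pip)
  n_keep <- which(mass >= config$rho - 1e-12)[1]
  sel <- ord[seq_len(n_keep)]
  sel <- sel[out$pip[sel] > 0]
  out$in_credible_set <- seq_len(k) %in% sel
  out
}

#' Fine-map significant associations across all LD blocks
#'
#' @param assoc Significant association records (see [build_blocks()]).
#' @param weights Weight tibble covering the records' models.
#' @param ld An [ld_reference()].
#' @param blocks LD-block tibble.
#' @param config A [finemap_config()].
#' @return A tibble of class `finemap_result`: block_id, feature_id, panel,
#'   pos, z, pip, in_credible_set, null_in_credible; attribute `config`
#'   records the prior settings.
#' @export
finemap_blocks <- function(assoc, weights, ld, blocks,
                           config = finemap_config()) {
  blks <- build_blocks(assoc, weights, ld, blocks)
  out <- map(blks, function(b) {
    res <- tryCatch(
      config_posteriors(b$members$z, b$omega, config),
      mwascan_finemap_error = function(e) {
        warn(sprintf("block %s skipped: %s", b$block_id, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) return(NULL)
    credible_set(res, b$members, config) |>
      mutate(block_id = b$block_id, .before = 1)
  }) |>
    list_rbind()
  class(out) <- c("finemap_result", class(out))
  attr(out, "config") <- config
  out
}
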