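#' Bonferroni threshold over the full model family
#'
#' @param n_tests Total number of models tested (summed across panels).
#' @param alpha Family-wise error rate.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  assert_count(n_tests, "n_tests")
  alpha / n_tests
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param fdr Significance level; flags use `q <= fdr` (inclusive).
#' @return Tibble: p, q, significant.
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (!length(p)) return(tibble(p = numeric(), q = numeric(),
                                significant = logical()))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, significant = q <= fdr)
}

#' Wrap a genotype panel as an LD reference
#'
#' The panel is used only for variant-variant covariance and per-variant
#' dosage standard deviations; sample-level data never enter the association
#' statistic directly.
#'
#' @param geno A `genotype_matrix`.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  structure(list(geno = geno), class = "ld_reference")
}

#' Align model weights with GWAS summary statistics
#'
#' Matches each model entry to a GWAS record by variant id (falling back to
#' chrom+pos), orienting the GWAS effect to the model's effect allele: if the
#' GWAS effect allele equals the model's, `beta` is kept; if the alleles are
#' swapped, `beta` is negated; any other allele pair is dropped as
#' unmatched. Strand-ambiguous (A/T, C/G) variants are dropped under the
#' default policy.
#'
#' @param weights One model's weight tibble (rows = entries).
#' @param stats A `gwas_sumstats` tibble.
#' @param policy `"drop_ambiguous"` (default) or `"keep"`.
#' @return The aligned entries with columns `beta`, `se`, `gwas_p` appended
#'   (beta oriented to the model's effect allele); attribute `"n_dropped"`
#'   counts unmatched plus ambiguous entries.
#' @export
harmonize_variants <- function(weights, stats,
                               policy = c("drop_ambiguous", "keep")) {
  policy <- match.arg(policy)
  st <- as_tibble(stats)[c("variant_id", "chrom", "pos", "effect_allele",
                           "other_allele", "beta", "se", "p")]
  by_id <- weights |>
    inner_join(st, by = "variant_id",
               suffix = c("", "_gwas"), relationship = "many-to-one")
  unmatched <- weights |> anti_join(st, by = "variant_id")
  if (nrow(unmatched)) {
    by_pos <- unmatched |>
      inner_join(st |> select(-"variant_id"),
                 by = c("chrom", "variant_pos" = "pos"),
                 suffix = c("", "_gwas"), relationship = "many-to-one")
    by_id <- bind_rows(by_id, by_pos)
  }
  n_in <- nrow(weights)
  out <- by_id |>
    mutate(
      same = .data$effect_allele == .data$effect_allele_gwas &
        .data$other_allele == .data$other_allele_gwas,
      swapped = .data$effect_allele == .data$other_allele_gwas &
        .data$other_allele == .data$effect_allele_gwas,
      ambiguous = is_strand_ambiguous(.data$effect_allele, .data$other_allele)
    ) |>
    filter(.data$same | .data$swapped) |>
    filter(policy == "keep" | !.data$ambiguous) |>
    mutate(beta = ifelse(.data$swapped, -.data$beta, .data$beta)) |>
    select(-"same", -"swapped", -"effect_allele_gwas", -"other_allele_gwas") |>
    rename(gwas_p = "p")
  attr(out, "n_dropped") <- n_in - nrow(out)
  out
}

# Orient LD-panel dosages to the model's effect allele and extract the
# covariance of the model's variants. Returns NULL if any variant is absent
# from the panel or has incompatible alleles.
model_ld <- function(entries, ld, ridge_eps = 1e-6) {
  pv <- ld$geno$variants
  idx <- match(entries$variant_id, pv$variant_id)
  if (anyNA(idx)) return(NULL)
  same <- entries$effect_allele == pv$alt[idx] &
    entries$other_allele == pv$ref[idx]
  flip <- entries$effect_allele == pv$ref[idx] &
    entries$other_allele == pv$alt[idx]
  if (!all(same | flip)) return(NULL)
  d <- ld$geno$dosage[, idx, drop = FALSE]
  storage.mode(d) <- "double"
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  sigma <- stats::cov(d)
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) sigma <- sigma + ridge_eps * diag(nrow(sigma))
  list(sigma = sigma, sigma_l = sqrt(diag(sigma)))
}

#' Variance of the genetically predicted level under an LD reference
#'
#' @param entries Harmonized model entries (from [harmonize_variants()], or
#'   any weight tibble whose variants exist in the panel).
#' @param ld An [ld_reference()].
#' @param ridge_eps Ridge added to the covariance when its smallest
#'   eigenvalue is negative.
#' @return List: `sigma_g2` (w' Sigma w), `sigma_l` (per-variant dosage SD),
#'   `sigma` (covariance). `sigma_g2 <= 1e-12` signals variance collapse.
#' @export
predicted_variance <- function(entries, ld, ridge_eps = 1e-6) {
  ml <- model_ld(entries, ld, ridge_eps)
  if (is.null(ml)) {
    abort("model variants missing from or allele-incompatible with LD panel")
  }
  w <- entries$weight
  list(sigma_g2 = as.numeric(t(w) %*% ml$sigma %*% w),
       sigma_l = ml$sigma_l, sigma = ml$sigma)
}

#' Summary-statistic association test for one prediction model
#'
#' Computes the S-PrediXcan-style statistic
#' \deqn{Z = \sum_l w_l \frac{\sigma_l}{\sigma_g} \frac{\beta_l}{se_l}}
#' with \eqn{\sigma_g^2 = w^\top \Sigma w} from the LD reference, the
#' per-SD log odds ratio
#' \eqn{\sum_l w_l \sigma_l^2 \beta_l / \sigma_g^2}, and the two-sided
#' normal p-value.
#'
#' @param weights One model's weight tibble.
#' @param stats A `gwas_sumstats` tibble.
#' @param ld An [ld_reference()].
#' @param policy Harmonization policy, see [harmonize_variants()].
#' @param ridge_eps Covariance ridge, see [predicted_variance()].
#' @return One-row tibble: feature_id, panel, chrom, pos, n_snps_used, z, p,
#'   effect (log OR per SD), or_per_sd, sigma_g, reason (NA when testable).
#' @export
association_test <- function(weights, stats, ld, policy = "drop_ambiguous",
                             ridge_eps = 1e-6) {
  feature_id <- weights$cpg_id[1] %||% weights$feature_id[1]
  base <- tibble(
    feature_id = feature_id, panel = weights$panel[1],
    chrom = weights$chrom[1], pos = weights$cpg_pos[1],
    n_snps_used = 0L, z = NA_real_, p = NA_real_, effect = NA_real_,
    or_per_sd = NA_real_, sigma_g = NA_real_, reason = NA_character_
  )
  h <- harmonize_variants(weights, stats, policy)
  if (nrow(h) == 0) {
    base$reason <- "no harmonizable variants"
    return(base)
  }
  ml <- model_ld(h, ld, ridge_eps)
  if (is.null(ml)) {
    base$reason <- "variants missing from LD reference"
    return(base)
  }
  w <- h$weight
  sigma_g2 <- as.numeric(t(w) %*% ml$sigma %*% w)
  if (!is.finite(sigma_g2) || sigma_g2 <= 1e-12) {
    base$reason <- "variance collapse"
    return(base)
  }
  if (any(!is.finite(h$beta)) || any(!is.finite(h$se)) || any(h$se <= 0)) {
    base$reason <- "non-finite GWAS inputs"
    return(base)
  }
  sigma_g <- sqrt(sigma_g2)
  z_stat <- sum(w * (ml$sigma_l / sigma_g) * (h$beta / h$se))
  eff <- sum(w * (ml$sigma_l^2 / sigma_g2) * h$beta)
  base |>
    mutate(n_snps_used = nrow(h), z = .env$z_stat, p = z_to_p(.env$z_stat),
           effect = .env$eff, or_per_sd = exp(.env$eff),
           sigma_g = .env$sigma_g)
}

#' Scan a model registry against GWAS summary statistics
#'
#' Runs [association_test()] for every retained model in both panels (a CpG
#' modelled by both panels yields two records), removes CpGs overlapping the
#' exclusion BED before multiple testing, applies Benjamini-Hochberg jointly
#' across all remaining tests, flags novelty by distance to known risk
#' variants (novel iff strictly more than `novel_distance` bp from every
#' known variant on the same chromosome), and reports cross-panel sign
#' concordance among CpGs significant in both panels.
#'
#' @param registry A `model_registry`.
#' @param stats A `gwas_sumstats` tibble.
#' @param ld An [ld_reference()].
#' @param known_variants Optional tibble (variant_id, chrom, pos) of known
#'   risk variants.
#' @param exclusion_bed Optional tibble (chrom, start, end), 0-based
#'   half-open, of regions whose CpGs are removed before testing (e.g.
#'   long-range LD regions).
#' @param fdr FDR level for significance flags.
#' @param novel_distance Novelty distance in bp (strict inequality).
#' @return A tibble of class `mwas_result` with columns feature_id, panel,
#'   chrom, pos, n_snps_used, z, p, q, effect, or_per_sd, sigma_g, novelty,
#'   reason; attributes `concordance` (cross-panel sign agreement fraction,
#'   NA if no CpG is significant in both panels), `bonferroni` and
#'   `n_excluded`.
#' @export
mwas_scan <- function(registry, stats, ld, known_variants = NULL,
                      exclusion_bed = NULL, fdr = 0.05,
                      novel_distance = 5e5) {
  stopifnot(inherits(registry, "model_registry"))
  weights <- registry$weights
  if (nrow(weights) == 0) abort("registry has no retained models")

  n_excluded <- 0L
  if (!is.null(exclusion_bed) && nrow(exclusion_bed)) {
    pos_tab <- weights |> distinct(.data$cpg_id, .data$chrom,
                                   pos = .data$cpg_pos)
    excluded <- pos_tab |>
      inner_join(exclusion_bed, by = "chrom",
                 relationship = "many-to-many") |>
      filter(.data$pos > .data$start, .data$pos <= .data$end) |>
      distinct(.data$cpg_id)
    n_excluded <- nrow(excluded)
    weights <- weights |> anti_join(excluded, by = "cpg_id")
  }

  records <- weights |>
    group_by(.data$panel, .data$cpg_id) |>
    group_map(~ association_test(.x |> mutate(panel = .y$panel,
                                              cpg_id = .y$cpg_id),
                                 stats, ld)) |>
    list_rbind()

  testable <- !is.na(records$z)
  records$q <- NA_real_
  if (any(testable)) {
    records$q[testable] <- p.adjust(records$p[testable], method = "BH")
  }
  records <- records |>
    mutate(significant = !is.na(.data$q) & .data$q <= fdr)

  records$novelty <- "unassessed"
  if (is.null(known_variants) || nrow(known_variants) == 0) {
    records$novelty[testable] <- "novel"
  } else {
    kv <- as_tibble(known_variants)
    bad <- !complete.cases(kv[c("chrom", "pos")])
    if (any(bad)) {
      warn(sprintf("skipping %d malformed known-variant row(s)", sum(bad)))
      kv <- kv[!bad, ]
    }
    min_dist <- map_dbl(seq_len(nrow(records)), function(i) {
      same <- kv$chrom == records$chrom[i]
      if (!any(same)) return(Inf)
      min(abs(kv$pos[same] - records$pos[i]))
    })
    records$novelty[testable] <-
      ifelse(min_dist[testable] > novel_distance, "novel", "known-locus")
  }

  both <- records |>
    filter(.data$significant) |>
    summarise(n_panels = dplyr::n_distinct(.data$panel),
              sign_agree = length(unique(sign(.data$z))) == 1,
              .by = "feature_id") |>
    filter(.data$n_panels >= 2)
  concordance <- if (nrow(both)) mean(both$sign_agree) else NA_real_

  out <- records
  class(out) <- c("mwas_result", class(out))
  attr(out, "concordance") <- concordance
  attr(out, "bonferroni") <- bonferroni_threshold(max(sum(testable), 1), 0.05)
  attr(out, "n_excluded") <- n_excluded
  out
}
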