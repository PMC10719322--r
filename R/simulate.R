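#' Simulation configuration
#'
#' Defines the generative model used throughout the package's synthetic
#' fixtures: LD-correlated biallelic genotypes, a cis-meQTL architecture with
#' configurable cis heritability, methylation-mediated gene expression, and a
#' liability-threshold case-control phenotype for GWAS summary statistics.
#'
#' The latent genotype model draws, per LD block of `block_size` adjacent
#' variants, a multivariate normal with AR(1) correlation `ld_rho`, then
#' thresholds each variant's latent value into Hardy-Weinberg genotype classes
#' at its drawn minor-allele frequency. One master `seed` drives the whole
#' generator; each stage (genotypes, methylation, expression, GWAS, folds)
#' uses the deterministic child seed `seed + 1000 * stage_id`, so stages are
#' independently reproducible.
#'
#' @param n_samples Number of individuals.
#' @param n_snps Number of biallelic variants (one chromosome, evenly spaced
#'   `snp_spacing` bp apart).
#' @param n_cpgs Number of CpG sites.
#' @param maf_range Length-2 numeric, minor-allele frequency range in
#'   (0, 0.5].
#' @param ld_rho AR(1) latent correlation between adjacent variants within an
#'   LD block, in \[0, 1).
#' @param block_size Number of adjacent variants per LD block.
#' @param cis_h2 Fraction of each CpG's latent variance explained by its
#'   causal cis variants, in \[0, 1).
#' @param n_causal_per_cpg Number of causal cis variants per CpG.
#' @param cis_window Max distance (bp) from a CpG within which its causal
#'   variants are placed.
#' @param mediation_beta Effect of the CpG latent on its mediated gene's
#'   expression (expression = `mediation_beta` * latent + N(0, 1) noise).
#' @param prevalence Disease prevalence for the liability threshold, in
#'   (0, 1).
#' @param liability_effects Named numeric vector mapping CpG ids to liability
#'   effects; `NULL` means a global null (no CpG affects risk).
#' @param snp_spacing Base pairs between adjacent variants.
#' @param seed Master seed (integer).
#'
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 500, n_snps = 200, n_cpgs = 20,
                       maf_range = c(0.05, 0.5), ld_rho = 0.5,
                       block_size = 20, cis_h2 = 0.3, n_causal_per_cpg = 2,
                       cis_window = 100000, mediation_beta = 0.5,
                       prevalence = 0.1, liability_effects = NULL,
                       snp_spacing = 1000, seed = 1) {
  n_samples <- assert_count(n_samples, "n_samples", min = 2)
  n_snps <- assert_count(n_snps, "n_snps")
  n_cpgs <- assert_count(n_cpgs, "n_cpgs")
  block_size <- assert_count(block_size, "block_size")
  n_causal_per_cpg <- assert_count(n_causal_per_cpg, "n_causal_per_cpg")
  if (n_causal_per_cpg > n_snps) {
    abort("`n_causal_per_cpg` cannot exceed `n_snps`",
          class = "mwascan_config_error")
  }
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair", class = "mwascan_config_error")
  }
  assert_fraction(maf_range[1], "maf_range[1]", lo = 0, hi = 0.5, lo_open = TRUE)
  assert_fraction(maf_range[2], "maf_range[2]", lo = 0, hi = 0.5, lo_open = TRUE)
  assert_fraction(ld_rho, "ld_rho", hi = 1, hi_open = TRUE)
  assert_fraction(cis_h2, "cis_h2", hi = 1, hi_open = TRUE)
  assert_fraction(prevalence, "prevalence", lo_open = TRUE, hi_open = TRUE)
  if (!is.null(liability_effects) &&
      (is.null(names(liability_effects)) || !is.numeric(liability_effects))) {
    abort("`liability_effects` must be a named numeric vector",
          class = "mwascan_config_error")
  }
  structure(list(
    n_samples = n_samples, n_snps = n_snps, n_cpgs = n_cpgs,
    maf_range = as.numeric(maf_range), ld_rho = ld_rho,
    block_size = block_size, cis_h2 = cis_h2,
    n_causal_per_cpg = n_causal_per_cpg, cis_window = cis_window,
    mediation_beta = mediation_beta, prevalence = prevalence,
    liability_effects = liability_effects, snp_spacing = snp_spacing,
    seed = as.integer(seed)
  ), class = "sim_config")
}

new_genotype_matrix <- function(variants, dosage, sample_ids) {
  stopifnot(ncol(dosage) == nrow(variants), nrow(dosage) == length(sample_ids))
  dimnames(dosage) <- list(sample_ids, variants$variant_id)
  structure(list(variants = variants, dosage = dosage,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  print(head(x$variants, 5))
  invisible(x)
}

new_molecular_matrix <- function(features, values, kind) {
  kind <- match.arg(kind, c("methylation-beta", "normalized", "expression"))
  dimnames(values) <- list(rownames(values), features$feature_id)
  structure(list(features = features, values = values, kind = kind),
            class = "molecular_matrix")
}

#' @export
print.molecular_matrix <- function(x, ...) {
  cat(sprintf("<molecular_matrix:%s> %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate LD-correlated genotype dosages
#'
#' Draws a latent AR(1) Gaussian within each LD block and thresholds it into
#' 0/1/2 genotype classes with Hardy-Weinberg proportions at each variant's
#' drawn minor-allele frequency. The alternate allele is the minor allele, so
#' dosage counts alternate alleles.
#'
#' A variant that happens to be monomorphic in the realized sample (possible
#' at small `n_samples` times low MAF) is given a single heterozygote in the
#' first sample so every variant stays polymorphic, as the downstream model
#' training requires.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix`: `variants` tibble (variant_id, chrom, pos,
#'   ref, alt, maf) plus a samples-by-variants dosage matrix.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, "genotypes"), {
    n <- config$n_samples
    m <- config$n_snps
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    # post-QC biallelic SNPs: alt avoids the ref complement, so no
    # strand-ambiguous (A/T, C/G) pairs enter the fixtures
    bases <- c("A", "C", "G", "T")
    complement <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- sample(bases, m, replace = TRUE)
    alt <- map_chr(ref, function(r)
      sample(setdiff(bases, c(r, complement[[r]])), 1))

    rho <- config$ld_rho
    z <- matrix(rnorm(n * m), n, m)
    if (rho > 0) {
      block <- rep(seq_len(ceiling(m / config$block_size)),
                   each = config$block_size)[seq_len(m)]
      for (j in seq_len(m)[-1]) {
        if (block[j] == block[j - 1]) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
    }
    p0 <- (1 - maf)^2
    p01 <- p0 + 2 * maf * (1 - maf)
    dosage <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      dosage[, j] <- (z[, j] > qnorm(p0[j])) + (z[, j] > qnorm(p01[j]))
    }
    mono <- which(apply(dosage, 2, function(d) length(unique(d)) == 1))
    if (length(mono)) dosage[1, mono] <- ifelse(dosage[1, mono] == 0L, 1L, 1L)

    variants <- tibble(
      variant_id = sprintf("rs%06d", seq_len(m)),
      chrom = "1",
      pos = config$snp_spacing * seq_len(m),
      ref = ref, alt = alt,
      maf = colMeans(dosage) / 2
    )
    new_genotype_matrix(variants, dosage,
                        sprintf("S%05d", seq_len(n)))
  })
}

#' Simulate methylation and mediated expression from genotypes
#'
#' Each CpG's latent level is a linear combination of its `n_causal_per_cpg`
#' nearest cis variants (standardized dosages) scaled so the genetic
#' component has variance exactly `cis_h2`, plus Gaussian noise with variance
#' `1 - cis_h2`. Methylation beta values are the inverse logit of the latent
#' plus a per-CpG baseline; each CpG mediates one gene whose expression is
#' `mediation_beta * latent + N(0, 1)`.
#'
#' @param geno A `genotype_matrix`.
#' @param config A [sim_config()].
#' @return A list: `meth` (`molecular_matrix`, beta values), `expr`
#'   (`molecular_matrix`, expression), and `truth` (causal effects, mediation
#'   coefficients, liability effects, and the latent CpG matrix used by
#'   [simulate_gwas()]).
#' @export
simulate_methylation_expression <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  if (nrow(geno$variants) == 0) abort("empty genotype matrix")
  n <- nrow(geno$dosage)
  k <- config$n_cpgs
  snp_pos <- geno$variants$pos

  withr::with_seed(child_seed(config$seed, "methylation"), {
    anchor <- round(seq_len(k) * length(snp_pos) / (k + 1))
    cpg_pos <- snp_pos[pmax(anchor, 1)] + 7L
    cpg_ids <- sprintf("cg%08d", seq_len(k))

    latent <- matrix(0, n, k)
    effects <- vector("list", k)
    b0 <- qlogis(runif(k, 0.2, 0.8))
    for (i in seq_len(k)) {
      in_cis <- which(abs(snp_pos - cpg_pos[i]) <= config$cis_window)
      if (length(in_cis) < config$n_causal_per_cpg) {
        abort(sprintf("CpG %s has %d cis variants, fewer than n_causal_per_cpg = %d",
                      cpg_ids[i], length(in_cis), config$n_causal_per_cpg),
              class = "mwascan_config_error")
      }
      causal <- in_cis[order(abs(snp_pos[in_cis] - cpg_pos[i]))][
        seq_len(config$n_causal_per_cpg)]
      w <- rnorm(length(causal))
      g <- scale(geno$dosage[, causal, drop = FALSE]) %*% w
      if (config$cis_h2 > 0 && sd(g) > 0) {
        scl <- sqrt(config$cis_h2) / sd(g)
      } else {
        scl <- 0
      }
      g <- as.vector(g) * scl
      latent[, i] <- g + rnorm(n, 0, sqrt(1 - config$cis_h2))
      effects[[i]] <- tibble(
        cpg_id = cpg_ids[i],
        variant_id = geno$variants$variant_id[causal],
        effect = w * scl
      )
    }
    colnames(latent) <- cpg_ids
    meth_features <- tibble(feature_id = cpg_ids, chrom = "1", pos = cpg_pos)
    meth <- new_molecular_matrix(meth_features, plogis(
      sweep(latent, 2, b0, "+")), "methylation-beta")
    rownames(meth$values) <- rownames(geno$dosage)
  })

  withr::with_seed(child_seed(config$seed, "expression"), {
    gene_ids <- sprintf("gene_%03d", seq_len(k))
    gene_tss <- cpg_pos + 1000L
    expr_values <- config$mediation_beta * latent +
      matrix(rnorm(n * k), n, k)
    expr_features <- tibble(feature_id = gene_ids, chrom = "1",
                            pos = gene_tss, strand = "+")
    expr <- new_molecular_matrix(expr_features, expr_values, "expression")
    rownames(expr$values) <- rownames(geno$dosage)
  })

  liab <- config$liability_effects
  truth <- list(
    cpg_effects = list_rbind(effects),
    cpg_baseline = tibble(cpg_id = cpg_ids, b0 = b0),
    mediation = tibble(gene_id = gene_ids, cpg_id = cpg_ids,
                       beta = config$mediation_beta),
    liability = tibble(
      cpg_id = cpg_ids,
      effect = if (is.null(liab)) 0 else unname(liab[cpg_ids]) %|NA|% 0
    ),
    latent = latent
  )
  missing_liab <- setdiff(names(liab), cpg_ids)
  if (length(missing_liab)) {
    abort(sprintf("liability_effects name(s) not simulated: %s",
                  paste(missing_liab, collapse = ", ")),
          class = "mwascan_config_error")
  }
  list(meth = meth, expr = expr, truth = truth)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

# Per-variant logistic regression (intercept + dosage): Wald beta, se, p.
logistic_scan <- function(dosage, y) {
  n <- length(y)
  out <- matrix(NA_real_, ncol(dosage), 3)
  for (j in seq_len(ncol(dosage))) {
    X <- cbind(1, dosage[, j])
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    info <- crossprod(X * sqrt(w))
    se <- sqrt(diag(chol2inv(chol(info))))[2]
    b <- fit$coefficients[2]
    out[j, ] <- c(b, se, z_to_p(b / se))
  }
  colnames(out) <- c("beta", "se", "p")
  out
}

#' Simulate case-control GWAS summary statistics
#'
#' Builds a liability as the weighted sum of CpG latents (weights =
#' `liability_effects`) plus standard normal environment, declares cases
#' above the empirical `1 - prevalence` liability quantile, and runs a
#' per-variant logistic regression of case status on dosage. The effect
#' allele is the alternate (minor) allele.
#'
#' @param geno A `genotype_matrix`.
#' @param config A [sim_config()].
#' @param truth Optional truth list from [simulate_methylation_expression()];
#'   required whenever `config$liability_effects` is non-null.
#' @return A tibble of class `gwas_sumstats`: variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta (log odds ratio), se, p,
#'   n_cases, n_controls.
#' @export
simulate_gwas <- function(geno, config, truth = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  n <- nrow(geno$dosage)
  withr::with_seed(child_seed(config$seed, "gwas"), {
    genetic <- 0
    if (!is.null(config$liability_effects)) {
      if (is.null(truth)) {
        abort("`truth` (with CpG latents) is required when liability_effects is set")
      }
      eff <- config$liability_effects
      genetic <- truth$latent[, names(eff), drop = FALSE] %*% eff
    }
    liability <- as.vector(genetic) + rnorm(n)
    thr <- quantile(liability, 1 - config$prevalence, names = FALSE)
    y <- as.integer(liability > thr)
    if (sum(y) == 0 || sum(y) == n) {
      abort("liability threshold produced zero cases or zero controls")
    }
    scan <- logistic_scan(geno$dosage, y)
    out <- bind_cols(
      geno$variants |>
        transmute(.data$variant_id, .data$chrom, .data$pos,
                  effect_allele = .data$alt, other_allele = .data$ref,
                  eaf = colMeans(geno$dosage) / 2),
      as_tibble(scan)
    ) |>
      mutate(n_cases = sum(y), n_controls = n - sum(y))
    class(out) <- c("gwas_sumstats", class(out))
    attr(out, "case_fraction") <- mean(y)
    attr(out, "case_status") <- setNames(y, rownames(geno$dosage))
    out
  })
}
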