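# Shared fixtures built once per test run; sizes kept small on purpose.

# Hand-built genotype matrix for exact-value tests.
make_geno <- function(dosage, pos, ref = NULL, alt = NULL, chrom = "1") {
  m <- ncol(dosage)
  ref <- ref %||% rep("A", m)
  alt <- alt %||% rep("G", m)
  variants <- tibble::tibble(
    variant_id = sprintf("rs%06d", seq_len(m)), chrom = chrom, pos = pos,
    ref = ref, alt = alt, maf = colMeans(dosage) / 2
  )
  mwascan:::new_genotype_matrix(variants, dosage,
                                sprintf("S%05d", seq_len(nrow(dosage))))
}

`%||%` <- rlang::`%||%`

# A mid-sized cohort with two causal CpGs, reused across training and
# association tests.
cohort <- local({
  cfg <- sim_config(
    n_samples = 1000, n_snps = 120, n_cpgs = 8, cis_h2 = 0.4, ld_rho = 0.3,
    n_causal_per_cpg = 2, cis_window = 5e4, seed = 7,
    liability_effects = c(cg00000002 = 0.8, cg00000005 = -0.8)
  )
  geno <- simulate_genotypes(cfg)
  sim <- simulate_methylation_expression(geno, cfg)
  meth_n <- adjust_and_normalize(sim$meth)
  stats <- simulate_gwas(geno, cfg, sim$truth)
  list(cfg = cfg, geno = geno, sim = sim, meth_n = meth_n, stats = stats,
       ld = ld_reference(geno))
})

# Independent brute-force Benjamini-Hochberg step-up rule (the oracle BH is
# tested against).
bh_bruteforce <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k / m * alpha) k_max <- k
  }
  sig <- logical(m)
  if (k_max > 0) sig[ord[seq_len(k_max)]] <- TRUE
  sig
}

# Independent MVN log-density via eigen decomposition (oracle for the
# Cholesky-based implementation inside fine-mapping).
mvn_logdensity_eigen <- function(z, sigma) {
  ee <- eigen(sigma, symmetric = TRUE)
  if (any(ee$values <= 0)) return(-Inf)
  y <- crossprod(ee$vectors, z)
  -0.5 * (length(z) * log(2 * pi) + sum(log(ee$values)) +
            sum(y^2 / ee$values))
}

# Brute-force fine-mapping over ALL 2^k configurations.
finemap_bruteforce <- function(z, omega, prior_p, v) {
  k <- length(z)
  subsets <- lapply(0:(2^k - 1), function(code) which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0))
  logpost <- vapply(subsets, function(s) {
    cov_c <- omega
    if (length(s)) {
      oc <- omega[, s, drop = FALSE]
      cov_c <- cov_c + v * oc %*% t(oc)
    }
    mvn_logdensity_eigen(z, cov_c) + length(s) * log(prior_p) +
      (k - length(s)) * log(1 - prior_p)
  }, numeric(1))
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  vapply(seq_len(k), function(i)
    sum(post[vapply(subsets, function(s) i %in% s, logical(1))]), numeric(1))
}
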