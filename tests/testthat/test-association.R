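mk_stats <- function(variant_id, effect_allele, other_allele, beta, se,
                     pos = seq_along(variant_id) * 1000, chrom = "1") {
  out <- tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = 0.3, beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
    n_cases = 1000L, n_controls = 1000L)
  class(out) <- c("gwas_sumstats", class(out))
  out
}

mk_weights <- function(variant_id, effect_allele, other_allele, weight,
                       pos = seq_along(variant_id) * 1000) {
  tibble::tibble(panel = "FHS", cpg_id = "cgA", chrom = "1", cpg_pos = 1500,
                 variant_id = variant_id, variant_pos = pos,
                 other_allele = other_allele, effect_allele = effect_allele,
                 weight = weight, standardized = FALSE)
}

test_that("harmonization keeps, flips or drops GWAS effects by allele match", {
  st <- mk_stats(c("rs1", "rs2", "rs3"),
                 effect_allele = c("A", "G", "A"),
                 other_allele = c("C", "A", "T"),
                 beta = c(0.5, 0.5, 0.5), se = 0.1)
  w <- mk_weights(c("rs1", "rs2", "rs3"),
                  effect_allele = c("A", "A", "A"),
                  other_allele = c("C", "G", "T"),
                  weight = c(1, 1, 1))
  h <- harmonize_variants(w, st)
  expect_equal(h$beta[h$variant_id == "rs1"], 0.5)    # same orientation
  expect_equal(h$beta[h$variant_id == "rs2"], -0.5)   # swapped alleles
  expect_false("rs3" %in% h$variant_id)               # A/T ambiguous
  h_keep <- harmonize_variants(w, st, policy = "keep")
  expect_equal(h_keep$beta[h_keep$variant_id == "rs3"], 0.5)
  # id-less match falls back to chrom+pos
  st2 <- mk_stats("chr1:1000", "A", "C", 0.3, 0.1, pos = 1000)
  h2 <- harmonize_variants(mk_weights("rs1", "A", "C", 1, pos = 1000), st2)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$beta, 0.3)
})

test_that("predicted variance reduces to exact closed forms", {
  a <- sqrt(3) / 2
  d1 <- 1 + c(-a, -a, a, a)
  d2 <- 1 + c(-a, a, -a, a)
  geno <- make_geno(cbind(d1, d2), pos = c(1000, 2000))
  ld <- ld_reference(geno)
  w <- mk_weights(c("rs000001", "rs000002"), c("G", "G"), c("A", "A"),
                  weight = c(1, 1))
  pv <- predicted_variance(w, ld)
  expect_equal(pv$sigma_g2, 2, tolerance = 1e-12)

  # perfectly correlated pair with opposite weights collapses
  geno2 <- make_geno(cbind(d1, d1), pos = c(1000, 2000))
  st <- mk_stats(c("rs000001", "rs000002"), c("G", "G"), c("A", "A"),
                 beta = c(0.2, 0.2), se = 0.05)
  rec <- association_test(
    mk_weights(c("rs000001", "rs000002"), c("G", "G"), c("A", "A"),
               weight = c(1, -1)),
    st, ld_reference(geno2))
  expect_equal(rec$reason, "variance collapse")
  expect_true(is.na(rec$z))
})

test_that("sigma_g2 equals the sample variance of the panel prediction", {
  g <- cohort$geno
  withr::with_seed(11, {
    idx <- sample(ncol(g$dosage), 6)
    w <- rnorm(6)
  })
  v <- g$variants[idx, ]
  entries <- tibble::tibble(
    panel = "FHS", cpg_id = "cgA", chrom = "1", cpg_pos = 1,
    variant_id = v$variant_id, variant_pos = v$pos,
    other_allele = v$ref, effect_allele = v$alt, weight = w,
    standardized = FALSE)
  pv <- predicted_variance(entries, cohort$ld)
  pred <- as.vector(g$dosage[, idx] %*% w)
  expect_lt(abs(pv$sigma_g2 - var(pred)) / var(pred), 1e-9)
})

test_that("a single-variant model reduces exactly to the GWAS Z", {
  withr::with_seed(12, {
    d <- rbinom(500, 2, 0.3)
    geno <- make_geno(matrix(d), pos = 1000)
  })
  st <- mk_stats("rs000001", "G", "A", beta = 0.37, se = 0.11, pos = 1000)
  rec <- association_test(mk_weights("rs000001", "G", "A", 2.5, pos = 1000),
                          st, ld_reference(geno))
  expect_equal(rec$z, 0.37 / 0.11, tolerance = 1e-12)
  expect_equal(rec$p, 2 * pnorm(-abs(0.37 / 0.11)), tolerance = 1e-12)
})

test_that("null GWAS effects give z = 0 and unit odds ratio", {
  withr::with_seed(13, {
    dosage <- matrix(rbinom(600, 2, 0.3), 300, 2)
    geno <- make_geno(dosage, pos = c(1000, 2000))
  })
  st <- mk_stats(c("rs000001", "rs000002"), c("G", "G"), c("A", "A"),
                 beta = c(0, 0), se = 0.1)
  rec <- association_test(
    mk_weights(c("rs000001", "rs000002"), c("G", "G"), c("A", "A"),
               c(1, 2)), st, ld_reference(geno))
  expect_equal(rec$z, 0)
  expect_equal(rec$or_per_sd, 1)
})

test_that("flipping a model entry's alleles with weight negation leaves z
           unchanged", {
  withr::with_seed(14, {
    dosage <- matrix(rbinom(900, 2, 0.4), 300, 3)
    geno <- make_geno(dosage, pos = c(1000, 2000, 3000))
    betas <- rnorm(3, 0, 0.2)
  })
  st <- mk_stats(sprintf("rs%06d", 1:3), rep("G", 3), rep("A", 3),
                 beta = betas, se = 0.1)
  w0 <- mk_weights(sprintf("rs%06d", 1:3), rep("G", 3), rep("A", 3),
                   weight = c(0.5, -1, 2))
  w_flip <- w0
  w_flip$effect_allele[2] <- "A"
  w_flip$other_allele[2] <- "G"
  w_flip$weight[2] <- -w_flip$weight[2]
  z0 <- association_test(w0, st, ld_reference(geno))$z
  z1 <- association_test(w_flip, st, ld_reference(geno))$z
  expect_equal(z0, z1, tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bonferroni_threshold(166290), 0.05 / 166290)
  toy <- bh_adjust(c(0.01, 0.02, 0.03))
  expect_true(all(toy$significant))
  ones <- bh_adjust(rep(1, 5))
  expect_false(any(ones$significant))
  expect_true(all(ones$q == 1))
  expect_equal(nrow(bh_adjust(numeric())), 0)

  withr::with_seed(15, {
    for (i in 1:1000) {
      m <- sample(1:40, 1)
      p <- runif(m)^sample(c(1, 3), 1)   # mix of null-ish and enriched
      res <- bh_adjust(p)
      expect_identical(res$significant, bh_bruteforce(p, 0.05))
      expect_true(all(res$q >= res$p))
    }
  })
})

test_that("scan flags novelty by strict distance and handles exclusions", {
  # two CpGs in the cohort carry real liability effects
  pf <- train_panel(cohort$geno, cohort$meth_n,
                    training_config("FHS", cis_window = 5e4, seed = 3))
  pb <- train_panel(cohort$geno, cohort$meth_n,
                    training_config("BIOS", cis_window = 5e4, seed = 3))
  reg <- build_registry(list(pf, pb), min_r2 = 0.01)
  res <- mwas_scan(reg, cohort$stats, cohort$ld)
  expect_true(all(res$novelty[!is.na(res$z)] == "novel"))  # no known list
  # p consistent with z under the standard normal
  ok <- !is.na(res$z)
  expect_equal(res$p[ok], 2 * pnorm(-abs(res$z[ok])), tolerance = 1e-12)

  # distance rule around one CpG's position, strict at 500 kb
  cpg2 <- res |> dplyr::filter(feature_id == "cg00000002") |> head(1)
  known_far <- tibble::tibble(variant_id = "kv1", chrom = "1",
                              pos = cpg2$pos + 500001)
  known_near <- tibble::tibble(variant_id = "kv1", chrom = "1",
                               pos = cpg2$pos + 499999)
  res_far <- mwas_scan(reg, cohort$stats, cohort$ld,
                       known_variants = known_far)
  res_near <- mwas_scan(reg, cohort$stats, cohort$ld,
                        known_variants = known_near)
  get_nov <- function(r) r$novelty[r$feature_id == "cg00000002"][1]
  expect_equal(get_nov(res_far), "novel")
  expect_equal(get_nov(res_near), "known-locus")

  # excluding a CpG's region removes it before multiple testing
  excl <- tibble::tibble(chrom = "1", start = cpg2$pos - 10,
                         end = cpg2$pos + 10)
  res_ex <- mwas_scan(reg, cohort$stats, cohort$ld, exclusion_bed = excl)
  expect_false("cg00000002" %in% res_ex$feature_id)
  expect_equal(attr(res_ex, "n_excluded"), 1L)
  kept <- !is.na(res_ex$z)
  expect_equal(res_ex$q[kept], p.adjust(res_ex$p[kept], "BH"))

  # causal CpGs significant in both panels agree in sign
  expect_equal(attr(res, "concordance"), 1.0)
  expect_gte(sum(res$significant &
                   res$feature_id %in% c("cg00000002", "cg00000005")), 4)
})
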