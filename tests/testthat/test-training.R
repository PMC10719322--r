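test_that("the meQTL cis window is strict for BIOS-style training", {
  withr::with_seed(1, {
    n <- 200
    dosage <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
    geno <- make_geno(dosage, pos = c(1000, 251001, 251003))
  })
  # CpG at 1002: distances 2 / 249999 / 250001
  meth <- mwascan:::new_molecular_matrix(
    tibble::tibble(feature_id = "cgA", chrom = "1", pos = 1002L),
    matrix(scale(geno$dosage[, 1] + rnorm(200, 0, 0.5)),
           dimnames = list(NULL, "cgA")),
    "normalized")
  cfg <- training_config("BIOS", seed = 1)
  cand <- meqtl_prefilter(geno, meth, cfg)
  tested <- attr(cand, "pairs")$variant_id
  expect_true("rs000002" %in% tested)    # 249,999 bp away: tested
  expect_false("rs000003" %in% tested)   # 250,001 bp away: not tested
})

test_that("a variant exactly at the window edge is included under an
           inclusive FHS-style window", {
  withr::with_seed(2, {
    dosage <- matrix(rbinom(400, 2, 0.3), 200, 2)
    geno <- make_geno(dosage, pos = c(5000, 6000))
  })
  meth <- mwascan:::new_molecular_matrix(
    tibble::tibble(feature_id = "cgA", chrom = "1", pos = 4000L),
    matrix(rnorm(200), dimnames = list(NULL, "cgA")), "normalized")
  fit_in <- train_cpg_model(geno, meth, "cgA",
                            training_config("FHS", cis_window = 2000,
                                            maf_min = 0, seed = 1))
  # both variants (distances 1000 and exactly 2000) are candidates
  expect_true(fit_in$summary$status %in% c("trained", "rejected"))
  strict <- train_cpg_model(geno, meth, "cgA",
                            training_config("FHS", cis_window = 2000,
                                            window_inclusive = FALSE,
                                            maf_min = 0, seed = 1))
  # with a strict window only one variant remains -> too few to train
  expect_equal(strict$summary$reason, "fewer than 2 cis variants")
})

test_that("meQTL gate retains exactly the CpG carrying a real signal", {
  withr::with_seed(3, {
    n <- 400
    dosage <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
    geno <- make_geno(dosage, pos = c(1000, 2000, 3000, 4000))
    vals <- cbind(
      cgSig = as.vector(scale(dosage[, 1])) + rnorm(n, 0, 0.3),
      cgNull = rnorm(n)
    )
  })
  meth <- mwascan:::new_molecular_matrix(
    tibble::tibble(feature_id = c("cgSig", "cgNull"), chrom = "1",
                   pos = c(1500L, 2500L)),
    vals, "normalized")
  cand <- meqtl_prefilter(geno, meth, training_config("BIOS", seed = 1))
  expect_identical(names(cand), "cgSig")
  # the gate admits all cis variants of the retained CpG, not only the hit
  expect_gt(length(cand$cgSig), 1)
})

test_that("elastic net recovers a planted cis meQTL with honest CV R2", {
  withr::with_seed(4, {
    n <- 500
    dosage <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
    geno <- make_geno(dosage, pos = seq(1000, 10000, by = 1000))
    g <- as.vector(scale(dosage[, 4]))
    y <- sqrt(0.5) * g + rnorm(n, 0, sqrt(0.5))
  })
  meth <- mwascan:::new_molecular_matrix(
    tibble::tibble(feature_id = "cgA", chrom = "1", pos = 4007L),
    matrix(y, dimnames = list(NULL, "cgA")), "normalized")
  fit <- train_cpg_model(geno, meth, "cgA",
                         training_config("FHS", cis_window = 1e5, seed = 1))
  expect_equal(fit$summary$status, "trained")
  expect_true("rs000004" %in% fit$weights$variant_id)
  expect_gt(fit$summary$cv_r2, 0.35)
  expect_lt(fit$summary$cv_r2, 0.6)
})

test_that("pure-noise CpGs are rejected or score below the R2 floor", {
  ok <- vapply(1:100, function(rep) {
    withr::with_seed(5000 + rep, {
      n <- 500
      dosage <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
      geno <- make_geno(dosage, pos = seq(1000, 8000, by = 1000))
      y <- rnorm(n)
    })
    meth <- mwascan:::new_molecular_matrix(
      tibble::tibble(feature_id = "cgA", chrom = "1", pos = 4007L),
      matrix(y, dimnames = list(NULL, "cgA")), "normalized")
    fit <- train_cpg_model(geno, meth, "cgA",
                           training_config("FHS", cis_window = 1e5,
                                           seed = rep))
    fit$summary$status == "rejected" || fit$summary$cv_r2 < 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("lasso keeps at most one of two perfectly collinear predictors", {
  withr::with_seed(6, {
    n <- 300
    d1 <- rbinom(n, 2, 0.4)
    y <- as.vector(scale(d1)) + rnorm(n, 0, 0.5)
    geno <- make_geno(cbind(d1, d1), pos = c(1000, 2000))
  })
  meth <- mwascan:::new_molecular_matrix(
    tibble::tibble(feature_id = "cgA", chrom = "1", pos = 1500L),
    matrix(y, dimnames = list(NULL, "cgA")), "normalized")
  fit <- train_cpg_model(geno, meth, "cgA",
                         training_config("FHS", cis_window = 1e4, alpha = 1,
                                         seed = 1))
  expect_lte(nrow(fit$weights), 1)
})

test_that("cross-validated R2 collapses under label permutation", {
  withr::with_seed(7, {
    n <- 300
    dosage <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
    geno <- make_geno(dosage, pos = seq(1000, 6000, by = 1000))
    y <- as.vector(scale(dosage[, 3])) + rnorm(n, 0, 0.7)
  })
  r2 <- vapply(1:50, function(rep) {
    y_perm <- withr::with_seed(7000 + rep, sample(y))
    meth <- mwascan:::new_molecular_matrix(
      tibble::tibble(feature_id = "cgA", chrom = "1", pos = 3007L),
      matrix(y_perm, dimnames = list(NULL, "cgA")), "normalized")
    fit <- train_cpg_model(geno, meth, "cgA",
                           training_config("FHS", cis_window = 1e5,
                                           seed = rep))
    if (fit$summary$status == "rejected") 0 else fit$summary$cv_r2
  }, numeric(1))
  expect_lt(median(r2), 0.01)
})

test_that("training is deterministic given data and seed", {
  fit1 <- train_cpg_model(cohort$geno, cohort$meth_n, "cg00000002",
                          training_config("FHS", cis_window = 5e4, seed = 3))
  fit2 <- train_cpg_model(cohort$geno, cohort$meth_n, "cg00000002",
                          training_config("FHS", cis_window = 5e4, seed = 3))
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(fit1$summary, fit2$summary)
})

test_that("registry applies the inclusive R2 floor and the probe-SNP filter", {
  mk_panel <- function(cpgs, r2, snp_pos) {
    weights <- purrr::list_rbind(purrr::map2(cpgs, snp_pos, function(cg, vp)
      tibble::tibble(panel = "FHS", cpg_id = cg, chrom = "1",
                     cpg_pos = 5000, variant_id = paste0("v", cg),
                     variant_pos = vp, other_allele = "A",
                     effect_allele = "G", weight = 1, standardized = FALSE)))
    summary <- tibble::tibble(panel = "FHS", cpg_id = cpgs, chrom = "1",
                              pos = 5000, cv_r2 = r2,
                              n_snps_model = 1L, status = "trained",
                              reason = NA_character_)
    structure(list(weights = weights, summary = summary,
                   config = training_config("FHS")),
              class = "weight_panel")
  }
  panel <- mk_panel(c("cg1", "cg2", "cg3", "cg4"),
                    r2 = c(0.005, 0.01, 0.02, 0.5),
                    snp_pos = c(100000, 100000, 100000, 5000))
  probes <- tibble::tibble(cpg_id = c("cg1", "cg2", "cg3", "cg4"),
                           chrom = "1", start = 4975L, end = 5024L)
  reg <- build_registry(list(panel), probes, min_r2 = 0.01)
  kept <- reg$summary$cpg_id[reg$summary$retained]
  expect_setequal(kept, c("cg2", "cg3"))      # 0.01 inclusive; cg4 probe SNP
  expect_true(reg$summary$probe_snp[reg$summary$cpg_id == "cg4"])
  # count conservation: attempted = trained + rejected
  expect_equal(reg$counts$trained + reg$counts$rejected,
               nrow(reg$summary))
})

test_that("a model without a probe interval is retained with a warning", {
  weights <- tibble::tibble(panel = "FHS", cpg_id = "cgX", chrom = "1",
                            cpg_pos = 5000, variant_id = "v1",
                            variant_pos = 5000, other_allele = "A",
                            effect_allele = "G", weight = 1,
                            standardized = FALSE)
  summary <- tibble::tibble(panel = "FHS", cpg_id = "cgX", chrom = "1",
                            pos = 5000, cv_r2 = 0.3, n_snps_model = 1L,
                            status = "trained", reason = NA_character_)
  panel <- structure(list(weights = weights, summary = summary,
                          config = training_config("FHS")),
                     class = "weight_panel")
  probes <- tibble::tibble(cpg_id = "cgOther", chrom = "1",
                           start = 0L, end = 49L)
  expect_warning(reg <- build_registry(list(panel), probes),
                 "without probe interval")
  expect_true(reg$summary$retained)
})

test_that("panel union accounting follows inclusion-exclusion", {
  u <- union_accounting(c("a", "b", "c"), c("b", "c", "d", "e"),
                        labels = c("FHS", "BIOS"))
  expect_equal(u$n_union, 5)
  expect_equal(u$n_shared, 2)
  expect_equal(u$n_a_only, 1)
  expect_equal(u$n_b_only, 2)
  expect_equal(u$n_union, u$n_a + u$n_b - u$n_shared)
})

test_that("unstandardizing weights preserves predictions up to a constant", {
  expect_identical(
    unstandardize_weights(
      tibble::tibble(variant_id = "rs1", weight = 1, standardized = TRUE),
      c(rs1 = 1))$weight, 1)
  expect_equal(
    unstandardize_weights(
      tibble::tibble(variant_id = "rs1", weight = 1, standardized = TRUE),
      c(rs1 = 2))$weight, 0.5)

  withr::with_seed(8, {
    n <- 400
    dosage <- matrix(rbinom(n * 5, 2, 0.35), n, 5)
    w_std <- rnorm(5)
  })
  ids <- sprintf("rs%d", 1:5)
  sds <- apply(dosage, 2, sd)
  w_tab <- tibble::tibble(variant_id = ids, weight = w_std,
                          standardized = TRUE)
  w_raw <- unstandardize_weights(w_tab, setNames(sds, ids))
  pred_std <- scale(dosage) %*% w_std
  pred_raw <- dosage %*% w_raw$weight
  expect_lt(abs(var(pred_raw) - var(pred_std)) / var(pred_std), 1e-9)
  expect_lt(sd((pred_raw - pred_std) - mean(pred_raw - pred_std)), 1e-9)

  expect_warning(
    out <- unstandardize_weights(
      tibble::tibble(variant_id = c("rs1", "rs2"), weight = c(1, 1),
                     standardized = TRUE),
      c(rs1 = 1)),
    "missing or zero")
  expect_equal(nrow(out), 1)
  expect_error(
    suppressWarnings(unstandardize_weights(
      tibble::tibble(variant_id = "rs2", weight = 1, standardized = TRUE),
      c(rs1 = 1))),
    class = "mwascan_rejection")
})
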