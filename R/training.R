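#' Training configuration for cis methylation prediction models
#'
#' Two panel styles are supported, mirroring the two common modelling
#' strategies for blood methylation weights: `"FHS"` (elastic net over all
#' variants within a 2 Mb window flanking the CpG, boundary inclusive) and
#' `"BIOS"` (a genome-wide meQTL pre-filter at 5% FDR gating CpGs, then an
#' elastic net over variants strictly closer than 250 kb).
#'
#' @param panel `"FHS"` or `"BIOS"`.
#' @param cis_window Window half-width in bp. Defaults: 1e6 (FHS), 2.5e5
#'   (BIOS).
#' @param window_inclusive Whether a variant exactly at `cis_window` bp is in
#'   the window. Defaults: `TRUE` for FHS ("flanking ... inclusive"),
#'   `FALSE` for BIOS ("closer than").
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param n_folds Cross-validation folds for the penalty path.
#' @param meqtl_fdr BH-FDR level for the BIOS-style meQTL CpG gate.
#' @param min_r2 Minimum cross-validated R2 for registry inclusion
#'   (inclusive threshold).
#' @param maf_min Minimum minor-allele frequency for candidate variants.
#' @param restrict_to_meqtl If `TRUE`, the elastic net sees only the
#'   FDR-significant SNP-CpG pairs instead of all cis variants of a gated
#'   CpG.
#' @param exclude_ambiguous Drop strand-ambiguous (A/T, C/G) variants before
#'   training, mirroring standard pre-training SNP QC; such variants cannot
#'   be safely harmonized with external summary statistics.
#' @param exclude_variants Optional character vector of variant ids to drop
#'   before training (stands in for external SNP QC lists such as imputation
#'   quality filters).
#' @param seed Seed for fold assignment.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(panel = c("FHS", "BIOS"), cis_window = NULL,
                            window_inclusive = NULL, alpha = 0.5,
                            n_folds = 5, meqtl_fdr = 0.05, min_r2 = 0.01,
                            maf_min = 0.05, restrict_to_meqtl = FALSE,
                            exclude_ambiguous = TRUE,
                            exclude_variants = character(), seed = 1) {
  panel <- match.arg(panel)
  cis_window <- cis_window %||% if (panel == "FHS") 1e6 else 2.5e5
  window_inclusive <- window_inclusive %||% (panel == "FHS")
  assert_fraction(alpha, "alpha")
  if (cis_window <= 0) abort("`cis_window` must be positive",
                             class = "mwascan_config_error")
  if (min_r2 < 0) abort("`min_r2` must be >= 0", class = "mwascan_config_error")
  assert_fraction(meqtl_fdr, "meqtl_fdr", lo_open = TRUE)
  structure(list(panel = panel, cis_window = cis_window,
                 window_inclusive = window_inclusive, alpha = alpha,
                 n_folds = assert_count(n_folds, "n_folds", min = 2),
                 meqtl_fdr = meqtl_fdr, min_r2 = min_r2, maf_min = maf_min,
                 restrict_to_meqtl = restrict_to_meqtl,
                 exclude_ambiguous = exclude_ambiguous,
                 exclude_variants = exclude_variants,
                 seed = as.integer(seed)),
            class = "training_config")
}

in_cis <- function(dist, config) {
  if (config$window_inclusive) dist <= config$cis_window
  else dist < config$cis_window
}

#' meQTL pre-filter: gate CpGs on having a significant cis meQTL
#'
#' Runs a simple linear regression for every SNP-CpG pair within the cis
#' window, applies Benjamini-Hochberg across all tested pairs jointly, and
#' retains a CpG iff at least one of its pairs is significant at
#' `config$meqtl_fdr`. The candidate set returned per retained CpG is all of
#' its cis variants (the significance requirement acts as a CpG-level gate),
#' unless `config$restrict_to_meqtl` is set.
#'
#' @param geno A `genotype_matrix`.
#' @param meth A `molecular_matrix` (normalized values recommended).
#' @param config A [training_config()].
#' @return Named list mapping retained CpG ids to candidate variant id
#'   vectors, with the full pair-level test table in attribute `"pairs"`.
#' @export
meqtl_prefilter <- function(geno, meth, config) {
  n <- nrow(geno$dosage)
  pairs <- vector("list", nrow(meth$features))
  for (i in seq_len(nrow(meth$features))) {
    cpg <- meth$features$feature_id[i]
    y <- meth$values[, cpg]
    idx <- which(geno$variants$chrom == meth$features$chrom[i] &
                   in_cis(abs(geno$variants$pos - meth$features$pos[i]), config))
    if (!length(idx)) next
    if (sd(y) == 0) {
      inform(sprintf("constant CpG vector, skipped: %s", cpg))
      next
    }
    r <- suppressWarnings(
      as.vector(cor(geno$dosage[, idx, drop = FALSE], y)))
    r[is.na(r)] <- 0
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    pairs[[i]] <- tibble(
      cpg_id = cpg, variant_id = geno$variants$variant_id[idx],
      r = r, p = 2 * pt(-abs(tstat), df = n - 2)
    )
  }
  pairs <- list_rbind(pairs)
  if (is.null(pairs) || nrow(pairs) == 0) {
    out <- list()
    attr(out, "pairs") <- tibble()
    return(out)
  }
  pairs$q <- p.adjust(pairs$p, method = "BH")
  gated <- pairs |>
    summarise(pass = any(.data$q <= config$meqtl_fdr), .by = "cpg_id") |>
    filter(.data$pass)
  keep <- if (config$restrict_to_meqtl) {
    pairs |> filter(.data$q <= config$meqtl_fdr)
  } else {
    pairs |> semi_join(gated, by = "cpg_id")
  }
  out <- split(keep$variant_id, keep$cpg_id)[gated$cpg_id]
  attr(out, "pairs") <- pairs
  out
}

#' Train one CpG's cis prediction model by cross-validated elastic net
#'
#' Fits `glmnet` with mixing `config$alpha` over the CpG's cis variants
#' (after the MAF filter and any exclusion list), choosing the penalty by
#' `n_folds`-fold cross-validation at the minimum-CV-error lambda. The
#' reported `cv_r2` is the squared correlation between the out-of-fold
#' predictions at that lambda and the observed values, so it is an honest
#' estimate of prediction performance.
#'
#' @param geno A `genotype_matrix`.
#' @param meth A `molecular_matrix` containing the CpG.
#' @param cpg_id CpG to model.
#' @param config A [training_config()].
#' @param candidates Optional variant id vector restricting the cis set
#'   (e.g. from [meqtl_prefilter()]).
#' @return A list: `weights` (tibble of nonzero entries, or `NULL` on
#'   rejection) and `summary` (one-row tibble: panel, cpg_id, chrom, pos,
#'   cv_r2, n_snps_model, status, reason).
#' @export
train_cpg_model <- function(geno, meth, cpg_id, config, candidates = NULL) {
  fi <- match(cpg_id, meth$features$feature_id)
  if (is.na(fi)) abort(sprintf("unknown CpG: %s", cpg_id))
  chrom <- meth$features$chrom[fi]
  pos <- meth$features$pos[fi]
  y <- meth$values[, cpg_id]

  reject <- function(reason) list(weights = NULL, summary = tibble(
    panel = config$panel, cpg_id = cpg_id, chrom = chrom, pos = pos,
    cv_r2 = NA_real_, n_snps_model = 0L, status = "rejected", reason = reason))

  if (sd(y) == 0) return(reject("constant methylation"))
  idx <- which(geno$variants$chrom == chrom &
                 in_cis(abs(geno$variants$pos - pos), config) &
                 geno$variants$maf >= config$maf_min &
                 !(geno$variants$variant_id %in% config$exclude_variants) &
                 !(config$exclude_ambiguous &
                     is_strand_ambiguous(geno$variants$ref,
                                         geno$variants$alt)))
  if (!is.null(candidates)) {
    idx <- idx[geno$variants$variant_id[idx] %in% candidates]
  }
  if (length(idx) < 2) return(reject("fewer than 2 cis variants"))

  x <- geno$dosage[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  foldid <- withr::with_seed(
    child_seed(config$seed, "folds"),
    sample(rep_len(seq_len(config$n_folds), length(y))))
  fit <- glmnet::cv.glmnet(x, y, alpha = config$alpha,
                           nfolds = config$n_folds, foldid = foldid,
                           keep = TRUE, standardize = TRUE)
  i_min <- match(fit$lambda.min, fit$lambda)
  oof <- fit$fit.preval[, i_min]
  cv_r2 <- if (sd(oof) == 0) 0 else cor(oof, y)^2
  beta <- as.vector(coef(fit, s = "lambda.min"))[-1]
  # coordinate descent can leave ~1e-13 residues on redundant columns
  nz <- which(abs(beta) > 1e-8)
  if (!length(nz)) return(reject("all weights zero"))

  v <- geno$variants[idx[nz], ]
  list(
    weights = tibble(
      panel = config$panel, cpg_id = cpg_id, chrom = chrom, cpg_pos = pos,
      variant_id = v$variant_id, variant_pos = v$pos,
      other_allele = v$ref, effect_allele = v$alt,
      weight = beta[nz], standardized = FALSE
    ),
    summary = tibble(
      panel = config$panel, cpg_id = cpg_id, chrom = chrom, pos = pos,
      cv_r2 = cv_r2, n_snps_model = length(nz), status = "trained",
      reason = NA_character_
    )
  )
}

#' Train a full panel of CpG models
#'
#' For a BIOS-style config the meQTL pre-filter is applied first and only
#' gated CpGs are trained; FHS-style trains every CpG.
#'
#' @inheritParams train_cpg_model
#' @param cpgs Optional subset of CpG ids.
#' @return A list of class `"weight_panel"`: `weights` (long tibble, one row
#'   per model entry), `summary` (one row per attempted CpG), `config`.
#' @export
train_panel <- function(geno, meth, config, cpgs = NULL) {
  cpgs <- cpgs %||% meth$features$feature_id
  candidates <- NULL
  if (config$panel == "BIOS") {
    candidates <- meqtl_prefilter(geno, meth, config)
    gated <- intersect(cpgs, names(candidates))
    skipped <- setdiff(cpgs, gated)
    cpgs <- gated
  } else {
    skipped <- character()
  }
  fits <- map(cpgs, function(cg) {
    train_cpg_model(geno, meth, cg, config,
                    candidates = if (is.null(candidates)) NULL else
                      candidates[[cg]])
  })
  summary <- list_rbind(map(fits, "summary"))
  if (length(skipped)) {
    fi <- match(skipped, meth$features$feature_id)
    summary <- bind_rows(summary, tibble(
      panel = config$panel, cpg_id = skipped,
      chrom = meth$features$chrom[fi], pos = meth$features$pos[fi],
      cv_r2 = NA_real_, n_snps_model = 0L, status = "rejected",
      reason = "no significant meQTL"))
  }
  structure(list(
    weights = list_rbind(map(fits, "weights")),
    summary = summary, config = config
  ), class = "weight_panel")
}

#' @export
print.weight_panel <- function(x, ...) {
  cat(sprintf("<weight_panel:%s> %d trained / %d attempted CpGs\n",
              x$config$panel, sum(x$summary$status == "trained"),
              nrow(x$summary)))
  invisible(x)
}

#' Convert standardized SNP weights to the raw-dosage scale
#'
#' Standardized models carry weights per standard deviation of dosage;
#' dividing each weight by that variant's reference-population dosage
#' standard deviation yields weights applicable to raw allele dosages, with
#' identical predictions up to an additive constant.
#'
#' @param weights Weight tibble with a `standardized` flag column set.
#' @param ref_sd Named numeric vector of per-variant dosage standard
#'   deviations.
#' @return The weight tibble on the raw-dosage scale (`standardized` =
#'   `FALSE`); variants with missing or zero `ref_sd` are dropped with a
#'   warning.
#' @export
unstandardize_weights <- function(weights, ref_sd) {
  if (!all(weights$standardized)) {
    abort("`weights` must be standardized models")
  }
  sd_v <- unname(ref_sd[weights$variant_id])
  bad <- is.na(sd_v) | sd_v <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d variant(s) with missing or zero reference SD",
                 sum(bad)))
    weights <- weights[!bad, ]
    sd_v <- sd_v[!bad]
  }
  if (nrow(weights) == 0) {
    abort("no variants left after reference-SD filtering",
          class = "mwascan_rejection")
  }
  weights |>
    mutate(weight = .data$weight / sd_v, standardized = FALSE)
}
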