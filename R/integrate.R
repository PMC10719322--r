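#' Rank-based inverse normal transform (Blom offset)
#'
#' Maps a vector to normal quantiles via
#' `qnorm((rank - 3/8) / (n + 1/4))`. Ties receive average ranks.
#'
#' @param x Numeric vector without missing values.
#' @return Transformed vector with mean ~0.
#' @export
inverse_normal_transform <- function(x) {
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

#' Quantile-normalize, inverse-normal transform, and residualize a matrix
#'
#' The normalization pipeline applied before any correlation or model
#' training: (1) quantile normalization across samples, so every sample
#' shares the mean sorted profile; (2) per-feature rank-based inverse normal
#' transform (Blom offset 3/8); (3) least-squares residualization on the
#' covariates (with intercept). Output features have |mean| < 1e-8 and are
#' orthogonal to every covariate column.
#'
#' Constant features cannot be rank-transformed and are dropped with a
#' warning.
#'
#' @param mat A `molecular_matrix` (samples x features).
#' @param covariates Optional tibble with `sample_id` plus numeric covariate
#'   columns (age, sex, cell-type fractions, genotype PCs, ...). Must be
#'   full column rank.
#' @return A `molecular_matrix` with kind `"normalized"`.
#' @export
adjust_and_normalize <- function(mat, covariates = NULL) {
  stopifnot(inherits(mat, "molecular_matrix"))
  vals <- mat$values
  if (nrow(vals) < 3) abort("need at least 3 samples")

  keep <- apply(vals, 2, sd) > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d constant (untransformable) feature(s): %s",
                 sum(!keep),
                 paste(head(colnames(vals)[!keep], 5), collapse = ", ")))
    vals <- vals[, keep, drop = FALSE]
  }

  # quantile normalization maps every feature onto the mean sorted profile;
  # it preserves within-feature ranks, so the rank-INT that follows is
  # unaffected by it except through tie structure
  qn <- if (ncol(vals) >= 2) limma::normalizeQuantiles(vals) else vals
  int <- apply(qn, 2, inverse_normal_transform)
  dimnames(int) <- dimnames(qn)

  if (!is.null(covariates)) {
    cv <- as_tibble(covariates)
    if (!is.null(cv$sample_id)) {
      if (!all(rownames(vals) %in% cv$sample_id)) {
        abort("covariate table missing samples present in the matrix")
      }
      cv <- cv[match(rownames(vals), cv$sample_id), ]
      cv$sample_id <- NULL
    }
    X <- cbind(`(Intercept)` = 1, as.matrix(cv))
    if (anyNA(X)) abort("covariates contain missing values")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      abort(sprintf("covariates are rank deficient; collinear column(s): %s",
                    paste(dropped, collapse = ", ")))
    }
    int <- qr.resid(qrX, int)
  } else {
    int <- scale(int, center = TRUE, scale = FALSE)
  }
  feats <- mat$features[match(colnames(vals), mat$features$feature_id), ]
  new_molecular_matrix(feats, int, "normalized")
}

#' Correlate CpG methylation with nearby gene expression
#'
#' Pairs each CpG with every gene whose TSS lies within `window` bp on the
#' same chromosome, computes the correlation on the adjusted normalized
#' values with a two-sided t-test, and adjusts by Benjamini-Hochberg across
#' all pairs.
#'
#' @param meth_adj,expr_adj Normalized `molecular_matrix` objects sharing
#'   samples.
#' @param window Pairing window in bp around the CpG.
#' @param method `"pearson"` (default, the normalization makes Pearson and
#'   Spearman nearly identical) or `"spearman"`.
#' @param fdr FDR level for the significance flag.
#' @return Tibble: cpg_id, gene_id, n_genes (0-pair CpGs are reported with
#'   `gene_id = NA`), r, p, q, significant.
#' @export
correlate_pairs <- function(meth_adj, expr_adj, window = 5e5,
                            method = c("pearson", "spearman"), fdr = 0.05) {
  method <- match.arg(method)
  shared <- intersect(rownames(meth_adj$values), rownames(expr_adj$values))
  if (length(shared) < 10) abort("fewer than 10 shared samples")
  M <- meth_adj$values[shared, , drop = FALSE]
  E <- expr_adj$values[shared, , drop = FALSE]
  n <- length(shared)

  pairs <- meth_adj$features |>
    select(cpg_id = "feature_id", "chrom", cpg_pos = "pos") |>
    inner_join(expr_adj$features |>
                 select(gene_id = "feature_id", "chrom", tss = "pos"),
               by = "chrom", relationship = "many-to-many") |>
    filter(abs(.data$tss - .data$cpg_pos) <= window)

  no_pair <- setdiff(meth_adj$features$feature_id, pairs$cpg_id)
  if (!nrow(pairs)) {
    return(tibble(cpg_id = no_pair, gene_id = NA_character_, r = NA_real_,
                  p = NA_real_, q = NA_real_, significant = FALSE))
  }
  r <- map_dbl(seq_len(nrow(pairs)), function(i)
    cor(M[, pairs$cpg_id[i]], E[, pairs$gene_id[i]], method = method))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- pairs |>
    transmute(.data$cpg_id, .data$gene_id, r = r, p = p,
              q = p.adjust(p, method = "BH")) |>
    mutate(significant = .data$q < fdr)
  if (length(no_pair)) {
    out <- bind_rows(out, tibble(cpg_id = no_pair, gene_id = NA_character_,
                                 r = NA_real_, p = NA_real_, q = NA_real_,
                                 significant = FALSE))
  }
  out
}

#' Association of genetically predicted expression with the trait
#'
#' The identical summary-statistic engine as the methylation scan, applied
#' to gene expression weight models, with Benjamini-Hochberg across the
#' genes tested.
#'
#' @param gene_weights Weight tibble in the same schema as methylation
#'   weights but keyed by gene (`cpg_id` column holds the gene id; the
#'   `feature_id` column name of the output reflects it).
#' @param stats A `gwas_sumstats` tibble.
#' @param ld An [ld_reference()].
#' @param fdr FDR level.
#' @return Association tibble (one row per gene model) with q-values and
#'   significance flags.
#' @export
expression_association <- function(gene_weights, stats, ld, fdr = 0.05) {
  records <- gene_weights |>
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
  records |>
    mutate(significant = !is.na(.data$q) & .data$q <= fdr) |>
    rename(gene_id = "feature_id")
}

#' Sign-consistency of a methylation-expression-risk triad
#'
#' A triad is direction-consistent when the methylation-to-risk log odds
#' ratio has the sign implied by the indirect path:
#' `sign(log or_m) == sign(r) * sign(log or_e)`.
#'
#' @param or_m Odds ratio per SD of predicted methylation.
#' @param r Methylation-expression correlation.
#' @param or_e Odds ratio per SD of predicted expression.
#' @return Logical vector.
#' @export
sign_consistent <- function(or_m, r, or_e) {
  sign(log(or_m)) == sign(r) * sign(log(or_e))
}

#' Triangulate methylation, expression and risk associations
#'
#' Joins the three legs for each CpG-gene pair and issues a verdict:
#' `consistent` when all three legs are significant at their thresholds and
#' the sign rule holds, `inconsistent` when all are significant but the
#' signs disagree, `incomplete` when any leg is missing or non-significant.
#' A CpG modelled in both panels contributes one record per panel.
#'
#' @param cpg_assoc Methylation association records with `significant`
#'   flags (e.g. a [mwas_scan()] result).
#' @param correlations Output of [correlate_pairs()].
#' @param gene_assoc Output of [expression_association()].
#' @return A tibble of class `triangulation`: cpg_id, panel, gene_id,
#'   expr_panel, b_m, or_m, r, b_e, or_e, verdict.
#' @export
triangulate <- function(cpg_assoc, correlations, gene_assoc) {
  ca <- as_tibble(cpg_assoc) |>
    select(cpg_id = "feature_id", "panel", b_m = "effect",
           m_sig = "significant")
  co <- correlations |>
    filter(!is.na(.data$gene_id)) |>
    select("cpg_id", "gene_id", "r", r_sig = "significant")
  ga <- as_tibble(gene_assoc) |>
    select("gene_id", expr_panel = "panel", b_e = "effect",
           e_sig = "significant")
  out <- ca |>
    inner_join(co, by = "cpg_id", relationship = "many-to-many") |>
    left_join(ga, by = "gene_id", relationship = "many-to-many")
  if (anyDuplicated(out[c("cpg_id", "panel", "gene_id", "expr_panel")])) {
    abort("duplicate (cpg, panel, gene, expression panel) keys")
  }
  out <- out |>
    mutate(
      complete = .data$m_sig & .data$r_sig &
        !is.na(.data$e_sig) & .data$e_sig &
        is.finite(.data$b_m) & is.finite(.data$r) & !is.na(.data$b_e),
      verdict = case_when(
        !.data$complete ~ "incomplete",
        sign(.data$b_m) == sign(.data$r) * sign(.data$b_e) ~ "consistent",
        .default = "inconsistent"
      ),
      or_m = exp(.data$b_m), or_e = exp(.data$b_e)
    ) |>
    select("cpg_id", "panel", "gene_id", "expr_panel", "b_m", "or_m",
           "r", "b_e", "or_e", "verdict")
  class(out) <- c("triangulation", class(out))
  out
}

#' Published blood methylation-expression-AD-risk triads
#'
#' A curated table of 52 reported CpG-gene associations for Alzheimer's
#' disease: the odds ratio per SD of genetically predicted methylation, the
#' covariate-adjusted methylation-expression correlation, and the odds ratio
#' per SD of genetically predicted expression, each with its reporting
#' panel. Used to validate the sign-consistency rule against real reported
#' effect directions.
#'
#' @return Tibble: cpg_id, chrom, pos, meth_panel, or_meth, r_meth_expr,
#'   expr_panel, or_expr, gene.
#' @export
read_triad_table <- function() {
  path <- system.file("extdata", "ad_triads.tsv", package = "mwascan",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c"))
}
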