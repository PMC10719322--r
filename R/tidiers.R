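#' Tidy a model registry
#'
#' @param x A `model_registry`.
#' @param ... Unused.
#' @return The per-model summary tibble with QC flags.
#' @method tidy model_registry
#' @export
tidy.model_registry <- function(x, ...) as_tibble(x$summary)

#' One-row summary of a model registry
#'
#' @param x A `model_registry`.
#' @param ... Unused.
#' @return Tibble with per-panel totals and the union CpG count.
#' @method glance model_registry
#' @export
glance.model_registry <- function(x, ...) {
  tibble(
    n_panels = nrow(x$counts),
    n_trained = sum(x$counts$trained),
    n_retained = sum(x$counts$passing_probe_filter),
    n_unique_cpgs = x$union$n_union[1] %||% NA_integer_
  )
}

#' @method tidy weight_panel
#' @export
tidy.weight_panel <- function(x, ...) as_tibble(x$summary)

#' @method glance weight_panel
#' @export
glance.weight_panel <- function(x, ...) {
  tibble(panel = x$config$panel,
         n_attempted = nrow(x$summary),
         n_trained = sum(x$summary$status == "trained"),
         median_cv_r2 = stats::median(x$summary$cv_r2, na.rm = TRUE))
}

#' @method tidy mwas_result
#' @export
tidy.mwas_result <- function(x, ...) as_tibble(x)

#' One-row summary of an association scan
#'
#' @param x An `mwas_result`.
#' @param ... Unused.
#' @return Tibble: tests run, testable, significant and novel counts,
#'   cross-panel concordance, Bonferroni threshold.
#' @method glance mwas_result
#' @export
glance.mwas_result <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_testable = sum(!is.na(x$z)),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_novel = sum(x$novelty == "novel" & x$significant, na.rm = TRUE),
    concordance = attr(x, "concordance"),
    bonferroni = attr(x, "bonferroni")
  )
}

#' @method tidy finemap_result
#' @export
tidy.finemap_result <- function(x, ...) as_tibble(x)

#' @method glance finemap_result
#' @export
glance.finemap_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_blocks = dplyr::n_distinct(x$block_id),
    n_sites = nrow(x),
    n_in_credible = sum(x$in_credible_set),
    prior_p = cfg$prior_p, prior_var = cfg$prior_var,
    max_causal = cfg$max_causal, rho = cfg$rho
  )
}

#' @method tidy triangulation
#' @export
tidy.triangulation <- function(x, ...) as_tibble(x)

#' @method glance triangulation
#' @export
glance.triangulation <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_consistent = sum(x$verdict == "consistent"),
    n_inconsistent = sum(x$verdict == "inconsistent"),
    n_incomplete = sum(x$verdict == "incomplete")
  )
}
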