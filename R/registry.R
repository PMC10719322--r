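#' Build a QC'd model registry from trained panels
#'
#' Applies the two registry filters: cross-validated R2 at least `min_r2`
#' (inclusive), and exclusion of any model containing a variant inside its
#' CpG's probe-binding interval (probe-SNP artifact filter). Per-panel and
#' union counts are tracked by inclusion-exclusion.
#'
#' A model whose CpG has no probe interval on record is retained with a
#' warning: exclusion requires positive evidence of a probe SNP.
#'
#' @param panels A list of `weight_panel` objects (one or more panels).
#' @param probe_intervals Tibble from [read_probe_bed()] (cpg_id, chrom,
#'   start, end; 0-based half-open).
#' @param min_r2 Inclusive cross-validated R2 threshold.
#' @return A `model_registry`: `weights` (long tibble over retained models),
#'   `summary` (per attempted model with status), `counts` (per-panel
#'   trained / passing_r2 / passing_probe_filter), `union` (inclusion-
#'   exclusion accounting over retained CpG sets).
#' @export
build_registry <- function(panels, probe_intervals = NULL, min_r2 = 0.01) {
  if (inherits(panels, "weight_panel")) panels <- list(panels)
  weights <- list_rbind(map(panels, "weights"))
  summary <- list_rbind(map(panels, "summary"))
  if (anyDuplicated(summary[c("panel", "cpg_id")])) {
    abort("duplicate (panel, cpg_id) keys across panels")
  }

  summary <- summary |>
    mutate(pass_r2 = .data$status == "trained" & !is.na(.data$cv_r2) &
             .data$cv_r2 >= min_r2)

  if (!is.null(probe_intervals) && nrow(weights) > 0) {
    probe_hit <- weights |>
      inner_join(probe_intervals, by = c("cpg_id", "chrom")) |>
      filter(.data$variant_pos > .data$start, .data$variant_pos <= .data$end) |>
      distinct(.data$panel, .data$cpg_id) |>
      mutate(probe_snp = TRUE)
    no_interval <- setdiff(unique(weights$cpg_id), probe_intervals$cpg_id)
    if (length(no_interval)) {
      warn(sprintf("%d CpG(s) without probe interval retained unchecked",
                   length(no_interval)))
    }
    summary <- summary |>
      left_join(probe_hit, by = c("panel", "cpg_id")) |>
      mutate(probe_snp = !is.na(.data$probe_snp))
  } else {
    summary$probe_snp <- FALSE
  }
  summary <- summary |>
    mutate(retained = .data$pass_r2 & !.data$probe_snp)

  counts <- summary |>
    summarise(
      trained = sum(.data$status == "trained"),
      rejected = sum(.data$status == "rejected"),
      passing_r2 = sum(.data$pass_r2),
      passing_probe_filter = sum(.data$retained),
      .by = "panel"
    )

  kept <- summary |> filter(.data$retained)
  sets <- split(kept$cpg_id, kept$panel)
  union_tab <- if (length(sets) == 2) {
    union_accounting(sets[[1]], sets[[2]],
                     labels = names(sets))
  } else {
    tibble(n_union = length(unique(kept$cpg_id)))
  }

  retained_weights <- weights |>
    semi_join(kept, by = c("panel", "cpg_id"))

  structure(list(weights = retained_weights, summary = summary,
                 counts = counts, union = union_tab),
            class = "model_registry")
}

#' Inclusion-exclusion accounting for two model panels
#'
#' @param ids_a,ids_b Character vectors of CpG ids retained per panel.
#' @param labels Panel labels (length 2).
#' @return One-row tibble: n_a, n_b, n_shared, n_union, n_a_only, n_b_only.
#' @export
union_accounting <- function(ids_a, ids_b, labels = c("A", "B")) {
  ids_a <- unique(ids_a)
  ids_b <- unique(ids_b)
  n_shared <- length(intersect(ids_a, ids_b))
  tibble(
    panel_a = labels[1], panel_b = labels[2],
    n_a = length(ids_a), n_b = length(ids_b), n_shared = n_shared,
    n_union = length(ids_a) + length(ids_b) - n_shared,
    n_a_only = length(ids_a) - n_shared,
    n_b_only = length(ids_b) - n_shared
  )
}

#' @export
print.model_registry <- function(x, ...) {
  cat("<model_registry>\n")
  print(x$counts)
  if (nrow(x$union)) print(x$union)
  invisible(x)
}
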