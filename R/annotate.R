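#' The closed set of 13 functional categories
#'
#' @return Character vector of the 13 category labels, in precedence order
#'   (highest first) as applied by [annotate_cpgs()].
#' @export
cpg_categories <- function() {
  c("exonic/splicing", "splicing", "exonic", "5'UTR/3'-UTR", "5'-UTR",
    "3'-UTR", "ncRNA_exonic", "intronic", "ncRNA_intronic",
    "upstream/downstream", "upstream", "downstream", "intergenic")
}

# Raw labels contributed by one (cpg, transcript) pair.
transcript_labels <- function(pos, tx, splice_margin) {
  ex <- tx[tx$feature == "exon", ]
  if (!nrow(ex)) return(character())
  span <- c(min(ex$start), max(ex$end))
  if (pos < span[1] || pos > span[2]) return(character())
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  # internal exon edges face introns; proximity to them defines splicing
  edges <- sort(c(ex$start, ex$end))
  internal <- setdiff(edges, span)
  near_edge <- length(internal) > 0 && min(abs(pos - internal)) <= splice_margin
  labs <- character()
  if (tx$coding[1]) {
    utr5 <- tx[tx$feature == "five_prime_UTR", ]
    utr3 <- tx[tx$feature == "three_prime_UTR", ]
    in_utr5 <- nrow(utr5) > 0 && any(pos >= utr5$start & pos <= utr5$end)
    in_utr3 <- nrow(utr3) > 0 && any(pos >= utr3$start & pos <= utr3$end)
    if (in_exon) {
      if (near_edge) labs <- c(labs, "exonic/splicing")
      labs <- c(labs, if (in_utr5) "5'-UTR" else if (in_utr3) "3'-UTR"
                else "exonic")
    } else {
      labs <- c(labs, if (near_edge) "splicing" else "intronic")
    }
  } else {
    labs <- c(labs, if (in_exon) "ncRNA_exonic" else "ncRNA_intronic")
  }
  labs
}

#' Annotate CpG sites into one of 13 functional categories
#'
#' Each CpG receives exactly one label, resolved across all overlapping
#' transcripts by a fixed precedence (highest first): exonic/splicing,
#' splicing, exonic, 5'UTR/3'-UTR (composite when distinct transcripts place
#' the site in a 5'-UTR and a 3'-UTR), 5'-UTR, 3'-UTR, ncRNA_exonic,
#' intronic, ncRNA_intronic, upstream/downstream (composite: within the
#' flank upstream of one gene and downstream of another), upstream,
#' downstream, intergenic. Upstream/downstream are strand-aware and use a
#' `flank` bp neighborhood around the transcript span.
#'
#' @param cpgs Tibble: cpg_id, chrom, pos (1-based).
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param flank Upstream/downstream neighborhood in bp.
#' @param splice_margin Distance (bp) to an internal exon boundary that
#'   counts as splicing-relevant.
#' @return A tibble of class `category_calls`: cpg_id, category, gene.
#' @export
annotate_cpgs <- function(cpgs, genes, flank = 1000, splice_margin = 2) {
  if (is.null(genes) || nrow(genes) == 0) {
    out <- tibble(cpg_id = cpgs$cpg_id, category = "intergenic",
                  gene = NA_character_)
    class(out) <- c("category_calls", class(out))
    return(out)
  }
  tx_split <- split(genes, genes$transcript_id)
  tx_meta <- genes |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              gene_id = .data$gene_id[1], gene_name = .data$gene_name[1],
              span_start = min(.data$start[.data$feature == "exon"]),
              span_end = max(.data$end[.data$feature == "exon"]),
              .by = "transcript_id")

  call_one <- function(chrom, pos) {
    on_chrom <- tx_meta[tx_meta$chrom == chrom, ]
    if (!nrow(on_chrom)) return(c("intergenic", NA_character_))
    labs <- character(); lab_genes <- character()
    up_genes <- character(); down_genes <- character()
    for (i in seq_len(nrow(on_chrom))) {
      tm <- on_chrom[i, ]
      if (pos >= tm$span_start && pos <= tm$span_end) {
        tl <- transcript_labels(pos, tx_split[[tm$transcript_id]],
                                splice_margin)
        labs <- c(labs, tl)
        lab_genes <- c(lab_genes, rep(tm$gene_name, length(tl)))
      } else {
        before <- pos < tm$span_start && tm$span_start - pos <= flank
        after <- pos > tm$span_end && pos - tm$span_end <= flank
        if (tm$strand == "+") {
          if (before) up_genes <- c(up_genes, tm$gene_name)
          if (after) down_genes <- c(down_genes, tm$gene_name)
        } else {
          if (after) up_genes <- c(up_genes, tm$gene_name)
          if (before) down_genes <- c(down_genes, tm$gene_name)
        }
      }
    }
    genes_for <- function(ls) paste(unique(lab_genes[labs %in% ls]),
                                    collapse = ";")
    if ("5'-UTR" %in% labs && "3'-UTR" %in% labs) {
      g <- genes_for(c("5'-UTR", "3'-UTR"))
      labs <- c(labs, "5'UTR/3'-UTR")
      lab_genes <- c(lab_genes, g)
    }
    if ("exonic" %in% labs && "splicing" %in% labs &&
        !("exonic/splicing" %in% labs)) {
      g <- genes_for("exonic")
      labs <- c(labs, "exonic/splicing")
      lab_genes <- c(lab_genes, g)
    }
    if (length(up_genes) && length(down_genes)) {
      labs <- c(labs, "upstream/downstream")
      lab_genes <- c(lab_genes, paste(unique(c(up_genes, down_genes)),
                                      collapse = ";"))
    } else if (length(up_genes)) {
      labs <- c(labs, "upstream")
      lab_genes <- c(lab_genes, paste(unique(up_genes), collapse = ";"))
    } else if (length(down_genes)) {
      labs <- c(labs, "downstream")
      lab_genes <- c(lab_genes, paste(unique(down_genes), collapse = ";"))
    }
    if (!length(labs)) {
      near <- which.min(pmax(on_chrom$span_start - pos,
                             pos - on_chrom$span_end, 0))
      return(c("intergenic", on_chrom$gene_name[near]))
    }
    best <- cpg_categories()[min(match(labs, cpg_categories()))]
    c(best, paste(unique(lab_genes[labs == best]), collapse = ";"))
  }

  calls <- vapply(seq_len(nrow(cpgs)),
                  function(i) call_one(cpgs$chrom[i], cpgs$pos[i]),
                  character(2))
  out <- tibble(cpg_id = cpgs$cpg_id, category = calls[1, ],
                gene = dplyr::na_if(calls[2, ], "NA"))
  class(out) <- c("category_calls", class(out))
  out
}

#' Two-proportion Pearson chi-square (no continuity correction)
#'
#' @param x1,n1 Count and total in the first group.
#' @param x2,n2 Count and total in the second group.
#' @return One-row tibble: chi2, p (two-sided, 1 df).
#' @export
proportion_chisq <- function(x1, n1, x2, n2) {
  pt <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  tibble(chi2 = unname(pt$statistic), p = pt$p.value)
}

#' Category enrichment of associated CpG sites
#'
#' Compares, per functional category, the proportion among associated CpG
#' sites against the comparison set with a two-proportion Pearson chi-square
#' (no continuity correction, two-sided, 1 df). The default comparison set
#' is ALL tested CpGs (the associated set is a subset of it); an
#' associated-vs-complement mode is available.
#'
#' @param assoc_calls `category_calls` for the associated CpGs.
#' @param all_calls `category_calls` for all tested CpGs.
#' @param mode `"all"` (associated vs all tested) or `"complement"`.
#' @return A tibble of class `enrichment_result`: category, count_assoc,
#'   total_assoc, count_all, total_all, proportion_assoc, proportion_all,
#'   chi2, p, note.
#' @export
category_enrichment <- function(assoc_calls, all_calls,
                                mode = c("all", "complement")) {
  mode <- match.arg(mode)
  if (!all(assoc_calls$cpg_id %in% all_calls$cpg_id)) {
    abort("associated CpGs must be a subset of all tested CpGs")
  }
  ref <- if (mode == "complement") {
    all_calls |> filter(!(.data$cpg_id %in% assoc_calls$cpg_id))
  } else {
    all_calls
  }
  n1 <- nrow(assoc_calls)
  n2 <- nrow(ref)
  out <- map(cpg_categories(), function(cat) {
    x1 <- sum(assoc_calls$category == cat)
    x2 <- sum(ref$category == cat)
    row <- tibble(category = cat, count_assoc = x1, total_assoc = n1,
                  count_all = x2, total_all = n2,
                  proportion_assoc = x1 / n1, proportion_all = x2 / n2,
                  chi2 = NA_real_, p = NA_real_, note = NA_character_)
    pooled <- (x1 + x2) / (n1 + n2)
    expected <- c(n1 * pooled, n1 * (1 - pooled),
                  n2 * pooled, n2 * (1 - pooled))
    if (any(expected == 0)) {
      row$note <- "zero expected cell; test skipped"
      return(row)
    }
    ct <- proportion_chisq(x1, n1, x2, n2)
    row$chi2 <- ct$chi2
    row$p <- ct$p
    row
  }) |>
    list_rbind()
  class(out) <- c("enrichment_result", class(out))
  out
}
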