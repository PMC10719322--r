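#' Write a complete synthetic fixture bundle to disk
#'
#' Runs the full generative model for `config` and writes every input the
#' downstream pipeline consumes: genotypes (VCF 4.2 with GT), methylation and
#' expression matrices (TSV, features in rows), CpG probe intervals (BED,
#' 0-based half-open, probe = CpG position +/- 24 bp), gene models (GFF3),
#' GWAS summary statistics (TSV), LD-block definitions (BED) and the
#' generative truth table (TSV). A `manifest.tsv` listing each file with its
#' MD5 checksum and the master seed is written alongside.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble (file, type, n_records, md5).
#' @export
write_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory: %s", out_dir))
  }
  geno <- simulate_genotypes(config)
  sim <- simulate_methylation_expression(geno, config)
  stats <- simulate_gwas(geno, config, sim$truth)

  paths <- c(
    genotypes = file.path(out_dir, "genotypes.vcf"),
    methylation = file.path(out_dir, "methylation.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    probes = file.path(out_dir, "cpg_probes.bed"),
    genes = file.path(out_dir, "genes.gff3"),
    sumstats = file.path(out_dir, "sumstats.tsv"),
    ld_blocks = file.path(out_dir, "ld_blocks.bed"),
    truth = file.path(out_dir, "truth.tsv")
  )

  write_vcf(geno, paths[["genotypes"]])
  write_molecular_tsv(sim$meth, paths[["methylation"]])
  write_molecular_tsv(sim$expr, paths[["expression"]])

  probes <- sim$meth$features |>
    transmute(chrom = .data$chrom, start = .data$pos - 25L,
              end = .data$pos + 24L, name = .data$feature_id)
  readr::write_tsv(probes, paths[["probes"]], col_names = FALSE)

  write_gene_gff3(sim$expr$features, paths[["genes"]])
  readr::write_tsv(as_tibble(stats), paths[["sumstats"]])

  blk <- geno$variants |>
    mutate(block = (dplyr::row_number() - 1) %/% config$block_size) |>
    summarise(first = min(.data$pos), last = max(.data$pos), .by = "block")
  half <- floor(config$snp_spacing / 2)
  ld_blocks <- blk |>
    transmute(chrom = "1",
              start = ifelse(.data$block == 0, 0L, .data$first - half - 1L),
              end = .data$last + half,
              name = sprintf("block_%03d", .data$block + 1))
  readr::write_tsv(ld_blocks, paths[["ld_blocks"]], col_names = FALSE)

  truth_long <- bind_rows(
    sim$truth$cpg_effects |>
      transmute(record_type = "cpg_effect", cpg_id = .data$cpg_id,
                gene_id = NA_character_, variant_id = .data$variant_id,
                value = .data$effect),
    sim$truth$cpg_baseline |>
      transmute(record_type = "cpg_baseline", cpg_id = .data$cpg_id,
                gene_id = NA_character_, variant_id = NA_character_,
                value = .data$b0),
    sim$truth$mediation |>
      transmute(record_type = "mediation", cpg_id = .data$cpg_id,
                gene_id = .data$gene_id, variant_id = NA_character_,
                value = .data$beta),
    sim$truth$liability |>
      transmute(record_type = "liability", cpg_id = .data$cpg_id,
                gene_id = NA_character_, variant_id = NA_character_,
                value = .data$effect)
  )
  readr::write_tsv(truth_long, paths[["truth"]])

  n_records <- c(nrow(geno$variants), ncol(sim$meth$values),
                 ncol(sim$expr$values), nrow(probes),
                 nrow(sim$expr$features), nrow(stats), nrow(ld_blocks),
                 nrow(truth_long))
  manifest <- tibble(
    file = basename(paths), type = names(paths), n_records = n_records,
    md5 = unname(tools::md5sum(paths)), seed = config$seed
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

write_vcf <- function(geno, path) {
  gt <- c("0/0", "0/1", "1/1")[geno$dosage + 1L]
  dim(gt) <- dim(geno$dosage)
  body <- apply(gt, 2, paste, collapse = "\t")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##contig=<ID=%s>", unique(geno$variants$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
            geno$variants$chrom, geno$variants$pos, geno$variants$variant_id,
            geno$variants$ref, geno$variants$alt, body)
  )
  writeLines(lines, path)
}

write_molecular_tsv <- function(mat, path) {
  meta <- mat$features
  vals <- t(mat$values)
  df <- bind_cols(meta, as_tibble(vals, .name_repair = "minimal"))
  readr::write_tsv(df, path)
}

write_gene_gff3 <- function(gene_features, path) {
  rows <- imap(seq_len(nrow(gene_features)), function(i, ...) {
    g <- gene_features[i, ]
    tss <- g$pos
    coding <- (i %% 5) != 0   # every fifth gene is a non-coding RNA
    gid <- g$feature_id
    tid <- paste0(g$feature_id, ".t1")
    ttype <- if (coding) "mRNA" else "ncRNA"
    span_end <- tss + 4999L
    feats <- c(
      sprintf("1\tmwascan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
              tss, span_end, g$strand, gid, toupper(gid),
              if (coding) "protein_coding" else "ncRNA"),
      sprintf("1\tmwascan\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              ttype, tss, span_end, g$strand, tid, gid),
      sprintf("1\tmwascan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              tss, tss + 999L, g$strand, tid),
      sprintf("1\tmwascan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              tss + 3000L, span_end, g$strand, tid)
    )
    if (coding) {
      feats <- c(feats,
        sprintf("1\tmwascan\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
                tss, tss + 199L, g$strand, tid),
        sprintf("1\tmwascan\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
                tss + 4500L, span_end, g$strand, tid))
    }
    feats
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
}

#' Read genotypes from a VCF into a genotype matrix
#'
#' Parses GT fields into alternate-allele dosages. Only biallelic records are
#' supported.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A `genotype_matrix`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fix <- as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  variants <- tibble(
    variant_id = fix$ID, chrom = as.character(fix$CHROM),
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    maf = rowMeans(dos) / 2
  )
  new_genotype_matrix(variants, t(dos), colnames(gt))
}

#' Read a molecular matrix TSV (features in rows, samples in columns)
#'
#' @param path Path to the TSV written by [write_fixture_bundle()].
#' @param kind One of `"methylation-beta"`, `"normalized"`, `"expression"`.
#' @return A `molecular_matrix`.
#' @export
read_molecular_tsv <- function(path, kind = "methylation-beta") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- intersect(c("feature_id", "chrom", "pos", "strand"), names(df))
  meta <- df[meta_cols]
  vals <- t(as.matrix(df[setdiff(names(df), meta_cols)]))
  colnames(vals) <- meta$feature_id
  new_molecular_matrix(as_tibble(meta), vals, kind)
}

#' Read CpG probe intervals from BED (0-based half-open)
#'
#' The CpG position is taken as the interval midpoint (probe = position
#' +/- 24 bp convention).
#'
#' @param path Path to a 4-column BED file.
#' @return Tibble: cpg_id, chrom, start, end, pos (1-based CpG position).
#' @export
read_probe_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                        show_col_types = FALSE)
  df |>
    transmute(cpg_id = .data$name, chrom = as.character(.data$chrom),
              start = .data$start, end = .data$end,
              pos = .data$start + 25L)
}

#' Read LD-block definitions from BED (0-based half-open)
#'
#' @param path Path to a BED file (chrom, start, end, optional name).
#' @return Tibble: block_id, chrom, start, end.
#' @export
read_ld_blocks <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  block_id <- if (ncol(df) >= 4) as.character(df[[4]]) else
    sprintf("block_%03d", seq_len(nrow(df)))
  tibble(block_id = block_id, chrom = as.character(df$chrom),
         start = df$start, end = df$end)
}

#' Read gene models from GFF3
#'
#' Returns one row per transcript feature (exon and UTRs), with a per
#' transcript coding flag (`mRNA`/presence of UTRs = coding; other transcript
#' types = non-coding RNA). Coordinates are 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble: gene_id, gene_name, transcript_id, chrom, strand, coding,
#'   feature, start, end.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  tx_types <- c("mRNA", "ncRNA", "transcript", "lnc_RNA", "miRNA", "snoRNA")
  tx <- df |>
    filter(.data$type %in% tx_types) |>
    transmute(transcript_id = .data$ID, gene_id = .data$Parent,
              tx_strand = as.character(.data$strand),
              coding = .data$type == "mRNA")
  genes <- df |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$ID,
              gene_name = if ("Name" %in% names(df)) .data$Name else .data$ID)
  feats <- df |>
    filter(.data$type %in% c("exon", "five_prime_UTR", "three_prime_UTR")) |>
    transmute(transcript_id = .data$Parent, chrom = as.character(.data$seqnames),
              feature = as.character(.data$type),
              start = .data$start, end = .data$end)
  feats |>
    inner_join(tx, by = "transcript_id") |>
    inner_join(genes, by = "gene_id") |>
    transmute(.data$gene_id, .data$gene_name, .data$transcript_id,
              .data$chrom, strand = .data$tx_strand, .data$coding,
              .data$feature, .data$start, .data$end)
}

#' Read GWAS summary statistics TSV
#'
#' Expects the columns variant_id, chrom, pos, effect_allele, other_allele,
#' eaf, beta, se, p, n_cases, n_controls.
#'
#' @param path Path to a TSV file.
#' @return A tibble of class `gwas_sumstats`.
#' @export
read_sumstats <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(chrom = "c"))
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n_cases", "n_controls")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("sumstats file missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- df[need]
  class(out) <- c("gwas_sumstats", class(out))
  out
}

#' Read the generative truth table written by [write_fixture_bundle()]
#'
#' @param path Path to truth.tsv.
#' @return A list of tibbles: cpg_effects, cpg_baseline, mediation, liability.
#' @export
read_truth_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  list(
    cpg_effects = df |> filter(.data$record_type == "cpg_effect") |>
      transmute(.data$cpg_id, .data$variant_id, effect = .data$value),
    cpg_baseline = df |> filter(.data$record_type == "cpg_baseline") |>
      transmute(.data$cpg_id, b0 = .data$value),
    mediation = df |> filter(.data$record_type == "mediation") |>
      transmute(.data$gene_id, .data$cpg_id, beta = .data$value),
    liability = df |> filter(.data$record_type == "liability") |>
      transmute(.data$cpg_id, effect = .data$value)
  )
}
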