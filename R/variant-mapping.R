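#' Effect of a single SNP allele on a protein, through one gene model
#'
#' The CDS coordinate of the SNP is computed strand-aware; for minus-strand
#' genes the alternative base is complemented before codon substitution. The
#' reference base is checked against the CDS.
#'
#' @param model A [gene_model()].
#' @param cds_sequence Spliced, strand-oriented CDS (as from
#'   [spliced_cds()]).
#' @param snp One-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`, `accessions`.
#' @return One-row data.frame describing the protein effect, or `NULL` when
#'   the SNP is non-coding for this model.
#' @export
snp_protein_effect <- function(model, cds_sequence, snp) {
  if (snp$chrom != model$chrom) return(NULL)
  cds_pos <- genomic_to_cds(model, snp$pos)
  if (is.na(cds_pos)) return(NULL)
  if (nchar(cds_sequence) != model$cds_length) {
    stop("gene ", model$gene_id, ": CDS sequence length ",
         nchar(cds_sequence), " does not match model (", model$cds_length,
         ")", call. = FALSE)
  }
  ref_cds <- if (model$strand == "-") complement_base(snp$ref) else toupper(snp$ref)
  alt_cds <- if (model$strand == "-") complement_base(snp$alt) else toupper(snp$alt)
  have <- substring(cds_sequence, cds_pos, cds_pos)
  if (have != ref_cds) {
    stop("reference allele mismatch for SNP ", snp$chrom, ":", snp$pos,
         " ", snp$ref, ">", snp$alt, " in gene ", model$gene_id,
         " (CDS has ", have, ")", call. = FALSE)
  }
  codon_idx <- (cds_pos + 2L) %/% 3L
  within <- cds_pos - 3L * (codon_idx - 1L)
  ref_codon <- substring(cds_sequence, 3L * codon_idx - 2L, 3L * codon_idx)
  alt_codon <- ref_codon
  substring(alt_codon, within, within) <- alt_cds
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  data.frame(
    protein_id = model$protein_id, gene_id = model$gene_id,
    protein_pos = codon_idx, ref_aa = ref_aa, alt_aa = alt_aa,
    effect_class = classify_aa_change(ref_aa, alt_aa),
    chrom = snp$chrom, pos = snp$pos, ref = toupper(snp$ref),
    alt = toupper(snp$alt), accessions = snp$accessions,
    cds_pos = cds_pos, stringsAsFactors = FALSE)
}

#' Map a SNP table onto a set of gene models
#'
#' Every SNP allele is evaluated against every gene model whose exons
#' contain its position (a SNP inside two overlapping genes yields one
#' effect per model). Effects are computed per alternative allele against
#' the reference CDS; SNPs sharing a codon are applied independently.
#'
#' @param snps SNP data.frame (from [read_snp_table()] or
#'   [read_snp_vcf()]).
#' @param models Named list of [gene_model()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @return data.frame of protein effects, one row per (SNP allele, model)
#'   pair; zero rows when nothing is coding.
#' @export
map_snp_effects <- function(snps, models, genome) {
  empty <- data.frame(
    protein_id = character(0), gene_id = character(0),
    protein_pos = integer(0), ref_aa = character(0), alt_aa = character(0),
    effect_class = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), accessions = character(0),
    cds_pos = integer(0), stringsAsFactors = FALSE)
  if (nrow(snps) == 0L || length(models) == 0L) return(empty)
  exon_tab <- do.call(rbind, lapply(seq_along(models), function(i) {
    m <- models[[i]]
    data.frame(chrom = m$chrom, start = m$exons[, 1L], end = m$exons[, 2L],
               model = i, stringsAsFactors = FALSE)
  }))
  cds_cache <- lapply(models, spliced_cds, genome = genome)
  out <- vector("list", 0L)
  for (chr in unique(snps$chrom)) {
    s_idx <- which(snps$chrom == chr)
    e_sub <- exon_tab[exon_tab$chrom == chr, , drop = FALSE]
    if (nrow(e_sub) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(snps$pos[s_idx], width = 1L),
      IRanges::IRanges(e_sub$start, e_sub$end))
    if (length(hits) == 0L) next
    for (h in seq_along(hits)) {
      si <- s_idx[S4Vectors::queryHits(hits)[h]]
      mi <- e_sub$model[S4Vectors::subjectHits(hits)[h]]
      eff <- snp_protein_effect(models[[mi]], cds_cache[[mi]], snps[si, ])
      if (!is.null(eff)) out[[length(out) + 1L]] <- eff
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize proteome-wide SNP effects
#'
#' Counts affected amino acid positions (distinct (protein, position) pairs,
#' regardless of how many alleles or accessions hit them), affected stop
#' codons, synonymous and non-synonymous substitution events, and
#' percentages of the total residue count. Percentages are
#' `100 * count / total_aa`, reported to two decimals (round-half-to-even).
#'
#' @param effects Effects data.frame from [map_snp_effects()].
#' @param proteome Named character vector of protein sequences (no stop
#'   symbols; the terminal stop codon is bookkept separately).
#' @return Object of class `effect_summary`.
#' @export
summarize_effects <- function(effects, proteome) {
  if (length(proteome) == 0L) stop("empty proteome", call. = FALSE)
  total_aa <- sum(nchar(proteome))
  is_stop_ref <- effects$ref_aa == "*"
  key <- paste(effects$protein_id, effects$protein_pos)
  affected_aa <- length(unique(key[!is_stop_ref]))
  affected_stop <- length(unique(key[is_stop_ref]))
  syn_count <- sum(effects$effect_class == "synonymous" & !is_stop_ref)
  nonsyn_count <- sum(effects$effect_class == "nonsynonymous")
  aa_sub <- table(effects$ref_aa[effects$effect_class == "nonsynonymous"])
  structure(list(
    total_aa = total_aa,
    affected_aa = affected_aa,
    affected_stop = affected_stop,
    syn_count = syn_count,
    nonsyn_count = nonsyn_count,
    stop_gained = sum(effects$effect_class == "stop_gained"),
    stop_lost = sum(effects$effect_class == "stop_lost"),
    per_aa_nonsyn = aa_sub,
    pct_affected_aa = effect_percentage(affected_aa, total_aa),
    pct_syn = effect_percentage(syn_count, total_aa),
    pct_nonsyn = effect_percentage(nonsyn_count, total_aa)),
    class = "effect_summary")
}

#' Percentage of a count relative to the proteome size
#'
#' @param count Numerator count.
#' @param total_aa Total number of amino acid residues.
#' @return `100 * count / total_aa` rounded to two decimals
#'   (round-half-to-even).
#' @export
#' @examples
#' effect_percentage(314705, 12285899)  # 2.56
effect_percentage <- function(count, total_aa) {
  if (total_aa <= 0) stop("total_aa must be positive", call. = FALSE)
  round(100 * count / total_aa, 2L)
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("SNP effect summary\n")
  cat(sprintf("  residues in proteome : %d\n", x$total_aa))
  cat(sprintf("  affected amino acids : %d (%.2f%%)\n", x$affected_aa,
              x$pct_affected_aa))
  cat(sprintf("  affected stop codons : %d\n", x$affected_stop))
  cat(sprintf("  synonymous events    : %d (%.2f%%)\n", x$syn_count, x$pct_syn))
  cat(sprintf("  non-synonymous events: %d (%.2f%%)\n", x$nonsyn_count,
              x$pct_nonsyn))
  invisible(x)
}

#' Per-amino-acid substitution odds relative to proteome abundance
#'
#' For each amino acid `a`, builds the 2x2 table
#' `[[nonsyn_from_a, nonsyn_total - nonsyn_from_a], [count_a, total_aa -
#' count_a]]` and reports the log2 odds ratio (positive when `a` is
#' substituted more often than its abundance predicts), a Fisher exact
#' p-value and Benjamini-Hochberg q-value across the 20 amino acids. Tables
#' with a zero cell get the Haldane-Anscombe 0.5 correction and are flagged.
#'
#' @param effects Effects data.frame from [map_snp_effects()].
#' @param proteome Named character vector of protein sequences.
#' @return data.frame with one row per amino acid present in the proteome.
#' @export
aa_abundance_odds <- function(effects, proteome) {
  ns <- effects[effects$effect_class == "nonsynonymous", , drop = FALSE]
  if (nrow(ns) == 0L) stop("no nonsynonymous effects", call. = FALSE)
  counts <- aa_counts(proteome)
  total_aa <- sum(counts)
  nonsyn_total <- nrow(ns)
  from <- table(factor(ns$ref_aa, levels = names(counts)))
  rows <- lapply(names(counts), function(a) {
    n11 <- as.integer(from[[a]])
    n12 <- nonsyn_total - n11
    n21 <- as.integer(counts[[a]])
    n22 <- total_aa - n21
    tab <- matrix(c(n11, n12, n21, n22), 2L, byrow = TRUE)
    corrected <- any(tab == 0L)
    tc <- if (corrected) tab + 0.5 else tab
    or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
    ft <- fisher_exact(tab)
    data.frame(aa = a, nonsyn = n11, abundance = n21,
               log2_or = log2(or), p = ft$p, corrected = corrected,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res
}

# amino acid counts over a proteome (20-letter alphabet)
aa_counts <- function(proteome) {
  tab <- table(factor(strsplit(paste(proteome, collapse = ""), "")[[1]],
                      levels = setdiff(AA_SYMBOLS, "*")))
  tab[tab > 0]
}
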