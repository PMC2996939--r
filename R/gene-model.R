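#' Construct a gene model
#'
#' A gene model links a protein to its ordered coding exon blocks on the
#' genome. Exons are 1-based inclusive genomic intervals, stored sorted by
#' genomic coordinate; for minus-strand genes the first coding base is the
#' rightmost exon base.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of coding exon blocks.
#' @param protein_id Identifier of the encoded protein (defaults to
#'   `gene_id`).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, protein_id = gene_id) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("gene ", gene_id, ": exon end before start", call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("gene ", gene_id, ": overlapping exons", call. = FALSE)
  }
  len <- sum(exons[, 2L] - exons[, 1L] + 1L)
  if (len %% 3L != 0L) {
    stop("gene ", gene_id, ": total exon length ", len,
         " not divisible by 3", call. = FALSE)
  }
  structure(list(gene_id = gene_id, protein_id = protein_id, chrom = chrom,
                 strand = strand, exons = exons, cds_length = len),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene_id, "on", x$chrom, x$strand,
      sprintf("(%d exon(s), CDS %d nt)\n", nrow(x$exons), x$cds_length))
  invisible(x)
}

#' Extract the spliced, strand-oriented CDS of a gene model
#'
#' @param model A [gene_model()].
#' @param genome Named character vector of chromosome sequences.
#' @return CDS nucleotide string in transcript orientation (includes the
#'   terminal stop codon when the model covers it).
#' @export
spliced_cds <- function(model, genome) {
  chrom <- genome[[model$chrom]]
  pieces <- substring(chrom, model$exons[, 1L], model$exons[, 2L])
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Map a genomic position to a 1-based CDS coordinate
#'
#' @param model A [gene_model()].
#' @param gpos Genomic position(s), 1-based.
#' @return Integer CDS position(s); `NA` when the position falls in an
#'   intron or outside the gene ("non-coding").
#' @export
#' @examples
#' m <- gene_model("g", "chr1", "+", rbind(c(101, 150), c(201, 250)))
#' genomic_to_cds(m, 220)  # 70
genomic_to_cds <- function(model, gpos) {
  gpos <- as.integer(gpos)
  exons <- model$exons
  offsets <- c(0L, cumsum(exons[, 2L] - exons[, 1L] + 1L))
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(exons))) {
    inside <- !is.na(gpos) & gpos >= exons[i, 1L] & gpos <= exons[i, 2L]
    out[inside] <- offsets[i] + (gpos[inside] - exons[i, 1L] + 1L)
  }
  if (model$strand == "-") out <- model$cds_length - out + 1L
  out
}

#' Map a 1-based CDS coordinate back to the genome
#'
#' Inverse of [genomic_to_cds()] on exon bases.
#'
#' @param model A [gene_model()].
#' @param cds_pos CDS position(s) in 1..cds_length.
#' @return Genomic position(s).
#' @export
cds_to_genomic <- function(model, cds_pos) {
  if (any(cds_pos < 1L | cds_pos > model$cds_length)) {
    stop("CDS position out of range for gene ", model$gene_id, call. = FALSE)
  }
  p <- if (model$strand == "-") model$cds_length - cds_pos + 1L else cds_pos
  exons <- model$exons
  offsets <- c(0L, cumsum(exons[, 2L] - exons[, 1L] + 1L))
  idx <- findInterval(p, offsets, left.open = TRUE)
  as.integer(exons[idx, 1L] + (p - offsets[idx] - 1L))
}

#' Read gene models from a GFF3 subset
#'
#' Only CDS features are used; they are grouped by their `Parent` attribute
#' into one model per transcript. Each model's exon blocks, strand and
#' chromosome come straight from the file.
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model()] objects keyed by transcript id.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::readGFF(path, filter = list(type = "CDS"))
  parents <- vapply(g$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  keep <- !is.na(parents)
  g <- g[keep, , drop = FALSE]
  parents <- parents[keep]
  models <- list()
  for (tx in unique(parents)) {
    rows <- which(parents == tx)
    models[[tx]] <- gene_model(
      gene_id = tx,
      chrom = as.character(g$seqid[rows[1L]]),
      strand = as.character(g$strand[rows[1L]]),
      exons = cbind(g$start[rows], g$end[rows]),
      protein_id = tx)
  }
  models
}

#' Write gene models as GFF3
#'
#' Emits one `gene` line and its `CDS` blocks per model, enough to round-trip
#' through [read_gene_models()].
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- range(m$exons)
    writeLines(sprintf("%s\tphosnp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chrom, span[1L], span[2L], m$strand, m$gene_id), con)
    # frame of each CDS block relative to translation start
    exons <- m$exons
    n <- nrow(exons)
    lens <- exons[, 2L] - exons[, 1L] + 1L
    tx_order <- if (m$strand == "+") seq_len(n) else rev(seq_len(n))
    before <- c(0L, cumsum(lens[tx_order]))[seq_len(n)]
    phase <- (3L - before %% 3L) %% 3L
    for (k in seq_len(n)) {
      i <- tx_order[k]
      writeLines(sprintf("%s\tphosnp\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
                         m$chrom, exons[i, 1L], exons[i, 2L], m$strand,
                         phase[k], m$gene_id, k, m$gene_id), con)
    }
  }
  invisible(path)
}
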