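#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file. Record ids are the first whitespace-delimited token
#'   of each header.
#' @param type `"AA"` or `"DNA"`; controls the alphabet used by the underlying
#'   Biostrings reader.
#' @return Named character vector id -> sequence. An empty file yields an
#'   empty vector with a warning.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (sequence before header) at line 1 of ", path,
         call. = FALSE)
  }
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector id -> sequence.
#' @param path Output file.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(c(paste0(">", id), substring(s, starts, starts + width - 1L)), con)
  }
  invisible(path)
}

# ---- typed tables ----------------------------------------------------------

TABLE_SCHEMAS <- list(
  snps    = c("chrom", "pos", "ref", "alt", "accessions"),
  sites   = c("protein_id", "position", "residue", "status", "score"),
  domains = c("protein_id", "start", "end", "domain_id"),
  terms   = c("protein_id", "term_id")
)

read_tsv_schema <- function(path, schema) {
  required <- TABLE_SCHEMAS[[schema]]
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema '", schema, "': missing required column(s) ",
         paste(missing, collapse = ", "), " in ", path, call. = FALSE)
  }
  df[required]
}

reject_rows <- function(df, bad, what) {
  if (any(bad)) {
    warning(sum(bad), " ", what, " row(s) rejected (rows ",
            paste(utils::head(which(bad), 10L), collapse = ", "), ")",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Read a SNP table (TSV)
#'
#' Columns: chrom, pos, ref, alt, accessions (comma-separated accession
#' names). Rows violating the record invariants (single-base ref/alt,
#' ref != alt, non-empty accession set) are dropped with a warning.
#'
#' @param path TSV file.
#' @return data.frame with one row per (chrom, pos, alt) allele; `accessions`
#'   is a comma-separated string.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_schema(path, "snps")
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  alts <- strsplit(df$alt, ",")
  valid_alt <- mapply(function(a, r) any(a %in% DNA_BASES & a != r),
                      alts, df$ref)
  bad <- !(df$ref %in% DNA_BASES) | is.na(df$pos) | df$pos < 1L |
    is.na(df$accessions) | df$accessions == "" | !valid_alt
  df <- reject_rows(df, bad, "SNP")
  split_multiallelic(df)
}

# one SnpRecord per alt allele
split_multiallelic <- function(df) {
  alts <- strsplit(df$alt, ",")
  n <- lengths(alts)
  out <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
  out$alt <- unlist(alts)
  rownames(out) <- NULL
  keep_attr <- attr(df, "n_rejected")
  out <- out[out$alt != out$ref & out$alt %in% DNA_BASES, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- keep_attr
  out
}

#' Read a phosphosite table (TSV)
#'
#' Columns: protein_id, position, residue (S/T/Y), status
#' (experimental/predicted), score (decision value; required for predicted
#' sites, may be NA for experimental ones). When `proteome` is supplied,
#' rows whose residue does not match the protein sequence at that position
#' are rejected with a warning listing the offending rows.
#'
#' @param path TSV file.
#' @param proteome Optional named character vector of protein sequences.
#' @return data.frame of validated sites.
#' @export
read_site_table <- function(path, proteome = NULL) {
  df <- read_tsv_schema(path, "sites")
  df$position <- as.integer(df$position)
  df$residue <- toupper(df$residue)
  df$score <- suppressWarnings(as.numeric(df$score))
  bad <- is.na(df$position) | df$position < 1L |
    !(df$residue %in% c("S", "T", "Y")) |
    !(df$status %in% c("experimental", "predicted")) |
    (df$status == "predicted" & is.na(df$score))
  if (!is.null(proteome)) {
    obs <- protein_letter(proteome, df$protein_id, df$position)
    bad <- bad | is.na(obs) | obs != df$residue
  }
  reject_rows(df, bad, "phosphosite")
}

# letter of protein `id` at 1-based `pos`; NA when out of range or unknown id
protein_letter <- function(proteome, id, pos) {
  seqs <- unname(proteome[id])
  out <- rep(NA_character_, length(id))
  ok <- !is.na(seqs) & !is.na(pos) & pos >= 1L & pos <= nchar(seqs)
  out[ok] <- substring(seqs[ok], pos[ok], pos[ok])
  out
}

#' Read a protein-domain table (TSV)
#'
#' Columns: protein_id, start, end, domain_id (1-based inclusive protein
#' coordinates). With a proteome supplied, intervals outside the protein are
#' rejected.
#'
#' @param path TSV file.
#' @param proteome Optional named character vector of protein sequences.
#' @return data.frame of validated domain annotations.
#' @export
read_domain_table <- function(path, proteome = NULL) {
  df <- read_tsv_schema(path, "domains")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- is.na(df$start) | is.na(df$end) | df$start < 1L | df$start > df$end
  if (!is.null(proteome)) {
    len <- nchar(proteome[df$protein_id])
    bad <- bad | is.na(len) | df$end > len
  }
  reject_rows(df, bad, "domain")
}

#' Read a term-annotation table (TSV)
#'
#' Columns: protein_id, term_id.
#'
#' @param path TSV file.
#' @return data.frame of annotations.
#' @export
read_term_table <- function(path) {
  df <- read_tsv_schema(path, "terms")
  bad <- is.na(df$protein_id) | df$protein_id == "" |
    is.na(df$term_id) | df$term_id == ""
  reject_rows(df, bad, "term annotation")
}

#' Read SNPs from a minimal VCF dialect
#'
#' Accepts plain-text VCF with CHROM/POS/ID/REF/ALT columns and per-accession
#' genotype columns; an accession carries the k-th alternative allele when its
#' genotype contains allele index k. Multi-allelic lines are split into one
#' record per alternative allele. No INFO parsing beyond the alleles.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return data.frame in the same shape as [read_snp_table()].
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",")[[1]]
    for (k in seq_along(alts)) {
      if (nchar(alts[k]) != 1L || nchar(ref) != 1L || alts[k] == ref) next
      carriers <- colnames(gt)[vapply(gt[i, ], function(g) {
        !is.na(g) && any(strsplit(g, "[/|]")[[1]] == as.character(k))
      }, TRUE)]
      if (length(carriers) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alts[k],
        accessions = paste(carriers, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      accessions = character(0)))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a packaged reference table
#'
#' Two verbatim transcriptions of published summary tables ship with the
#' package: `"table1"`, the 31 proteins with nine or more experimentally
#' identified phosphorylation sites (columns: protein_id, n_sites, n_ps,
#' n_pt, n_py, length, go6139 flag, hotspot flag), and `"table2"`, the 29
#' proteins carrying 43 significant phosphosite windows at window size 10
#' (columns: protein_id, n_windows, windows as "count(start)" descriptors).
#'
#' @param name `"table1"` or `"table2"`.
#' @return data.frame.
#' @export
#' @examples
#' nrow(load_fixture("table1"))  # 31
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  file <- switch(name,
    table1 = "table1_multisite_proteins.tsv",
    table2 = "table2_hotspots_win10.tsv")
  path <- system.file("extdata", file, package = "phosnp", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (name == "table1") {
    df$go6139 <- as.logical(df$go6139)
    df$hotspot <- as.logical(df$hotspot)
  }
  df
}

#' Parse "count(start)" hotspot window descriptors
#'
#' @param x Character vector of comma-separated descriptors such as
#'   `"5(6), 6(4)"`.
#' @return data.frame with columns `count` and `start`, one row per window.
#' @export
parse_window_descriptors <- function(x) {
  parts <- unlist(strsplit(x, ",\\s*"))
  m <- regmatches(parts, regexec("^(\\d+)\\((\\d+)\\)$", parts))
  ok <- lengths(m) == 3L
  if (!all(ok)) stop("malformed window descriptor: ", parts[!ok][1], call. = FALSE)
  data.frame(count = as.integer(vapply(m, `[`, "", 2L)),
             start = as.integer(vapply(m, `[`, "", 3L)))
}
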