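# 20 amino acids + stop, the alphabet used throughout.
AA_SYMBOLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "*")

DNA_BASES <- c("A", "C", "G", "T")

#' All 64 codons of the standard nuclear genetic code
#'
#' Named character vector mapping codon -> amino acid one-letter symbol,
#' with `"*"` for the three stop codons. Taken from the standard code as
#' shipped with Biostrings.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[["ATG"]]
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

#' Translate a single codon
#'
#' @param codon Three-letter string over A/C/G/T.
#' @return One-letter amino acid symbol, or `"*"` for a stop codon.
#' @details Ambiguity codes (e.g. N) are rejected: the analysis operates on
#'   fully resolved reference and accession sequences.
#' @export
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
translate_codon <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("invalid codon '", codon, "': must be 3 bases over A/C/G/T", call. = FALSE)
  }
  unname(genetic_code()[[codon]])
}

# Vectorised internal translation; inputs assumed pre-validated.
translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

#' Translate a coding sequence
#'
#' @param cds Nucleotide string whose length is a multiple of 3.
#' @return Amino acid string; a terminal stop codon translates to `"*"`.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not divisible by 3", call. = FALSE)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters", call. = FALSE)
  starts <- seq.int(1L, n, by = 3L)
  paste(translate_codons(substring(cds, starts, starts + 2L)), collapse = "")
}

#' Classify the effect of a codon change
#'
#' @param ref_codon,alt_codon Reference and alternative codons.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stop_gained"`,
#'   `"stop_lost"`.
#' @details Identical translations (including stop -> stop) are synonymous;
#'   a non-stop codon becoming a stop is `stop_gained` and the reverse is
#'   `stop_lost`.
#' @export
#' @examples
#' codon_change_effect("TCT", "TCC")  # synonymous
#' codon_change_effect("TCT", "ACT")  # nonsynonymous (S -> T)
codon_change_effect <- function(ref_codon, alt_codon) {
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  classify_aa_change(ref_aa, alt_aa)
}

classify_aa_change <- function(ref_aa, alt_aa) {
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*") return("stop_gained")
  if (ref_aa == "*") return("stop_lost")
  "nonsynonymous"
}

#' Minimal-substitution cost matrix between amino acids
#'
#' For every ordered pair of symbols (20 amino acids plus stop) the minimal
#' number of nucleotide substitutions required to convert some codon of the
#' first into some codon of the second: the minimum Hamming distance over all
#' codon pairs. Entries lie in 0..3 with a zero diagonal and full symmetry.
#'
#' @return 21 x 21 integer matrix with dimnames `AA_SYMBOLS`.
#' @export
#' @examples
#' m <- cost_matrix()
#' m["S", "T"]  # 1: e.g. TCA -> ACA
cost_matrix <- function() {
  gc <- genetic_code()
  codons <- names(gc)
  b <- do.call(rbind, strsplit(codons, ""))
  # pairwise Hamming distances between all 64 codons
  ham <- matrix(0L, 64L, 64L)
  for (k in 1:3) ham <- ham + outer(b[, k], b[, k], "!=")
  m <- matrix(3L, length(AA_SYMBOLS), length(AA_SYMBOLS),
              dimnames = list(AA_SYMBOLS, AA_SYMBOLS))
  for (a1 in AA_SYMBOLS) {
    i <- which(gc == a1)
    for (a2 in AA_SYMBOLS) {
      j <- which(gc == a2)
      m[a1, a2] <- as.integer(min(ham[i, j, drop = FALSE]))
    }
  }
  m
}

# cached at first use; the matrix is a pure function of the genetic code
.phosnp_cache <- new.env(parent = emptyenv())

cost_matrix_cached <- function() {
  if (is.null(.phosnp_cache$cost)) .phosnp_cache$cost <- cost_matrix()
  .phosnp_cache$cost
}

#' Minimal number of DNA substitutions to change one amino acid into another
#'
#' @param aa1,aa2 One-letter amino acid symbols (or `"*"`).
#' @return Integer in 0..3.
#' @export
#' @examples
#' substitution_cost("S", "T")  # 1
#' substitution_cost("S", "D")  # 2
substitution_cost <- function(aa1, aa2) {
  for (a in c(aa1, aa2)) {
    if (!is.character(a) || length(a) != 1L || !(a %in% AA_SYMBOLS)) {
      stop("invalid amino acid symbol '", a, "'", call. = FALSE)
    }
  }
  cost_matrix_cached()[aa1, aa2]
}

#' Complement / reverse-complement of a nucleotide string
#' @param x Nucleotide string over A/C/G/T.
#' @return Complemented (or reverse-complemented) string.
#' @keywords internal
complement_base <- function(x) chartr("ACGT", "TGCA", toupper(x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
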