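# Shared toy fixtures and independent oracles, built in code.

# reverse complement, independent of the package internals
rc <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Hand-crafted two-gene dataset with known coordinates:
#   gene G1 (+ strand): CDS ATG TCT GGA TAC TAA (protein MSGY), two exons
#     chr1 11..17 and 28..35 separated by a 10 nt intron.
#   gene G2 (- strand): CDS ATG AGC ACC TAT TGA (protein MSTY), one exon
#     chr1 46..60 (genomic sequence is the reverse complement).
toy_dataset <- function() {
  cds1 <- "ATGTCTGGATACTAA"
  cds2 <- "ATGAGCACCTATTGA"
  pad <- function(n) strrep("A", n)
  ex1a <- substr(cds1, 1, 7)
  ex1b <- substr(cds1, 8, 15)
  chr1 <- paste0(pad(10), ex1a, "GTATCGATAG", ex1b, pad(10), rc(cds2), pad(10))
  models <- list(
    G1 = gene_model("G1", "chr1", "+", rbind(c(11, 17), c(28, 35)),
                    protein_id = "P1"),
    G2 = gene_model("G2", "chr1", "-", rbind(c(46, 60)), protein_id = "P2"))
  list(genome = c(chr1 = chr1),
       models = models,
       cds = list(G1 = cds1, G2 = cds2),
       proteome = c(P1 = "MSGY", P2 = "MSTY"))
}

toy_snp <- function(chrom, pos, ref, alt, accessions = "accA") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             accessions = accessions, stringsAsFactors = FALSE)
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher test
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# brute-force minimal substitution cost over all codon pairs; written
# directly against the standard code table, not via the package matrix
oracle_cost <- function(aa1, aa2) {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  c1 <- names(gc)[gc == aa1]
  c2 <- names(gc)[gc == aa2]
  best <- 3L
  for (x in c1) for (y in c2) {
    d <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    best <- min(best, d)
  }
  best
}

# small deterministic simulated dataset reused by several test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_proteins = 30, seed = 4242)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
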