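#' Residue-type proportions of a phosphosite set
#'
#' @param sites Phosphosite data.frame (columns `residue` at minimum).
#' @return data.frame with one row per residue (S, T, Y): count, full
#'   precision percentage, and a 1-decimal display value
#'   (round-half-to-even).
#' @export
#' @examples
#' s <- data.frame(residue = rep(c("S", "T", "Y"), c(5078, 1482, 618)))
#' residue_proportions(s)$percent  # 70.74..., 20.65..., 8.61...
residue_proportions <- function(sites) {
  if (nrow(sites) == 0L) stop("empty phosphosite set", call. = FALSE)
  counts <- table(factor(sites$residue, levels = c("S", "T", "Y")))
  total <- sum(counts)
  data.frame(residue = names(counts),
             count = as.integer(counts),
             percent = 100 * as.integer(counts) / total,
             display = round(100 * as.integer(counts) / total, 1L),
             stringsAsFactors = FALSE)
}

#' Fraction of phosphosites inside annotated domains, per residue type
#'
#' A site counts as "inside" when `start <= position <= end` for any domain
#' of its protein (boundaries inclusive). Proteins with no domain
#' annotation contribute all their sites to "outside".
#'
#' @param sites Phosphosite data.frame.
#' @param domains Domain data.frame (protein_id, start, end, domain_id).
#' @return data.frame per residue type plus an `all` row: n_inside,
#'   n_outside, fraction_inside.
#' @export
domain_location_fraction <- function(sites, domains) {
  inside <- sites_in_domains(sites, domains)
  res <- lapply(c("S", "T", "Y"), function(r) {
    sel <- sites$residue == r
    data.frame(residue = r, n_inside = sum(inside[sel]),
               n_outside = sum(!inside[sel]),
               fraction_inside = if (any(sel)) mean(inside[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res[[4L]] <- data.frame(residue = "all", n_inside = sum(inside),
                          n_outside = sum(!inside),
                          fraction_inside = mean(inside),
                          stringsAsFactors = FALSE)
  do.call(rbind, res)
}

# logical: site i falls inside >= 1 domain of its protein
sites_in_domains <- function(sites, domains) {
  if (nrow(sites) == 0L) return(logical(0))
  if (is.null(domains) || nrow(domains) == 0L) return(rep(FALSE, nrow(sites)))
  inside <- rep(FALSE, nrow(sites))
  doms <- split(domains, domains$protein_id)
  for (pid in intersect(names(doms), unique(sites$protein_id))) {
    d <- doms[[pid]]
    sel <- which(sites$protein_id == pid)
    pos <- sites$position[sel]
    hit <- vapply(pos, function(p) any(d$start <= p & p <= d$end), TRUE)
    inside[sel] <- hit
  }
  inside
}

#' Null model for the per-protein phosphosite count distribution
#'
#' Assumes every S/T/Y residue is phosphorylated with one constant
#' probability `p = total phosphosites / total STY residues`, independent of
#' the protein. The expected per-protein count is `E_x = p * n_STY(x)`; the
#' expected frequency-of-count histogram aggregates the binomial law
#' `Binom(n_STY(x), p)` over proteins. By construction the expected total
#' equals the observed total exactly.
#'
#' @param proteome Named character vector of protein sequences.
#' @param sites Phosphosite data.frame (every site's protein must be in the
#'   proteome).
#' @return Object of class `distribution_null` with elements `p`,
#'   `per_protein` (n_sty, expected, observed) and `histogram` (count,
#'   observed, expected).
#' @export
expected_count_distribution <- function(proteome, sites) {
  n_sty <- vapply(proteome, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("S", "T", "Y"))
  }, 0L)
  total_sty <- sum(n_sty)
  if (total_sty == 0L) stop("proteome contains no S/T/Y residues", call. = FALSE)
  unknown <- setdiff(unique(sites$protein_id), names(proteome))
  if (length(unknown) > 0L) {
    stop("sites reference proteins absent from the proteome: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  obs <- table(factor(sites$protein_id, levels = names(proteome)))
  p <- nrow(sites) / total_sty
  expected <- p * n_sty
  max_count <- max(c(as.integer(obs), n_sty))
  counts <- 0:max_count
  exp_hist <- vapply(counts, function(k) {
    sum(stats::dbinom(k, n_sty, p))
  }, 0)
  obs_hist <- tabulate(as.integer(obs) + 1L, nbins = max_count + 1L)
  structure(list(
    p = p,
    per_protein = data.frame(protein_id = names(proteome), n_sty = n_sty,
                             observed = as.integer(obs), expected = expected,
                             row.names = NULL, stringsAsFactors = FALSE),
    histogram = data.frame(count = counts, observed = obs_hist,
                           expected = exp_hist)),
    class = "distribution_null")
}

#' @export
print.distribution_null <- function(x, ...) {
  cat(sprintf("Phosphosite count null model: p = %.4g over %d proteins\n",
              x$p, nrow(x$per_protein)))
  cat(sprintf("  observed total %d, expected total %.4f\n",
              sum(x$per_protein$observed), sum(x$per_protein$expected)))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing the hypergeometric probabilities of
#' all tables (with the observed margins) whose probability does not exceed
#' that of the observed table. The odds ratio is the sample estimate
#' `ad/bc`, with the Haldane-Anscombe 0.5 correction (and a flag) when any
#' cell is zero. A degenerate margin gives `p = 1` and an undefined odds
#' ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p`, `odds_ratio`, `corrected` (zero-cell flag) and
#'   `degenerate`.
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p  # ~0.4857
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b          # row 1 margin
  n <- c_ + d         # row 2 margin
  k <- a + c_         # column 1 margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(list(p = 1, odds_ratio = NA_real_, corrected = FALSE,
                degenerate = TRUE))
  }
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  corrected <- any(table == 0)
  tc <- if (corrected) table + 0.5 else table
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  list(p = p, odds_ratio = or, corrected = corrected, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values (same order as input), clipped at 1 and monotone in
#'   rank; order-invariant.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5))  # 0.04 0.04 0.04 0.50
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Substitution enrichment at phosphorylated versus non-phosphorylated
#' S/T/Y residues
#'
#' For every substitution pair (from in S/T/Y, to in the 20 amino acids plus
#' stop, including the synonymous self pair), builds the 2x2 table with rows
#' = phosphorylated / non-phosphorylated positions of the from-residue and
#' columns = substituted-to-target / not, over the universe of proteins that
#' carry at least one SNP mapping onto a phosphosite of the chosen status
#' (the default, following the source analysis) or over all phosphoproteins
#' of that status (`universe = "phosphoproteins"`). A position counts as
#' substituted when at least one accession carries the substitution,
#' regardless of allele multiplicity. Pairs observed in neither class are
#' reported with `never_observed = TRUE` and not tested; tested pairs get
#' Fisher exact p-values with Benjamini-Hochberg adjustment across all
#' tested pairs.
#'
#' @param sites Phosphosite data.frame (one status).
#' @param effects Effects data.frame from [map_snp_effects()].
#' @param proteome Named character vector of protein sequences.
#' @param alpha FDR threshold marking significance.
#' @param universe `"snp_on_site"` or `"phosphoproteins"`.
#' @return data.frame with one row per (from, to) pair: cells, odds ratio,
#'   p, q, direction, flags.
#' @export
substitution_enrichment <- function(sites, effects, proteome, alpha = 0.05,
                                    universe = c("snp_on_site",
                                                 "phosphoproteins")) {
  universe <- match.arg(universe)
  site_key <- paste(sites$protein_id, sites$position)
  eff_key <- paste(effects$protein_id, effects$protein_pos)
  if (universe == "snp_on_site") {
    univ <- unique(effects$protein_id[eff_key %in% site_key])
  } else {
    univ <- intersect(unique(sites$protein_id), names(proteome))
  }
  if (length(univ) == 0L) stop("empty universe: no protein has a SNP on a phosphosite",
                               call. = FALSE)
  seqs <- proteome[univ]
  sites_u <- sites[sites$protein_id %in% univ, , drop = FALSE]
  eff_u <- effects[effects$protein_id %in% univ, , drop = FALSE]

  # per from-residue: all positions, phospho subset
  letters_by_prot <- strsplit(seqs, "")
  rows <- list()
  tested <- list()
  for (from in c("S", "T", "Y")) {
    n_total <- sum(vapply(letters_by_prot, function(x) sum(x == from), 0L))
    phospho_key <- unique(paste(sites_u$protein_id, sites_u$position)[
      sites_u$residue == from])
    n_phos <- length(phospho_key)
    n_non <- n_total - n_phos
    # substituted positions of this residue, deduplicated per target
    sel <- eff_u$ref_aa == from &
      eff_u$effect_class %in% c("synonymous", "nonsynonymous", "stop_gained")
    e <- eff_u[sel, , drop = FALSE]
    e$to <- ifelse(e$effect_class == "synonymous", e$ref_aa, e$alt_aa)
    e$key <- paste(e$protein_id, e$protein_pos)
    for (to in AA_SYMBOLS) {
      keys <- unique(e$key[e$to == to])
      n11 <- sum(keys %in% phospho_key)
      n21 <- length(keys) - n11
      if (n11 + n21 == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          from = from, to = to, phospho_hit = 0L, phospho_not = n_phos,
          nonphospho_hit = 0L, nonphospho_not = n_non,
          odds_ratio = NA_real_, p = NA_real_, q = NA_real_,
          direction = NA_character_, corrected = FALSE,
          never_observed = TRUE, significant = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      tab <- matrix(c(n11, n_phos - n11, n21, n_non - n21), 2L, byrow = TRUE)
      ft <- fisher_exact(tab)
      row <- data.frame(
        from = from, to = to, phospho_hit = n11, phospho_not = n_phos - n11,
        nonphospho_hit = n21, nonphospho_not = n_non - n21,
        odds_ratio = ft$odds_ratio, p = ft$p, q = NA_real_,
        direction = if (!is.na(ft$odds_ratio) && ft$odds_ratio > 1)
          "enriched_in_phosphosites" else "depleted_in_phosphosites",
        corrected = ft$corrected, never_observed = FALSE,
        significant = FALSE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- row
      tested[[length(tested) + 1L]] <- length(rows)
    }
  }
  res <- do.call(rbind, rows)
  idx <- unlist(tested)
  if (length(idx) > 0L) {
    res$q[idx] <- bh_adjust(res$p[idx])
    res$significant[idx] <- res$q[idx] <= alpha
  }
  res
}
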