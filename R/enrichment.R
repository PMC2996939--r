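#' Hypergeometric term over/under-representation with BH-FDR
#'
#' Tests every annotation term for over-representation (upper hypergeometric
#' tail, `P(K >= x)`) and under-representation (lower tail, `P(K <= x)`) of
#' the query set against the reference set. Proteins without any annotation
#' are discarded from both sets before testing; Benjamini-Hochberg
#' adjustment is applied within each direction across terms (optionally over
#' both directions jointly).
#'
#' @param query_set Character vector of protein ids (must be a subset of
#'   `reference_set`).
#' @param reference_set Character vector of protein ids.
#' @param annotations Term-annotation data.frame (protein_id, term_id).
#' @param alpha FDR threshold marking significance.
#' @param bh_family `"per_direction"` (default) or `"joint"`.
#' @return data.frame with one row per (term, direction): x (annotated in
#'   query), X (annotated query size), n (annotated in reference), N
#'   (annotated reference size), p, q, significant.
#' @export
term_enrichment <- function(query_set, reference_set, annotations,
                            alpha = 0.05,
                            bh_family = c("per_direction", "joint")) {
  bh_family <- match.arg(bh_family)
  if (!all(query_set %in% reference_set)) {
    stop("query set must be a subset of the reference set", call. = FALSE)
  }
  annotated <- unique(annotations$protein_id)
  query <- intersect(unique(query_set), annotated)
  reference <- intersect(unique(reference_set), annotated)
  if (length(query) == 0L) stop("no annotated protein in the query set",
                                call. = FALSE)
  ann <- annotations[annotations$protein_id %in% reference, , drop = FALSE]
  X <- length(query)
  N <- length(reference)
  terms <- unique(ann$term_id)
  rows <- lapply(terms, function(term) {
    members <- unique(ann$protein_id[ann$term_id == term])
    n <- length(members)
    x <- sum(query %in% members)
    p_over <- stats::phyper(x - 1L, n, N - n, X, lower.tail = FALSE)
    p_under <- stats::phyper(x, n, N - n, X)
    data.frame(term_id = term,
               direction = c("over", "under"),
               x = x, X = X, n = n, N = N,
               p = c(p_over, p_under), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (bh_family == "per_direction") {
    for (d in c("over", "under")) {
      sel <- res$direction == d
      res$q[sel] <- bh_adjust(res$p[sel])
    }
  } else {
    res$q <- bh_adjust(res$p)
  }
  res$significant <- res$q <= alpha
  rownames(res) <- NULL
  res
}

#' Pearson correlation of binary term-presence profiles
#'
#' @param term_presence_a,term_presence_b Logical/0-1 vectors over the same
#'   ordered term universe.
#' @return List with `r` (Pearson correlation; `NA` with `constant = TRUE`
#'   when either profile has zero variance).
#' @export
#' @examples
#' profile_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0))$r  # 0
profile_correlation <- function(term_presence_a, term_presence_b) {
  if (length(term_presence_a) != length(term_presence_b)) {
    stop("profiles must be the same length", call. = FALSE)
  }
  a <- as.numeric(term_presence_a)
  b <- as.numeric(term_presence_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, constant = TRUE))
  }
  list(r = stats::cor(a, b), constant = FALSE)
}
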