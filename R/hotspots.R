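# evaluate `code` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Hotspot detection configuration
#'
#' @param mode `"experimental"` (window score = phosphosite count) or
#'   `"predicted"` (window score = sum of prediction scores).
#' @param winsize Window size in residues. Customary choices are 5/10/15/20
#'   for experimental sites and 10/20/30/40 for predicted sites.
#' @param alpha Significance level for the Bonferroni-corrected p-value.
#' @param n_background Number of Monte-Carlo background proteomes (default
#'   10,000 for experimental mode, 1,000 for predicted mode).
#' @param seed RNG seed; mandatory, every run is reproducible.
#' @return List of class `hotspot_config`.
#' @export
hotspot_config <- function(mode = c("experimental", "predicted"),
                           winsize = 10L, alpha = 0.05,
                           n_background = NULL, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(n_background)) {
    n_background <- if (mode == "experimental") 10000L else 1000L
  }
  stopifnot(winsize >= 1L, alpha > 0, alpha < 1, n_background >= 1L)
  structure(list(mode = mode, winsize = as.integer(winsize), alpha = alpha,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "hotspot_config")
}

#' Sliding-window scores of one protein
#'
#' Scans the protein with a step-1 window of fixed size. Among consecutive
#' windows containing the identical set of S/T/Y residues only the first is
#' kept. The score is the phosphosite count (experimental) or the sum of
#' the supplied per-position scores (predicted); the number of S/T/Y
#' residues per window is also reported.
#'
#' @param sequence Protein sequence.
#' @param winsize Window size.
#' @param site_positions Integer positions of phosphosites (experimental
#'   mode).
#' @param scores data.frame with `position` and `score` covering the scored
#'   S/T/Y positions (predicted mode).
#' @return data.frame with `start`, `score`, `n_sty`; zero rows (with a
#'   warning) when the protein is shorter than the window.
#' @export
scan_windows <- function(sequence, winsize, site_positions = NULL,
                         scores = NULL) {
  L <- nchar(sequence)
  if (L < winsize) {
    warning("protein shorter than window (", L, " < ", winsize, ")",
            call. = FALSE)
    return(data.frame(start = integer(0), score = numeric(0),
                      n_sty = integer(0)))
  }
  chars <- strsplit(sequence, "")[[1]]
  sty <- chars %in% c("S", "T", "Y")
  val <- numeric(L)
  if (!is.null(scores)) {
    val[scores$position] <- scores$score
  } else if (!is.null(site_positions)) {
    val[site_positions] <- 1
  }
  cs <- c(0, cumsum(val))
  css <- c(0L, cumsum(sty))
  starts <- seq_len(L - winsize + 1L)
  score <- cs[starts + winsize] - cs[starts]
  n_sty <- css[starts + winsize] - css[starts]
  sty0 <- c(FALSE, sty)
  keep <- starts == 1L | sty0[starts] | sty[starts + winsize - 1L]
  data.frame(start = starts[keep], score = score[keep], n_sty = n_sty[keep])
}

#' Statistical profile of a proteome for background simulation
#'
#' Captures the protein length multiset, the S/T/Y/other residue category
#' frequencies, and either the per-residue phosphorylation probabilities
#' (experimental mode: fraction of each residue type that is a phosphosite)
#' or the pool of prediction scores carried by all S/T/Y residues
#' (predicted mode).
#'
#' @param proteome Named character vector of protein sequences.
#' @param sites Phosphosite data.frame (experimental mode).
#' @param mode `"experimental"` or `"predicted"`.
#' @param scorer Scoring function used to build the score pool in predicted
#'   mode.
#' @return List of class `proteome_profile`.
#' @export
proteome_profile <- function(proteome, sites = NULL,
                             mode = c("experimental", "predicted"),
                             scorer = toy_scorer) {
  mode <- match.arg(mode)
  lengths <- nchar(proteome)
  all_chars <- strsplit(paste(proteome, collapse = ""), "")[[1]]
  n_total <- length(all_chars)
  n_res <- c(S = sum(all_chars == "S"), T = sum(all_chars == "T"),
             Y = sum(all_chars == "Y"))
  if (sum(n_res) == 0L) stop("proteome has no S/T/Y residues", call. = FALSE)
  cat_prob <- c(n_res, other = n_total - sum(n_res)) / n_total
  out <- list(n_proteins = length(proteome), lengths = unname(lengths),
              cat_prob = cat_prob, sty_freq = sum(n_res) / n_total,
              mode = mode)
  if (mode == "experimental") {
    if (is.null(sites)) stop("experimental profile needs sites", call. = FALSE)
    n_phos <- table(factor(sites$residue, levels = c("S", "T", "Y")))
    out$phospho_prob <- as.numeric(n_phos) / pmax(as.numeric(n_res), 1L)
    names(out$phospho_prob) <- c("S", "T", "Y")
  } else {
    pool <- unlist(lapply(proteome, function(s) score_protein(s, scorer)$score),
                   use.names = FALSE)
    out$score_pool <- pool
  }
  structure(out, class = "proteome_profile")
}

#' Simulate the empirical background window-score distribution
#'
#' Samples `n_background` replicate proteomes matching the profile (same
#' number of proteins, lengths resampled with replacement from the real
#' length multiset, residues i.i.d. from the global composition), assigns
#' phosphosites (experimental: per-residue-type probabilities) or scores
#' (predicted: resampled from the score pool) at S/T/Y positions, scans all
#' proteins with the deduplicating window scan, and pools the scores into
#' one empirical distribution. Fully reproducible under the config seed.
#'
#' @param profile A [proteome_profile()].
#' @param config A [hotspot_config()].
#' @return List of class `hotspot_background`: for experimental mode a
#'   tail-count table over integer scores; for predicted mode the sorted
#'   score vector; plus the total number of background windows.
#' @export
simulate_background <- function(profile, config) {
  stopifnot(inherits(profile, "proteome_profile"),
            inherits(config, "hotspot_config"))
  w <- config$winsize
  n_prot <- profile$n_proteins
  cat_prob <- as.numeric(profile$cat_prob)  # S, T, Y, other
  with_seed(config$seed, {
    if (config$mode == "experimental") {
      pprob <- c(profile$phospho_prob, 0)
      max_score <- w
      tail_counts <- numeric(max_score + 1L)  # index k+1 = count of score==k
      n_windows <- 0
      chunk <- max(1L, min(config$n_background,
                           ceiling(8e6 / max(1, n_prot * mean(profile$lengths)))))
      done <- 0L
      while (done < config$n_background) {
        nb <- min(chunk, config$n_background - done)
        done <- done + nb
        lens <- sample(profile$lengths, n_prot * nb, replace = TRUE)
        lens <- lens[lens >= w]
        if (length(lens) == 0L) next
        N <- sum(lens)
        cat <- sample.int(4L, N, replace = TRUE, prob = cat_prob)
        ph <- stats::runif(N) < pprob[cat]
        sty <- cat != 4L
        off <- cumsum(c(0L, lens[-length(lens)]))
        nw <- lens - w + 1L
        ls <- sequence(nw)
        starts <- ls + rep(off, nw)
        # dedup first, then score only the retained windows
        sty0 <- c(FALSE, sty)
        keep <- ls == 1L | sty0[starts] | sty[starts + w - 1L]
        sk <- starts[keep]
        cs <- c(0L, cumsum(ph))
        sc <- cs[sk + w] - cs[sk]
        tail_counts <- tail_counts + tabulate(sc + 1L, nbins = max_score + 1L)
        n_windows <- n_windows + length(sc)
      }
      structure(list(mode = "experimental",
                     score_counts = tail_counts,
                     n_windows = n_windows, winsize = w),
                class = "hotspot_background")
    } else {
      pool <- profile$score_pool
      all_scores <- list()
      n_windows <- 0
      chunk <- max(1L, min(config$n_background,
                           ceiling(2e6 / max(1, n_prot * mean(profile$lengths)))))
      done <- 0L
      while (done < config$n_background) {
        nb <- min(chunk, config$n_background - done)
        done <- done + nb
        lens <- sample(profile$lengths, n_prot * nb, replace = TRUE)
        lens <- lens[lens >= w]
        if (length(lens) == 0L) next
        N <- sum(lens)
        cat <- sample.int(4L, N, replace = TRUE, prob = cat_prob)
        sty <- cat != 4L
        val <- numeric(N)
        val[sty] <- sample(pool, sum(sty), replace = TRUE)
        off <- cumsum(c(0L, lens[-length(lens)]))
        nw <- lens - w + 1L
        ls <- sequence(nw)
        starts <- ls + rep(off, nw)
        sty0 <- c(FALSE, sty)
        keep <- ls == 1L | sty0[starts] | sty[starts + w - 1L]
        sk <- starts[keep]
        cs <- c(0, cumsum(val))
        sc <- cs[sk + w] - cs[sk]
        all_scores[[length(all_scores) + 1L]] <- sc
        n_windows <- n_windows + length(sc)
      }
      structure(list(mode = "predicted",
                     sorted_scores = sort(unlist(all_scores)),
                     n_windows = n_windows, winsize = w),
                class = "hotspot_background")
    }
  })
}

# number of background windows with score >= s
background_tail <- function(background, s) {
  if (background$mode == "experimental") {
    counts <- background$score_counts
    cum_ge <- rev(cumsum(rev(counts)))
    k <- pmin(floor(s), length(counts) - 1L)
    out <- ifelse(s > length(counts) - 1L, 0, cum_ge[pmax(k, 0) + 1L])
    ifelse(s <= 0, background$n_windows, out)
  } else {
    srt <- background$sorted_scores
    length(srt) - findInterval(s, srt, left.open = TRUE)
  }
}

#' Detect phosphorylation hotspots
#'
#' Scans every protein with the deduplicating fixed-size window, assigns
#' each candidate window the right-tail empirical p-value
#' `(background windows with score >= observed + 1) / (background windows +
#' 1)` against the pooled Monte-Carlo background, applies the Bonferroni
#' correction with `m` = number of candidate windows tested proteome-wide,
#' and keeps windows with corrected p below `alpha`. In predicted mode a
#' candidate window must additionally contain at least
#' `floor(winsize * STY frequency)` S/T/Y residues (this filter applies to
#' the real candidates only, not to the background).
#'
#' @param proteome Named character vector of protein sequences.
#' @param sites Phosphosite data.frame; in predicted mode its `score`
#'   column is used.
#' @param config A [hotspot_config()].
#' @param background Optional precomputed [simulate_background()] result
#'   (profile and background are rebuilt from the inputs when omitted).
#' @param scorer Scorer used for the predicted-mode score pool.
#' @return Object of class `hotspot_scan`.
#' @export
detect_hotspots <- function(proteome, sites, config, background = NULL,
                            scorer = toy_scorer) {
  stopifnot(inherits(config, "hotspot_config"))
  if (is.null(background)) {
    profile <- proteome_profile(proteome, sites, mode = config$mode,
                                scorer = scorer)
    background <- simulate_background(profile, config)
  } else {
    profile <- proteome_profile(proteome, sites, mode = config$mode,
                                scorer = scorer)
  }
  w <- config$winsize
  cands <- list()
  for (pid in names(proteome)) {
    seqs <- proteome[[pid]]
    if (nchar(seqs) < w) next
    psites <- sites[sites$protein_id == pid, , drop = FALSE]
    if (config$mode == "experimental") {
      sw <- scan_windows(seqs, w, site_positions = psites$position)
    } else {
      sw <- scan_windows(seqs, w,
                         scores = psites[c("position", "score")])
    }
    if (nrow(sw) == 0L) next
    sw$protein_id <- pid
    cands[[length(cands) + 1L]] <- sw
  }
  if (length(cands) == 0L) {
    windows <- data.frame(protein_id = character(0), start = integer(0),
                          winsize = integer(0), score = numeric(0),
                          n_sty = integer(0), raw_p = numeric(0),
                          corrected_p = numeric(0))
    return(structure(list(windows = windows, m = 0L, background = background,
                          config = config), class = "hotspot_scan"))
  }
  cand <- do.call(rbind, cands)
  if (config$mode == "predicted") {
    min_sty <- floor(w * profile$sty_freq)
    cand <- cand[cand$n_sty >= min_sty, , drop = FALSE]
  }
  m <- nrow(cand)
  raw_p <- (background_tail(background, cand$score) + 1) /
    (background$n_windows + 1)
  corrected <- pmin(1, raw_p * m)
  sig <- corrected < config$alpha
  windows <- data.frame(protein_id = cand$protein_id, start = cand$start,
                        winsize = w, score = cand$score, n_sty = cand$n_sty,
                        raw_p = raw_p, corrected_p = corrected,
                        stringsAsFactors = FALSE)[sig, , drop = FALSE]
  windows <- windows[order(windows$protein_id, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  structure(list(windows = windows, m = m, background = background,
                 config = config), class = "hotspot_scan")
}

#' @export
print.hotspot_scan <- function(x, ...) {
  cat(sprintf("Hotspot scan (%s mode, winsize %d): %d significant window(s) in %d protein(s)\n",
              x$config$mode, x$config$winsize, nrow(x$windows),
              length(unique(x$windows$protein_id))))
  cat(sprintf("  %d candidate windows tested against %d background windows\n",
              x$m, x$background$n_windows))
  invisible(x)
}

#' Merge significant hotspot windows into runs
#'
#' Overlapping or bookended (adjacent) windows of the same protein are
#' merged into maximal contiguous runs; a solitary hotspot yields a run
#' identical to its own span.
#'
#' @param windows Hotspot window data.frame (`protein_id`, `start`,
#'   `winsize`), e.g. `detect_hotspots(...)$windows`.
#' @return data.frame with `protein_id`, `start`, `end`, `n_windows`.
#' @export
merge_runs <- function(windows) {
  if (nrow(windows) == 0L) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0)))
  }
  windows$end <- windows$start + windows$winsize - 1L
  out <- list()
  for (pid in unique(windows$protein_id)) {
    ww <- windows[windows$protein_id == pid, , drop = FALSE]
    ww <- ww[order(ww$start), , drop = FALSE]
    cur_start <- ww$start[1L]; cur_end <- ww$end[1L]; n <- 1L
    flush <- function(s, e, k) data.frame(protein_id = pid, start = s, end = e,
                                          n_windows = k, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ww))[-1L]) {
      if (ww$start[i] <= cur_end + 1L) {  # overlap or adjacency
        cur_end <- max(cur_end, ww$end[i]); n <- n + 1L
      } else {
        out[[length(out) + 1L]] <- flush(cur_start, cur_end, n)
        cur_start <- ww$start[i]; cur_end <- ww$end[i]; n <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush(cur_start, cur_end, n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation test for hotspot-domain overlap
#'
#' Counts hotspots whose interval intersects at least one annotated domain
#' of their protein, then builds the null by re-placing each hotspot
#' uniformly at random within its own protein (same length) and recounting,
#' `n_permutations` times. Empirical p-values use the add-one estimator
#' `(r + 1) / (n + 1)`. The depletion p-value (hotspots preferentially
#' outside domains) is the left tail; enrichment is the right tail. With no
#' domains at all the observed overlap is 0 and the depletion p-value is 1
#' by convention.
#'
#' @param hotspots data.frame with `protein_id`, `start`, `end` (e.g. from
#'   [merge_runs()] or `detect_hotspots(...)$windows` with `end` added).
#' @param domains Domain data.frame.
#' @param proteome Named character vector (protein lengths).
#' @param n_permutations Number of Monte-Carlo placements.
#' @param seed RNG seed.
#' @return List: `observed_overlap`, `p_depletion`, `p_enrichment`,
#'   `n_permutations`, `n_hotspots`.
#' @export
domain_overlap_test <- function(hotspots, domains, proteome,
                                n_permutations = 10000L, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (!"end" %in% names(hotspots) && "winsize" %in% names(hotspots)) {
    hotspots$end <- hotspots$start + hotspots$winsize - 1L
  }
  doms <- if (is.null(domains)) NULL else split(domains, domains$protein_id)
  obs <- 0L
  qs <- numeric(0)
  for (i in seq_len(nrow(hotspots))) {
    pid <- hotspots$protein_id[i]
    L <- nchar(proteome[[pid]])
    hlen <- hotspots$end[i] - hotspots$start[i] + 1L
    if (hlen > L) {
      warning("hotspot longer than protein ", pid, "; placement skipped",
              call. = FALSE)
      next
    }
    d <- doms[[pid]]
    hit_obs <- !is.null(d) && any(d$start <= hotspots$end[i] &
                                    d$end >= hotspots$start[i])
    obs <- obs + as.integer(hit_obs)
    # probability that a uniformly placed copy of this hotspot overlaps a
    # domain: fraction of valid start positions whose interval intersects
    # any domain
    n_starts <- L - hlen + 1L
    if (is.null(d) || nrow(d) == 0L) {
      qs <- c(qs, 0)
    } else {
      ok <- rep(FALSE, n_starts)
      for (j in seq_len(nrow(d))) {
        lo <- max(1L, d$start[j] - hlen + 1L)
        hi <- min(n_starts, d$end[j])
        if (lo <= hi) ok[lo:hi] <- TRUE
      }
      qs <- c(qs, mean(ok))
    }
  }
  if (length(qs) == 0L || all(qs == 0)) {
    null_counts <- integer(n_permutations)
  } else {
    null_counts <- with_seed(seed, {
      counts <- integer(n_permutations)
      for (q in qs[qs > 0]) {
        counts <- counts + (stats::runif(n_permutations) < q)
      }
      counts
    })
  }
  list(observed_overlap = obs,
       p_depletion = (sum(null_counts <= obs) + 1) / (n_permutations + 1),
       p_enrichment = (sum(null_counts >= obs) + 1) / (n_permutations + 1),
       n_permutations = n_permutations,
       n_hotspots = length(qs))
}
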