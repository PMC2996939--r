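# Fixed residue propensities and distance weights of the toy phosphosite
# scorer. The propensities loosely follow basophilic/proline-directed plant
# kinase motif preferences (basic and S/P-rich context scores up, acidic and
# bulky hydrophobic context scores down); the exact values are an arbitrary
# published constant of the package, chosen so that both high-confidence
# regimes (score >= 1 and score <= -1) are reachable by single amino acid
# substitutions in the +/-6 window.
TOY_PROPENSITY <- c(
  A = -0.1, R = 1.0, N = 0.3, D = -0.6, C = -0.2, Q = 0.2, E = -0.7,
  G = 0.1, H = 0.4, I = -0.8, L = -1.0, K = 0.8, M = -0.4, F = -0.6,
  P = 0.5, S = 0.6, T = 0.3, W = -0.5, Y = -0.3, V = -0.7, `*` = 0)

TOY_WEIGHTS <- c(0.50, 0.30, 0.20, 0.12, 0.08, 0.05)  # |offset| 1..6

TOY_CENTRAL <- c(S = 0.10, T = 0.00, Y = -0.10)

#' Deterministic toy phosphorylation-site scorer
#'
#' Scores the sequence context from -6 to +6 residues around a central S, T
#' or Y as a fixed weighted sum of residue propensities, squashed through
#' `3 * tanh()` into (-3, 3). Positions beyond the protein ends contribute
#' zero. Scores >= 1 are read as high-confidence phosphosites and scores
#' <= -1 as high-confidence non-sites, both thresholds inclusive.
#'
#' @param sequence Protein sequence.
#' @param position 1-based position of an S/T/Y residue.
#' @return Decision value in (-3, 3).
#' @export
toy_scorer <- function(sequence, position) {
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("scorer position ", position, " outside protein (length ", n, ")",
         call. = FALSE)
  }
  central <- substring(sequence, position, position)
  if (!(central %in% c("S", "T", "Y"))) {
    stop("scorer requires a central S/T/Y residue, got '", central,
         "' at position ", position, call. = FALSE)
  }
  raw <- TOY_CENTRAL[[central]]
  for (d in 1:6) {
    for (p in c(position - d, position + d)) {
      if (p >= 1L && p <= n) {
        aa <- substring(sequence, p, p)
        raw <- raw + TOY_WEIGHTS[d] * TOY_PROPENSITY[[aa]]
      }
    }
  }
  3 * tanh(raw)
}

#' Score every S/T/Y position of a protein
#'
#' @param sequence Protein sequence.
#' @param scorer Scoring function `(sequence, position) -> value`.
#' @return data.frame with `position`, `residue`, `score`.
#' @export
score_protein <- function(sequence, scorer = toy_scorer) {
  chars <- strsplit(sequence, "")[[1]]
  pos <- which(chars %in% c("S", "T", "Y"))
  data.frame(position = pos, residue = chars[pos],
             score = vapply(pos, function(p) scorer(sequence, p), 0),
             stringsAsFactors = FALSE)
}

#' Reconstruct an accession's protein sequence
#'
#' Applies all of one accession's substitutions for a protein to the
#' reference sequence (needed for correct +/-6 scorer context when several
#' SNPs fall close together). A stop gain truncates the sequence.
#'
#' @param sequence Reference protein sequence.
#' @param subs data.frame with `protein_pos` and `alt_aa` for one
#'   (protein, accession).
#' @return Accession protein sequence.
#' @export
apply_substitutions <- function(sequence, subs) {
  if (nrow(subs) == 0L) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  trunc_at <- NA_integer_
  for (i in seq_len(nrow(subs))) {
    p <- subs$protein_pos[i]
    if (p > length(chars)) next
    if (subs$alt_aa[i] == "*") {
      trunc_at <- min(trunc_at, p - 1L, na.rm = TRUE)
    } else {
      chars[p] <- subs$alt_aa[i]
    }
  }
  if (!is.na(trunc_at)) chars <- chars[seq_len(max(trunc_at, 0L))]
  paste(chars, collapse = "")
}

# explode comma-separated accession strings into one row per accession
explode_accessions <- function(effects) {
  accs <- strsplit(effects$accessions, ",")
  n <- lengths(accs)
  out <- effects[rep(seq_len(nrow(effects)), n), , drop = FALSE]
  out$accession <- unlist(accs)
  rownames(out) <- NULL
  out
}

gain_loss_empty <- function() {
  data.frame(protein_id = character(0), position = integer(0),
             accession = character(0), kind = character(0),
             status = integer(0), ref_residue = character(0),
             alt_residue = character(0), ref_score = numeric(0),
             alt_score = numeric(0), stringsAsFactors = FALSE)
}

#' Call losses of experimental phosphosites
#'
#' A loss is recorded for every accession whose substitution replaces the
#' phosphorylated residue: by default any amino acid exchange counts,
#' including exchanges to another phosphorylatable residue (e.g. S -> T) and
#' gained stops; `strict = TRUE` restricts losses to exchanges to
#' non-phosphorylatable targets.
#'
#' @param sites Experimental phosphosite data.frame.
#' @param effects Effects data.frame from [map_snp_effects()].
#' @param strict Restrict to non-S/T/Y substitution targets.
#' @return data.frame of loss events (one row per site x accession), with
#'   `status = 2` (substitution-based) and `NA` scores.
#' @export
call_experimental_losses <- function(sites, effects, strict = FALSE) {
  sites <- sites[sites$status == "experimental", , drop = FALSE]
  if (nrow(sites) == 0L || nrow(effects) == 0L) return(gain_loss_empty())
  eff <- effects[effects$effect_class %in% c("nonsynonymous", "stop_gained"), ,
                 drop = FALSE]
  key_s <- paste(sites$protein_id, sites$position)
  key_e <- paste(eff$protein_id, eff$protein_pos)
  hit <- match(key_e, key_s)
  eff <- eff[!is.na(hit), , drop = FALSE]
  site_res <- sites$residue[hit[!is.na(hit)]]
  if (nrow(eff) == 0L) return(gain_loss_empty())
  if (any(eff$ref_aa != site_res)) {
    stop("phosphosite residue does not match mapped reference amino acid",
         call. = FALSE)
  }
  if (strict) {
    keep <- !(eff$alt_aa %in% c("S", "T", "Y"))
    eff <- eff[keep, , drop = FALSE]
  }
  if (nrow(eff) == 0L) return(gain_loss_empty())
  ex <- explode_accessions(eff)
  out <- data.frame(protein_id = ex$protein_id, position = ex$protein_pos,
                    accession = ex$accession, kind = "loss", status = 2L,
                    ref_residue = ex$ref_aa, alt_residue = ex$alt_aa,
                    ref_score = NA_real_, alt_score = NA_real_,
                    stringsAsFactors = FALSE)
  out[!duplicated(out[c("protein_id", "position", "accession",
                        "alt_residue")]), , drop = FALSE]
}

#' Call gains and losses of predicted phosphosites per accession
#'
#' Implements the two event types for prediction-based sites:
#' substitution-based (status 2: a high-confidence site residue exchanged
#' for a non-phosphorylatable amino acid is a loss; a non-S/T/Y residue
#' exchanged for an S/T/Y whose accession-context score is >= 1 is a gain)
#' and score-based (status 1: the central residue is retained but
#' substitutions within the +/-6 context move the score from >= 1 to <= -1,
#' a loss, or from <= -1 to >= 1, a gain). Scores strictly inside (-1, 1)
#' on either side yield no call; a central S/T/Y exchanged for a different
#' S/T/Y is likewise a no-call.
#'
#' @param sites Predicted phosphosite data.frame (reference scores >= 1).
#' @param effects Effects data.frame from [map_snp_effects()].
#' @param proteome Named character vector of reference protein sequences.
#' @param scorer Scoring function `(sequence, position) -> value`.
#' @return data.frame of gain/loss events.
#' @export
call_predicted_gain_loss <- function(sites, effects, proteome,
                                     scorer = toy_scorer) {
  sites <- sites[sites$status == "predicted", , drop = FALSE]
  if (nrow(sites) > 0L && any(!is.na(sites$score) & sites$score < 1)) {
    stop("predicted input sites must have reference score >= 1", call. = FALSE)
  }
  if (nrow(effects) == 0L) return(gain_loss_empty())
  ex <- explode_accessions(effects)
  ex <- ex[ex$effect_class %in% c("nonsynonymous", "stop_gained"), ,
           drop = FALSE]
  if (nrow(ex) == 0L) return(gain_loss_empty())
  events <- list()
  groups <- split(ex, paste(ex$protein_id, ex$accession, sep = "\r"))
  for (g in groups) {
    pid <- g$protein_id[1L]
    acc <- g$accession[1L]
    refseq <- unname(proteome[pid])
    if (is.na(refseq)) next
    accseq <- apply_substitutions(refseq, g)
    psites <- sites[sites$protein_id == pid, , drop = FALSE]
    sub_pos <- g$protein_pos
    # --- losses at predicted sites
    for (i in seq_len(nrow(psites))) {
      pos <- psites$position[i]
      ref_res <- psites$residue[i]
      acc_res <- if (pos <= nchar(accseq)) substring(accseq, pos, pos) else "*"
      if (!(acc_res %in% c("S", "T", "Y"))) {
        # central residue exchanged for a non-phosphorylatable one (or lost
        # to a truncation): substitution-based loss, but only when this
        # accession actually substitutes the site
        if (any(sub_pos == pos) || pos > nchar(accseq)) {
          events[[length(events) + 1L]] <- data.frame(
            protein_id = pid, position = pos, accession = acc,
            kind = "loss", status = 2L, ref_residue = ref_res,
            alt_residue = acc_res, ref_score = psites$score[i],
            alt_score = NA_real_, stringsAsFactors = FALSE)
        }
      } else if (acc_res == ref_res) {
        # central retained: score-based call needs a neighbour substitution
        if (any(abs(sub_pos - pos) <= 6L & sub_pos != pos)) {
          new_score <- scorer(accseq, pos)
          if (new_score <= -1) {
            events[[length(events) + 1L]] <- data.frame(
              protein_id = pid, position = pos, accession = acc,
              kind = "loss", status = 1L, ref_residue = ref_res,
              alt_residue = acc_res, ref_score = psites$score[i],
              alt_score = new_score, stringsAsFactors = FALSE)
          }
        }
      }
      # S/T/Y exchanged for a different S/T/Y: no call
    }
    # --- substitution-based gains: non-STY reference residue becomes S/T/Y
    gain_rows <- g[!(g$ref_aa %in% c("S", "T", "Y")) &
                     g$alt_aa %in% c("S", "T", "Y"), , drop = FALSE]
    for (i in seq_len(nrow(gain_rows))) {
      pos <- gain_rows$protein_pos[i]
      if (pos > nchar(accseq)) next
      new_score <- scorer(accseq, pos)
      if (new_score >= 1) {
        events[[length(events) + 1L]] <- data.frame(
          protein_id = pid, position = pos, accession = acc,
          kind = "gain", status = 2L, ref_residue = gain_rows$ref_aa[i],
          alt_residue = gain_rows$alt_aa[i], ref_score = NA_real_,
          alt_score = new_score, stringsAsFactors = FALSE)
      }
    }
    # --- score-based gains: reference S/T/Y with high-confidence negative
    # reference score, central retained, neighbour substitution flips it
    site_pos <- sites$position[sites$protein_id == pid]
    chars <- strsplit(refseq, "")[[1]]
    sty_pos <- which(chars %in% c("S", "T", "Y"))
    cand <- setdiff(sty_pos, site_pos)
    cand <- cand[vapply(cand, function(p) {
      any(abs(sub_pos - p) <= 6L & sub_pos != p) && !any(sub_pos == p)
    }, TRUE)]
    for (pos in cand) {
      if (pos > nchar(accseq)) next
      if (substring(accseq, pos, pos) != chars[pos]) next
      ref_score <- scorer(refseq, pos)
      if (ref_score > -1) next
      new_score <- scorer(accseq, pos)
      if (new_score >= 1) {
        events[[length(events) + 1L]] <- data.frame(
          protein_id = pid, position = pos, accession = acc,
          kind = "gain", status = 1L, ref_residue = chars[pos],
          alt_residue = chars[pos], ref_score = ref_score,
          alt_score = new_score, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(events) == 0L) return(gain_loss_empty())
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Summarize gain/loss events
#'
#' @param events Events data.frame from the callers.
#' @return List with distinct-protein counts per kind and the status
#'   breakdown (status 2 = substitution-based, status 1 = score-based).
#' @export
summarize_gain_loss <- function(events) {
  kinds <- c("loss", "gain")
  proteins <- lapply(kinds, function(k) {
    unique(events$protein_id[events$kind == k])
  })
  names(proteins) <- kinds
  status_tab <- table(factor(events$kind, levels = kinds),
                      factor(events$status, levels = c(1L, 2L)))
  list(n_loss_proteins = length(proteins$loss),
       n_gain_proteins = length(proteins$gain),
       loss_proteins = proteins$loss,
       gain_proteins = proteins$gain,
       by_status = status_tab,
       n_events = nrow(events))
}
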