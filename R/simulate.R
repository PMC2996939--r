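# Default amino acid composition (approximate plant proteome frequencies,
# normalised at use). S/T/Y frequencies matter most here: together with the
# default per-residue phosphorylation probabilities they give a realized
# phosphosite split close to 70.7% pS / 20.7% pT / 8.6% pY.
DEFAULT_AA_FREQ <- c(
  A = 6.3, R = 5.4, N = 4.3, D = 5.4, C = 1.8, Q = 3.5, E = 6.7, G = 6.4,
  H = 2.3, I = 5.3, L = 9.5, K = 6.4, M = 2.4, F = 4.2, P = 4.7, S = 9.0,
  T = 5.1, W = 1.2, Y = 2.9, V = 6.8)

codons_by_aa <- function() {
  gc <- genetic_code()
  split(names(gc), gc)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. All generator
#' output is a pure function of this configuration (including its mandatory
#' seed).
#'
#' @param n_proteins Number of proteins/genes.
#' @param length_meanlog,length_sdlog Log-normal protein length parameters.
#' @param min_length Minimum protein length (residues).
#' @param composition Named amino acid frequency vector (normalised
#'   internally).
#' @param phospho_probs Per-residue phosphorylation probabilities for S, T,
#'   Y. The defaults, combined with the default composition, target the
#'   canonical experimental residue split of roughly 70.7/20.7/8.6.
#' @param snp_rate Background SNP rate per coding base.
#' @param n_accessions Number of natural accessions.
#' @param allele_share Probability that any given accession carries a SNP's
#'   alternative allele (at least one carrier is enforced).
#' @param max_exons Maximum exons per gene (1..max sampled uniformly).
#' @param intron_range,intergenic_range Min/max intron and intergenic
#'   lengths (bp).
#' @param domain_coverage Fraction of residues covered by domains.
#' @param domain_length Min/max domain length (residues).
#' @param n_terms Size of the annotation-term vocabulary.
#' @param term_rate_range Min/max per-term base annotation rate.
#' @param term_enrich Optional list(`term`, `proteins`, `factor`) boosting
#'   one term's rate in a protein subset.
#' @param planted_hotspots Optional data.frame (`protein` index, `start`,
#'   `winsize`, `n_sites`) of phosphosite clusters forced into windows.
#' @param planted_events Optional named integer vector over
#'   `c("loss2", "loss1", "gain2", "gain1")`: numbers of predicted-site
#'   gain/loss events to engineer via single-base SNPs.
#' @param plant_tn Optional list(`rate_site`, `rate_background`): rates of
#'   planted T-to-N SNPs at predicted phospho-threonines versus other
#'   threonines.
#' @param seed Mandatory RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 150L,
                       length_meanlog = log(300), length_sdlog = 0.45,
                       min_length = 40L,
                       composition = DEFAULT_AA_FREQ,
                       phospho_probs = c(S = 0.100, T = 0.052, Y = 0.038),
                       snp_rate = 0.001,
                       n_accessions = 20L,
                       allele_share = 0.15,
                       max_exons = 3L,
                       intron_range = c(30L, 90L),
                       intergenic_range = c(50L, 150L),
                       domain_coverage = 0.3,
                       domain_length = c(30L, 60L),
                       n_terms = 30L,
                       term_rate_range = c(0.02, 0.2),
                       term_enrich = NULL,
                       planted_hotspots = NULL,
                       planted_events = NULL,
                       plant_tn = NULL,
                       seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  composition <- composition / sum(composition)
  stopifnot(all(phospho_probs >= 0 & phospho_probs <= 1),
            snp_rate >= 0, snp_rate <= 1,
            allele_share >= 0, allele_share <= 1,
            domain_coverage >= 0, domain_coverage <= 1)
  if (!is.null(planted_hotspots)) {
    if (any(planted_hotspots$n_sites > planted_hotspots$winsize)) {
      stop("planted hotspot exceeds window capacity (n_sites > winsize)",
           call. = FALSE)
    }
  }
  structure(list(
    n_proteins = as.integer(n_proteins), length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, min_length = as.integer(min_length),
    composition = composition, phospho_probs = phospho_probs,
    snp_rate = snp_rate, n_accessions = as.integer(n_accessions),
    allele_share = allele_share, max_exons = as.integer(max_exons),
    intron_range = intron_range, intergenic_range = intergenic_range,
    domain_coverage = domain_coverage, domain_length = domain_length,
    n_terms = as.integer(n_terms), term_rate_range = term_rate_range,
    term_enrich = term_enrich, planted_hotspots = planted_hotspots,
    planted_events = planted_events, plant_tn = plant_tn,
    seed = as.integer(seed)), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic proteome with gene models and genome
#'
#' Samples protein lengths from a log-normal, residues i.i.d. from the
#' configured composition, back-translates each protein into a CDS by
#' sampling synonymous codons uniformly (plus a random stop codon), splits
#' the CDS into 1..max_exons exon blocks separated by short introns, and
#' assembles the genes (alternating strands, so splice/strand logic is
#' genuinely exercised) into two chromosomes with random intergenic
#' spacers. Proteins referenced by planted hotspots are guaranteed enough
#' S/T/Y residues inside the window.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_proteome` with `proteome`, `models`, `cds`
#'   and `genome`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cba <- codons_by_aa()
  with_seed(config$seed, {
    n <- config$n_proteins
    lens <- pmax(config$min_length,
                 round(stats::rlnorm(n, config$length_meanlog,
                                     config$length_sdlog)))
    ph <- config$planted_hotspots
    if (!is.null(ph)) {
      for (i in seq_len(nrow(ph))) {
        need <- ph$start[i] + ph$winsize[i] - 1L
        lens[ph$protein[i]] <- max(lens[ph$protein[i]], need)
      }
    }
    aa_all <- sample(names(config$composition), sum(lens), replace = TRUE,
                     prob = config$composition)
    idx <- rep(seq_len(n), lens)
    proteins <- vapply(split(aa_all, idx), paste, "", collapse = "")
    names(proteins) <- sprintf("P%03d", seq_len(n))
    # guarantee S/T/Y supply inside planted windows
    if (!is.null(ph)) {
      for (i in seq_len(nrow(ph))) {
        p <- ph$protein[i]
        win <- ph$start[i]:(ph$start[i] + ph$winsize[i] - 1L)
        chars <- strsplit(proteins[[p]], "")[[1]]
        sty_in <- win[chars[win] %in% c("S", "T", "Y")]
        deficit <- ph$n_sites[i] - length(sty_in)
        if (deficit > 0L) {
          non_sty <- win[!(chars[win] %in% c("S", "T", "Y"))]
          fix <- sample(non_sty, deficit)
          chars[fix] <- "S"
          proteins[p] <- paste(chars, collapse = "")
        }
      }
    }
    # back-translate all residues at once (uniform synonymous codon choice)
    codon_pool <- unlist(cba, use.names = FALSE)
    pool_off <- cumsum(lengths(cba)) - lengths(cba)
    names(pool_off) <- names(cba)
    n_codons <- lengths(cba)
    aa_final <- unlist(strsplit(unname(proteins), ""), use.names = FALSE)
    pick <- floor(stats::runif(length(aa_final)) * n_codons[aa_final]) + 1L
    codons_all <- codon_pool[pool_off[aa_final] + pick]
    codon_split <- split(codons_all, rep(seq_len(n), nchar(proteins)))
    # build gene structures
    models <- list()
    cds_list <- list()
    chroms <- c(chr1 = "", chr2 = "")
    cursors <- c(chr1 = 0L, chr2 = 0L)
    parts <- list(chr1 = list(), chr2 = list())
    for (i in seq_len(n)) {
      cds <- paste(c(codon_split[[i]], sample(c("TAA", "TAG", "TGA"), 1L)),
                   collapse = "")
      L_nt <- nchar(cds)
      n_ex <- sample.int(config$max_exons, 1L)
      cuts <- if (n_ex > 1L) sort(sample.int(L_nt - 1L, n_ex - 1L)) else integer(0)
      ex_bounds <- cbind(c(1L, cuts + 1L), c(cuts, L_nt))  # transcript coords
      intron_lens <- if (n_ex > 1L) {
        sample(seq(config$intron_range[1L], config$intron_range[2L]),
               n_ex - 1L, replace = TRUE)
      } else integer(0)
      # transcript-orientation gene segment with introns inserted
      seg_pieces <- character(0)
      tx_spans <- matrix(0L, n_ex, 2L)  # exon spans within the segment
      cursor <- 0L
      for (e in seq_len(n_ex)) {
        ex_seq <- substring(cds, ex_bounds[e, 1L], ex_bounds[e, 2L])
        tx_spans[e, ] <- c(cursor + 1L, cursor + nchar(ex_seq))
        seg_pieces <- c(seg_pieces, ex_seq)
        cursor <- cursor + nchar(ex_seq)
        if (e < n_ex) {
          seg_pieces <- c(seg_pieces, random_dna(intron_lens[e]))
          cursor <- cursor + intron_lens[e]
        }
      }
      seg <- paste(seg_pieces, collapse = "")
      M <- nchar(seg)
      strand <- if (i %% 2L == 0L) "-" else "+"
      chrom <- if (i <= ceiling(n / 2)) "chr1" else "chr2"
      gap <- sample(seq(config$intergenic_range[1L],
                        config$intergenic_range[2L]), 1L)
      seg_start <- cursors[[chrom]] + gap + 1L
      if (strand == "+") {
        exons <- cbind(seg_start + tx_spans[, 1L] - 1L,
                       seg_start + tx_spans[, 2L] - 1L)
        placed <- seg
      } else {
        exons <- cbind(seg_start + M - tx_spans[, 2L],
                       seg_start + M - tx_spans[, 1L])
        placed <- revcomp(seg)
      }
      parts[[chrom]][[length(parts[[chrom]]) + 1L]] <- random_dna(gap)
      parts[[chrom]][[length(parts[[chrom]]) + 1L]] <- placed
      cursors[[chrom]] <- seg_start + M - 1L
      gid <- sprintf("G%03d", i)
      models[[gid]] <- gene_model(gid, chrom, strand, exons,
                                  protein_id = names(proteins)[i])
      cds_list[[gid]] <- cds
    }
    for (chrom in names(parts)) {
      tail_gap <- random_dna(60L)
      chroms[[chrom]] <- paste(c(unlist(parts[[chrom]]), tail_gap),
                               collapse = "")
    }
    structure(list(proteome = proteins, models = models, cds = cds_list,
                   genome = chroms, config = config),
              class = "sim_proteome")
  })
}

#' @export
print.sim_proteome <- function(x, ...) {
  cat(sprintf("<sim_proteome> %d proteins (%d residues) on %d chromosome(s)\n",
              length(x$proteome), sum(nchar(x$proteome)), length(x$genome)))
  invisible(x)
}

#' Generate phosphosites for a synthetic proteome
#'
#' Experimental mode phosphorylates each S/T/Y independently with its
#' residue-specific probability and forces `n_sites` phosphosites into
#' every planted hotspot window. Predicted mode scores all S/T/Y with the
#' supplied scorer and keeps positions with score >= 1 as high-confidence
#' predicted sites.
#'
#' @param sim A [generate_proteome()] result.
#' @param config A [sim_config()].
#' @param mode `"experimental"` or `"predicted"`.
#' @param scorer Scorer used in predicted mode.
#' @return Phosphosite data.frame.
#' @export
generate_sites <- function(sim, config, mode = c("experimental", "predicted"),
                           scorer = toy_scorer) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "sim_proteome"))
  if (mode == "predicted") {
    sc <- score_proteome(sim$proteome, scorer)
    out <- sc[sc$score >= 1, , drop = FALSE]
    if (nrow(out) > 0L) out$status <- "predicted"
    else out$status <- character(0)
    rownames(out) <- NULL
    return(out[c("protein_id", "position", "residue", "status", "score")])
  }
  with_seed(config$seed + 1L, {
    probs <- config$phospho_probs
    rows <- list()
    ph <- config$planted_hotspots
    for (i in seq_along(sim$proteome)) {
      pid <- names(sim$proteome)[i]
      chars <- strsplit(sim$proteome[[i]], "")[[1]]
      sel <- logical(length(chars))
      for (r in c("S", "T", "Y")) {
        pos <- which(chars == r)
        sel[pos] <- stats::runif(length(pos)) < probs[[r]]
      }
      if (!is.null(ph)) {
        for (k in which(ph$protein == i)) {
          win <- ph$start[k]:(ph$start[k] + ph$winsize[k] - 1L)
          sty_in <- win[chars[win] %in% c("S", "T", "Y")]
          already <- sum(sel[sty_in])
          need <- ph$n_sites[k] - already
          if (need > 0L) {
            cand <- sty_in[!sel[sty_in]]
            sel[sample(cand, need)] <- TRUE
          }
        }
      }
      pos <- which(sel)
      if (length(pos) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, position = pos, residue = chars[pos],
          status = "experimental", score = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(protein_id = character(0), position = integer(0),
                        residue = character(0), status = character(0),
                        score = numeric(0), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Score every S/T/Y residue of a proteome
#'
#' @param proteome Named character vector of protein sequences.
#' @param scorer Scoring function.
#' @return data.frame with `protein_id`, `position`, `residue`, `score`.
#' @export
score_proteome <- function(proteome, scorer = toy_scorer) {
  rows <- lapply(names(proteome), function(pid) {
    df <- score_protein(proteome[[pid]], scorer)
    if (nrow(df) == 0L) return(NULL)
    df$protein_id <- pid
    df
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("protein_id", "position", "residue", "score")]
}

# all single-base variants of a codon: data.frame(offset, base, codon, aa)
single_base_variants <- function(codon) {
  out <- list()
  for (k in 1:3) {
    cur <- substring(codon, k, k)
    for (b in setdiff(DNA_BASES, cur)) {
      v <- codon
      substring(v, k, k) <- b
      out[[length(out) + 1L]] <- data.frame(
        offset = k, base = b, codon = v, aa = translate_codons(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# build one SNP row that rewrites CDS position `cds_pos` of `gid` to
# `new_base` (CDS orientation)
snp_for_cds_change <- function(sim, gid, cds_pos, new_base, accession) {
  model <- sim$models[[gid]]
  gpos <- cds_to_genomic(model, cds_pos)
  ref_g <- substring(sim$genome[[model$chrom]], gpos, gpos)
  alt_g <- if (model$strand == "-") complement_base(new_base) else new_base
  data.frame(chrom = model$chrom, pos = gpos, ref = ref_g, alt = alt_g,
             accessions = accession, stringsAsFactors = FALSE)
}

mutate_protein <- function(sequence, pos, new_aa) {
  substring(sequence, pos, pos) <- new_aa
  sequence
}

#' Generate SNPs (background plus engineered gain/loss events)
#'
#' Background SNPs are placed independently at the configured per-coding-base
#' rate with a random alternative allele and accession carriers drawn by the
#' allele-sharing probability (at least one carrier). Planted gain/loss
#' events are engineered by exhaustive search over single-base codon changes
#' (guaranteeing feasibility under the genetic code) and verified against
#' the gain/loss caller so that each planted SNP produces exactly its
#' intended event; each planted event gets its own accession. Optional
#' planted T-to-N substitution excess targets predicted phospho-threonines
#' at a higher rate than other threonines.
#'
#' @param sim A [generate_proteome()] result.
#' @param sites_pred Predicted phosphosite data.frame (needed for planted
#'   events and T-to-N planting; may be NULL otherwise).
#' @param config A [sim_config()].
#' @param scorer Scorer used to verify planted score-based events.
#' @return List with `snps` (SNP data.frame) and `truth` (planted-event
#'   data.frame).
#' @export
generate_snps <- function(sim, sites_pred = NULL, config, scorer = toy_scorer) {
  stopifnot(inherits(sim, "sim_proteome"))
  accs <- sprintf("acc%02d", seq_len(config$n_accessions))
  with_seed(config$seed + 2L, {
    snp_rows <- list()
    # ---- background SNPs
    if (config$snp_rate > 0) {
      for (gid in names(sim$models)) {
        model <- sim$models[[gid]]
        L_nt <- model$cds_length
        n_snp <- stats::rbinom(1L, L_nt, config$snp_rate)
        if (n_snp == 0L) next
        cds_pos <- sample.int(L_nt, n_snp)
        for (cp in cds_pos) {
          ref_cds <- substring(sim$cds[[gid]], cp, cp)
          alt_cds <- sample(setdiff(DNA_BASES, ref_cds), 1L)
          carriers <- accs[stats::runif(length(accs)) < config$allele_share]
          if (length(carriers) == 0L) carriers <- sample(accs, 1L)
          snp_rows[[length(snp_rows) + 1L]] <-
            snp_for_cds_change(sim, gid, cp, alt_cds,
                               paste(carriers, collapse = ","))
        }
      }
    }
    # ---- planted T->N excess at predicted phospho-threonines
    if (!is.null(config$plant_tn)) {
      tn <- plant_tn_snps(sim, sites_pred, config)
      snp_rows <- c(snp_rows, tn)
    }
    # ---- planted gain/loss events
    truth <- data.frame(protein_id = character(0), position = integer(0),
                        accession = character(0), kind = character(0),
                        status = integer(0), stringsAsFactors = FALSE)
    if (!is.null(config$planted_events)) {
      pe <- plant_events(sim, sites_pred, config, scorer, accs)
      snp_rows <- c(snp_rows, pe$snps)
      truth <- pe$truth
    }
    snps <- if (length(snp_rows) > 0L) {
      out <- do.call(rbind, snp_rows)
      rownames(out) <- NULL
      out
    } else {
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), accessions = character(0),
                 stringsAsFactors = FALSE)
    }
    list(snps = snps, truth = truth)
  })
}

# T->N planting helper: predicted pT sites vs other T positions; only
# codons ACT/ACC can reach asparagine by a single base change, so the
# candidate sets are restricted symmetrically in both classes
plant_tn_snps <- function(sim, sites_pred, config) {
  rate_site <- config$plant_tn$rate_site
  rate_bg <- config$plant_tn$rate_background
  prot2gene <- stats::setNames(names(sim$models),
                               vapply(sim$models, `[[`, "", "protein_id"))
  site_key <- paste(sites_pred$protein_id, sites_pred$position)
  rows <- list()
  for (pid in names(sim$proteome)) {
    gid <- prot2gene[[pid]]
    chars <- strsplit(sim$proteome[[pid]], "")[[1]]
    tpos <- which(chars == "T")
    for (p in tpos) {
      codon <- substring(sim$cds[[gid]], 3L * p - 2L, 3L * p)
      if (!(codon %in% c("ACT", "ACC"))) next
      is_site <- paste(pid, p) %in% site_key
      rate <- if (is_site) rate_site else rate_bg
      if (stats::runif(1L) < rate) {
        # ACx -> AAx : position 2 C->A gives asparagine
        rows[[length(rows) + 1L]] <-
          snp_for_cds_change(sim, gid, 3L * p - 1L, "A", "acc01")
      }
    }
  }
  rows
}

# engineer the requested gain/loss events by search over single-base codon
# changes; each candidate is verified against the caller before acceptance
plant_events <- function(sim, sites_pred, config, scorer, accs) {
  req <- config$planted_events
  want <- rep(names(req), req)
  snps <- list()
  truth <- list()
  used_positions <- character(0)  # "(pid) (pos)" keys already used
  used_proteins_acc <- character(0)
  prot2gene <- stats::setNames(names(sim$models),
                               vapply(sim$models, `[[`, "", "protein_id"))
  acc_i <- 0L
  verify <- function(pid, snp_row, expected) {
    models <- sim$models[prot2gene[[pid]]]
    eff <- map_snp_effects(snp_row, models, sim$genome)
    ev <- call_predicted_gain_loss(sites_pred, eff, sim$proteome, scorer)
    nrow(ev) == 1L && ev$kind == expected$kind &&
      ev$status == expected$status && ev$position == expected$position &&
      ev$protein_id == pid
  }
  for (type in want) {
    acc_i <- acc_i + 1L
    accession <- accs[(acc_i - 1L) %% length(accs) + 1L]
    planted <- FALSE
    if (type == "loss2") {
      for (si in seq_len(nrow(sites_pred))) {
        pid <- sites_pred$protein_id[si]
        pos <- sites_pred$position[si]
        if (paste(pid, pos) %in% used_positions) next
        gid <- prot2gene[[pid]]
        codon <- substring(sim$cds[[gid]], 3L * pos - 2L, 3L * pos)
        v <- single_base_variants(codon)
        v <- v[!(v$aa %in% c("S", "T", "Y", "*")), , drop = FALSE]
        for (k in seq_len(nrow(v))) {
          snp <- snp_for_cds_change(sim, gid, 3L * (pos - 1L) + v$offset[k],
                                    v$base[k], accession)
          exp_ev <- list(kind = "loss", status = 2L, position = pos)
          if (verify(pid, snp, exp_ev)) {
            snps[[length(snps) + 1L]] <- snp
            truth[[length(truth) + 1L]] <- data.frame(
              protein_id = pid, position = pos, accession = accession,
              kind = "loss", status = 2L, stringsAsFactors = FALSE)
            used_positions <- c(used_positions, paste(pid, pos))
            planted <- TRUE
            break
          }
        }
        if (planted) break
      }
    } else if (type == "loss1") {
      for (si in seq_len(nrow(sites_pred))) {
        pid <- sites_pred$protein_id[si]
        pos <- sites_pred$position[si]
        if (paste(pid, pos) %in% used_positions) next
        gid <- prot2gene[[pid]]
        seqs <- sim$proteome[[pid]]
        for (d in c(1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L, -5L, 6L, -6L)) {
          np <- pos + d
          if (np < 1L || np > nchar(seqs)) next
          codon <- substring(sim$cds[[gid]], 3L * np - 2L, 3L * np)
          v <- single_base_variants(codon)
          v <- v[v$aa != translate_codons(codon) & v$aa != "*", ,
                 drop = FALSE]
          found <- FALSE
          for (k in seq_len(nrow(v))) {
            mut <- mutate_protein(seqs, np, v$aa[k])
            if (scorer(mut, pos) > -1) next
            snp <- snp_for_cds_change(sim, gid, 3L * (np - 1L) + v$offset[k],
                                      v$base[k], accession)
            exp_ev <- list(kind = "loss", status = 1L, position = pos)
            if (verify(pid, snp, exp_ev)) {
              snps[[length(snps) + 1L]] <- snp
              truth[[length(truth) + 1L]] <- data.frame(
                protein_id = pid, position = pos, accession = accession,
                kind = "loss", status = 1L, stringsAsFactors = FALSE)
              used_positions <- c(used_positions, paste(pid, pos))
              planted <- TRUE
              found <- TRUE
              break
            }
          }
          if (found) break
        }
        if (planted) break
      }
    } else if (type == "gain2") {
      for (pid in names(sim$proteome)) {
        gid <- prot2gene[[pid]]
        seqs <- sim$proteome[[pid]]
        chars <- strsplit(seqs, "")[[1]]
        cand <- which(!(chars %in% c("S", "T", "Y")))
        for (pos in cand) {
          if (paste(pid, pos) %in% used_positions) next
          codon <- substring(sim$cds[[gid]], 3L * pos - 2L, 3L * pos)
          v <- single_base_variants(codon)
          v <- v[v$aa %in% c("S", "T", "Y"), , drop = FALSE]
          found <- FALSE
          for (k in seq_len(nrow(v))) {
            mut <- mutate_protein(seqs, pos, v$aa[k])
            if (scorer(mut, pos) < 1) next
            snp <- snp_for_cds_change(sim, gid, 3L * (pos - 1L) + v$offset[k],
                                      v$base[k], accession)
            exp_ev <- list(kind = "gain", status = 2L, position = pos)
            if (verify(pid, snp, exp_ev)) {
              snps[[length(snps) + 1L]] <- snp
              truth[[length(truth) + 1L]] <- data.frame(
                protein_id = pid, position = pos, accession = accession,
                kind = "gain", status = 2L, stringsAsFactors = FALSE)
              used_positions <- c(used_positions, paste(pid, pos))
              planted <- TRUE
              found <- TRUE
              break
            }
          }
          if (found) break
        }
        if (planted) break
      }
    } else if (type == "gain1") {
      site_key <- paste(sites_pred$protein_id, sites_pred$position)
      for (pid in names(sim$proteome)) {
        gid <- prot2gene[[pid]]
        seqs <- sim$proteome[[pid]]
        chars <- strsplit(seqs, "")[[1]]
        cand <- which(chars %in% c("S", "T", "Y"))
        cand <- cand[!(paste(pid, cand) %in% c(site_key, used_positions))]
        for (pos in cand) {
          if (scorer(seqs, pos) > -1) next
          found <- FALSE
          for (d in c(1L, -1L, 2L, -2L, 3L, -3L)) {
            np <- pos + d
            if (np < 1L || np > nchar(seqs)) next
            if (chars[np] %in% c("S", "T", "Y")) next  # keep context simple
            codon <- substring(sim$cds[[gid]], 3L * np - 2L, 3L * np)
            v <- single_base_variants(codon)
            v <- v[v$aa != translate_codons(codon) &
                     !(v$aa %in% c("S", "T", "Y", "*")), , drop = FALSE]
            for (k in seq_len(nrow(v))) {
              mut <- mutate_protein(seqs, np, v$aa[k])
              if (scorer(mut, pos) < 1) next
              snp <- snp_for_cds_change(sim, gid, 3L * (np - 1L) + v$offset[k],
                                        v$base[k], accession)
              exp_ev <- list(kind = "gain", status = 1L, position = pos)
              if (verify(pid, snp, exp_ev)) {
                snps[[length(snps) + 1L]] <- snp
                truth[[length(truth) + 1L]] <- data.frame(
                  protein_id = pid, position = pos, accession = accession,
                  kind = "gain", status = 1L, stringsAsFactors = FALSE)
                used_positions <- c(used_positions, paste(pid, pos))
                planted <- TRUE
                found <- TRUE
                break
              }
            }
            if (found) break
          }
          if (found) break
        }
        if (planted) break
      }
    } else {
      stop("unknown planted event type '", type, "'", call. = FALSE)
    }
    if (!planted) {
      stop("could not engineer planted event of type '", type,
           "' under the genetic code and scorer", call. = FALSE)
    }
  }
  list(snps = snps,
       truth = if (length(truth) > 0L) do.call(rbind, truth)
               else data.frame(protein_id = character(0),
                               position = integer(0),
                               accession = character(0),
                               kind = character(0), status = integer(0),
                               stringsAsFactors = FALSE))
}

#' Generate domain and term annotations
#'
#' Domains cover a configurable fraction of each protein (split into a few
#' non-overlapping blocks placed at random); terms are assigned per protein
#' with per-term base rates, optionally boosted for one term in a designated
#' protein subset.
#'
#' @param sim A [generate_proteome()] result.
#' @param config A [sim_config()].
#' @return List with `domains` and `terms` data.frames.
#' @export
generate_domains_terms <- function(sim, config) {
  stopifnot(inherits(sim, "sim_proteome"))
  with_seed(config$seed + 3L, {
    drows <- list()
    if (config$domain_coverage > 0) {
      mean_dl <- mean(config$domain_length)
      for (pid in names(sim$proteome)) {
        L <- nchar(sim$proteome[[pid]])
        d_total <- round(config$domain_coverage * L)
        if (d_total < 1L) next
        k <- max(1L, round(d_total / mean_dl))
        base_len <- d_total %/% k
        lens <- rep(base_len, k)
        lens[seq_len(d_total - base_len * k)] <- base_len + 1L
        free <- L - d_total
        gw <- stats::runif(k + 1L)
        gaps <- floor(gw / sum(gw) * free)
        gaps[1L] <- gaps[1L] + (free - sum(gaps))
        pos <- 0L
        for (j in seq_len(k)) {
          pos <- pos + gaps[j]
          drows[[length(drows) + 1L]] <- data.frame(
            protein_id = pid, start = pos + 1L, end = pos + lens[j],
            domain_id = sprintf("DOM%02d", sample.int(15L, 1L)),
            stringsAsFactors = FALSE)
          pos <- pos + lens[j]
        }
      }
    }
    domains <- if (length(drows) > 0L) do.call(rbind, drows) else
      data.frame(protein_id = character(0), start = integer(0),
                 end = integer(0), domain_id = character(0),
                 stringsAsFactors = FALSE)
    rownames(domains) <- NULL
    # terms
    trows <- list()
    if (config$n_terms > 0L) {
      term_ids <- sprintf("TERM%02d", seq_len(config$n_terms))
      rates <- stats::runif(config$n_terms, config$term_rate_range[1L],
                            config$term_rate_range[2L])
      te <- config$term_enrich
      for (pid in names(sim$proteome)) {
        r <- rates
        if (!is.null(te) && pid %in% te$proteins) {
          r[te$term] <- pmin(1, r[te$term] * te$factor)
        }
        hit <- stats::runif(config$n_terms) < r
        if (any(hit)) {
          trows[[length(trows) + 1L]] <- data.frame(
            protein_id = pid, term_id = term_ids[hit],
            stringsAsFactors = FALSE)
        }
      }
    }
    terms <- if (length(trows) > 0L) do.call(rbind, trows) else
      data.frame(protein_id = character(0), term_id = character(0),
                 stringsAsFactors = FALSE)
    rownames(terms) <- NULL
    list(domains = domains, terms = terms)
  })
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates [generate_proteome()], [generate_sites()] (experimental and
#' predicted), [generate_snps()] and [generate_domains_terms()] into one
#' reproducible dataset with planted ground truth.
#'
#' @param config A [sim_config()].
#' @param scorer Prediction scorer.
#' @return Object of class `phospho_sim`.
#' @export
simulate_dataset <- function(config, scorer = toy_scorer) {
  sim <- generate_proteome(config)
  sites_exp <- generate_sites(sim, config, "experimental")
  sites_pred <- generate_sites(sim, config, "predicted", scorer)
  sv <- generate_snps(sim, sites_pred, config, scorer)
  dt <- generate_domains_terms(sim, config)
  structure(list(proteome = sim$proteome, models = sim$models,
                 cds = sim$cds, genome = sim$genome,
                 sites_experimental = sites_exp,
                 sites_predicted = sites_pred,
                 snps = sv$snps, truth = sv$truth,
                 domains = dt$domains, terms = dt$terms,
                 config = config), class = "phospho_sim")
}

#' @export
print.phospho_sim <- function(x, ...) {
  cat(sprintf(paste0("<phospho_sim> %d proteins, %d experimental + %d ",
                     "predicted sites, %d SNP record(s), %d planted event(s)\n"),
              length(x$proteome), nrow(x$sites_experimental),
              nrow(x$sites_predicted), nrow(x$snps), nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits genome.fasta, genes.gff3, proteome.fasta, sites.tsv (both
#' statuses), snps.tsv, domains.tsv, terms.tsv and truth.json.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_fasta(sim$proteome, file.path(dir, "proteome.fasta"))
  write_gene_models(sim$models, file.path(dir, "genes.gff3"))
  write_tsv(rbind(sim$sites_experimental, sim$sites_predicted),
            file.path(dir, "sites.tsv"))
  write_tsv(sim$snps, file.path(dir, "snps.tsv"))
  write_tsv(sim$domains, file.path(dir, "domains.tsv"))
  write_tsv(sim$terms, file.path(dir, "terms.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows")
  invisible(dir)
}
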