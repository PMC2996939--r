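# context helpers: craft sequences with controlled toy-scorer scores
high_ctx <- function(central) {
  # R/K-rich context pushes the raw score far positive
  paste0("AAAAAA", "RKRKRR", central, "RRKRKR", "AAAAAA")
}
low_ctx <- function(central) {
  paste0("AAAAAA", "LELELL", central, "LLELEL", "AAAAAA")
}

test_that("toy scorer is deterministic, bounded and reaches both confidence regimes", {
  s_hi <- high_ctx("S")
  s_lo <- low_ctx("S")
  expect_identical(toy_scorer(s_hi, 13), toy_scorer(s_hi, 13))
  expect_gt(toy_scorer(s_hi, 13), 1)
  expect_lt(toy_scorer(s_lo, 13), -1)
  expect_true(abs(toy_scorer(s_hi, 13)) < 3)
  expect_error(toy_scorer("MAAAA", 2), "central S/T/Y")
  expect_error(toy_scorer("MS", 7), "outside")
  # edge positions are defined (out-of-protein context contributes zero)
  expect_silent(toy_scorer("SAAAA", 1))
})

test_that("experimental losses cover any exchange, with a strict non-STY mode", {
  sites <- data.frame(protein_id = "P1", position = 2L, residue = "S",
                      status = "experimental", score = NA_real_)
  eff <- data.frame(protein_id = "P1", protein_pos = 2L, ref_aa = "S",
                    alt_aa = c("N", "T"), effect_class = "nonsynonymous",
                    accessions = c("Bur-0", "accA,accB"),
                    stringsAsFactors = FALSE)
  ev <- call_experimental_losses(sites, eff)
  expect_identical(nrow(ev), 3L)  # one per accession
  expect_setequal(ev$accession, c("Bur-0", "accA", "accB"))
  expect_setequal(unique(ev$alt_residue), c("N", "T"))
  expect_true(all(ev$status == 2L))
  # strict mode drops the S -> T exchange
  strict <- call_experimental_losses(sites, eff, strict = TRUE)
  expect_identical(nrow(strict), 1L)
  expect_identical(strict$alt_residue, "N")
  # synonymous SNP at the site yields no event
  syn <- data.frame(protein_id = "P1", protein_pos = 2L, ref_aa = "S",
                    alt_aa = "S", effect_class = "synonymous",
                    accessions = "accA", stringsAsFactors = FALSE)
  expect_identical(nrow(call_experimental_losses(sites, syn)), 0L)
})

test_that("predicted-site calls follow the score and substitution rules", {
  seq_hi <- high_ctx("S")     # site at 13, score > 1
  proteome <- c(P1 = seq_hi)
  ref_score <- toy_scorer(seq_hi, 13)
  sites <- data.frame(protein_id = "P1", position = 13L, residue = "S",
                      status = "predicted", score = ref_score)
  mk_eff <- function(pos, ref, alt, cls = "nonsynonymous", acc = "accA") {
    data.frame(protein_id = "P1", protein_pos = pos, ref_aa = ref,
               alt_aa = alt, effect_class = cls, accessions = acc,
               stringsAsFactors = FALSE)
  }
  # status-2 loss: central S -> P
  ev <- call_predicted_gain_loss(sites, mk_eff(13, "S", "P"), proteome)
  expect_identical(ev$kind, "loss")
  expect_identical(ev$status, 2L)
  # central S -> T (still phosphorylatable): no call
  ev <- call_predicted_gain_loss(sites, mk_eff(13, "S", "T"), proteome)
  expect_identical(nrow(ev), 0L)
  # status-1 loss: enough neighbours flipped to L to drive the score <= -1
  eff1 <- rbind(mk_eff(12, "R", "L"), mk_eff(14, "R", "L"),
                mk_eff(11, "R", "L"), mk_eff(15, "R", "L"))
  mut <- apply_substitutions(proteome[["P1"]], eff1)
  expect_lte(toy_scorer(mut, 13), -1)  # the rewritten context must flip
  ev <- call_predicted_gain_loss(sites, eff1, proteome)
  expect_identical(ev$kind, "loss")
  expect_identical(ev$status, 1L)
  expect_identical(ev$position, 13L)
  expect_lte(ev$alt_score, -1)
  # neighbour substitution that barely moves the score: still >= 1, no call
  eff_weak <- mk_eff(8, "K", "R")
  ev <- call_predicted_gain_loss(sites, eff_weak, proteome)
  expect_identical(nrow(ev), 0L)
  # status-2 gain: A -> S in a strong context scores >= 1
  no_sites <- sites[0, ]
  eff_gain <- mk_eff(7, "R", "S")
  ev <- call_predicted_gain_loss(no_sites, eff_gain, proteome)
  expect_identical(ev$kind, "gain")
  expect_identical(ev$status, 2L)
  expect_gte(ev$alt_score, 1)
  # same change in a weak context: no call
  weak <- c(P2 = paste0("AAAAAA", "AAAAAA", "A", "AAAAAA", "AAAAAA"))
  eff_weak_gain <- data.frame(protein_id = "P2", protein_pos = 13L,
                              ref_aa = "A", alt_aa = "S",
                              effect_class = "nonsynonymous",
                              accessions = "accA", stringsAsFactors = FALSE)
  ev <- call_predicted_gain_loss(no_sites, eff_weak_gain, weak)
  expect_identical(nrow(ev), 0L)
})

test_that("score thresholds 1 and -1 are inside the high-confidence regions", {
  # scorer stub with exact boundary values
  stub <- function(value) function(sequence, position) value
  proteome <- c(P1 = high_ctx("S"))
  sites <- data.frame(protein_id = "P1", position = 13L, residue = "S",
                      status = "predicted", score = 1)
  eff <- data.frame(protein_id = "P1", protein_pos = 12L, ref_aa = "R",
                    alt_aa = "L", effect_class = "nonsynonymous",
                    accessions = "accA", stringsAsFactors = FALSE)
  # alt score exactly -1 counts as a loss (inclusive threshold)
  ev <- call_predicted_gain_loss(sites, eff, proteome, scorer = stub(-1))
  expect_identical(ev$kind, "loss")
  # alt score just above -1 is no call
  ev <- call_predicted_gain_loss(sites, eff, proteome, scorer = stub(-0.999))
  expect_identical(nrow(ev), 0L)
  # gain at exactly 1
  eff_gain <- data.frame(protein_id = "P1", protein_pos = 7L, ref_aa = "R",
                         alt_aa = "S", effect_class = "nonsynonymous",
                         accessions = "accA", stringsAsFactors = FALSE)
  ev <- call_predicted_gain_loss(sites[0, ], eff_gain, proteome,
                                 scorer = stub(1))
  expect_identical(ev$kind, "gain")
})

test_that("no event is ever emitted for synonymous substitutions", {
  sim <- shared_sim()
  eff <- map_snp_effects(sim$snps, sim$models, sim$genome)
  syn_only <- eff[eff$effect_class == "synonymous", , drop = FALSE]
  expect_identical(nrow(call_experimental_losses(sim$sites_experimental,
                                                 syn_only)), 0L)
  expect_identical(nrow(call_predicted_gain_loss(sim$sites_predicted,
                                                 syn_only, sim$proteome)), 0L)
})

test_that("event summary counts distinct proteins and statuses", {
  ev <- data.frame(protein_id = c("P1", "P1", "P2", "P3"),
                   position = 1:4, accession = "a",
                   kind = c("loss", "loss", "loss", "gain"),
                   status = c(2L, 2L, 1L, 2L),
                   stringsAsFactors = FALSE)
  s <- summarize_gain_loss(ev)
  expect_identical(s$n_loss_proteins, 2L)
  expect_identical(s$n_gain_proteins, 1L)
  expect_identical(as.integer(s$by_status["loss", "2"]), 2L)
  expect_identical(as.integer(s$by_status["loss", "1"]), 1L)
})

test_that("status-1 events keep the central residue; status-2 events change it", {
  cfg <- sim_config(n_proteins = 40, snp_rate = 0,
                    planted_events = c(loss2 = 2, loss1 = 2, gain2 = 2,
                                       gain1 = 2),
                    seed = 77)
  sim <- generate_proteome(cfg)
  pred <- generate_sites(sim, cfg, "predicted")
  sv <- generate_snps(sim, pred, cfg)
  eff <- map_snp_effects(sv$snps, sim$models, sim$genome)
  ev <- call_predicted_gain_loss(pred, eff, sim$proteome)
  s1 <- ev[ev$status == 1L, ]
  s2 <- ev[ev$status == 2L & ev$kind == "loss", ]
  expect_true(all(s1$ref_residue == s1$alt_residue))
  expect_true(all(s2$ref_residue != s2$alt_residue))
})
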