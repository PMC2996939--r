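test_that("residue proportions reproduce the printed experimental split", {
  s <- data.frame(residue = rep(c("S", "T", "Y"), c(5078, 1482, 618)))
  pr <- residue_proportions(s)
  expect_equal(pr$percent, c(100 * 5078 / 7178, 100 * 1482 / 7178,
                             100 * 618 / 7178))
  expect_identical(pr$display, c(70.7, 20.6, 8.6))
  expect_equal(round(pr$percent, 2), c(70.74, 20.65, 8.61))
  pr3 <- residue_proportions(data.frame(residue = c("S", "T", "Y")))
  expect_identical(pr3$display, c(33.3, 33.3, 33.3))
  pr1 <- residue_proportions(data.frame(residue = rep("S", 10)))
  expect_identical(pr1$percent, c(100, 0, 0))
  expect_error(residue_proportions(data.frame(residue = character(0))),
               "empty")
})

test_that("domain location uses inclusive boundaries and handles missing domains", {
  sites <- data.frame(protein_id = c("P1", "P1", "P1", "P2"),
                      position = c(10L, 20L, 21L, 5L),
                      residue = c("S", "S", "T", "Y"))
  domains <- data.frame(protein_id = "P1", start = 10L, end = 20L,
                        domain_id = "D1")
  out <- domain_location_fraction(sites, domains)
  # boundary positions 10 and 20 are inside; 21 outside; P2 has no domains
  expect_identical(out$n_inside[out$residue == "S"], 2L)
  expect_identical(out$n_inside[out$residue == "T"], 0L)
  expect_identical(out$n_inside[out$residue == "Y"], 0L)
  expect_equal(out$fraction_inside[out$residue == "all"], 0.5)
})

test_that("uniformly placed sites land inside domains at the coverage rate", {
  set.seed(55)
  proteome <- stats::setNames(
    vapply(1:40, function(i) paste(sample(c("S", "A"), 200, TRUE), collapse = ""), ""),
    sprintf("P%02d", 1:40))
  # domains covering 30% of each protein
  domains <- do.call(rbind, lapply(names(proteome), function(pid) {
    data.frame(protein_id = pid, start = 71L, end = 130L, domain_id = "D")
  }))
  sites <- do.call(rbind, lapply(names(proteome), function(pid) {
    chars <- strsplit(proteome[[pid]], "")[[1]]
    pos <- which(chars == "S")
    pos <- pos[stats::runif(length(pos)) < 0.5]
    if (length(pos) == 0) return(NULL)
    data.frame(protein_id = pid, position = pos, residue = "S")
  }))
  out <- domain_location_fraction(sites, domains)
  expect_equal(out$fraction_inside[out$residue == "all"], 0.3,
               tolerance = 0.1)
})

test_that("phosphosite count null conserves the expected total exactly", {
  proteome <- c(A = strrep("S", 10), B = paste0(strrep("T", 20)))
  sites <- data.frame(protein_id = c(rep("A", 2), rep("B", 4)),
                      position = c(1:2, 1:4),
                      residue = c(rep("S", 2), rep("T", 4)))
  null <- expected_count_distribution(proteome, sites)
  expect_equal(null$p, 6 / 30)
  expect_equal(null$per_protein$expected, c(2, 4))
  expect_equal(sum(null$per_protein$expected), 6)
  expect_equal(sum(null$histogram$expected * null$histogram$count),
               sum(null$histogram$observed * null$histogram$count))
  expect_error(expected_count_distribution(c(A = "MKLV"), sites[0, ]),
               "no S/T/Y")
})

test_that("constant-probability sites fit the binomial null; a loaded protein shows the long tail", {
  cfg <- sim_config(n_proteins = 120, phospho_probs = c(S = 0.08, T = 0.08,
                                                        Y = 0.08),
                    seed = 606)
  sim <- generate_proteome(cfg)
  sites <- generate_sites(sim, cfg)
  null <- expected_count_distribution(sim$proteome, sites)
  h <- null$histogram
  # pool bins to expected counts >= 5 and chi-square goodness of fit
  ord <- order(h$count)
  h <- h[ord, ]
  grp <- cumsum(h$expected) %/% 5
  obs <- tapply(h$observed, grp, sum)
  expc <- tapply(h$expected, grp, sum)
  keep <- expc > 0
  stat <- sum((obs[keep] - expc[keep])^2 / expc[keep])
  pval <- stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.05)
  # one protein carrying every site exceeds its expectation (long tail)
  two <- c(P = strrep("SA", 50), Q = strrep("SA", 50))
  loaded <- data.frame(protein_id = "P", position = seq(1, 39, 2),
                       residue = "S")
  nl <- expected_count_distribution(two, loaded)
  expect_gt(nl$per_protein$observed[1], nl$per_protein$expected[1])
})

test_that("fisher_exact matches the enumeration oracle and the stats reference", {
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2))$p, 1)
  ft <- fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(ft$p, 34 / 70, tolerance = 1e-12)
  expect_equal(ft$odds_ratio, 9)
  ft0 <- fisher_exact(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))
  expect_equal(ft0$p, 2 / 252, tolerance = 1e-12)
  expect_true(ft0$corrected)
  # degenerate margin
  ftd <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_identical(ftd$p, 1)
  expect_true(ftd$degenerate)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  # randomized agreement with the oracle and with stats::fisher.test
  set.seed(31)
  for (i in 1:300) {
    tab <- matrix(stats::rpois(4, 4), 2)
    if (sum(tab) > 60 || sum(tab) == 0) next
    got <- fisher_exact(tab)
    expect_equal(got$p, oracle_fisher_p(tab), tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(got$p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("BH adjustment is a step-up procedure, order-invariant, with q >= p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(8)
  p <- stats::runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("substitution enrichment recovers a planted T-to-N excess and reports never-observed pairs", {
  cfg <- sim_config(n_proteins = 250, snp_rate = 0,
                    plant_tn = list(rate_site = 0.5, rate_background = 0.1),
                    seed = 911)
  sim <- generate_proteome(cfg)
  pred <- generate_sites(sim, cfg, "predicted")
  sv <- generate_snps(sim, pred, cfg)
  eff <- map_snp_effects(sv$snps, sim$models, sim$genome)
  res <- substitution_enrichment(pred, eff, sim$proteome,
                                 universe = "phosphoproteins")
  tn <- res[res$from == "T" & res$to == "N", ]
  expect_true(tn$significant)
  expect_identical(tn$direction, "enriched_in_phosphosites")
  # pairs observed in neither class are flagged, not tested
  never <- res[res$never_observed, ]
  expect_gt(nrow(never), 0)
  expect_true(all(is.na(never$p)))
})

test_that("label permutation within residue type gives well-behaved p-values", {
  cfg <- sim_config(n_proteins = 150, snp_rate = 0.004, seed = 777)
  sim <- simulate_dataset(cfg)
  eff <- map_snp_effects(sim$snps, sim$models, sim$genome)
  sites <- sim$sites_experimental
  # permute phospho labels within residue type: sites keep their residue
  # but move to random same-residue positions
  set.seed(1234)
  perm_sites <- do.call(rbind, lapply(split(sites, sites$residue), function(s) {
    res <- s$residue[1]
    pool <- do.call(rbind, lapply(names(sim$proteome), function(pid) {
      pos <- which(strsplit(sim$proteome[[pid]], "")[[1]] == res)
      if (length(pos) == 0) return(NULL)
      data.frame(protein_id = pid, position = pos, stringsAsFactors = FALSE)
    }))
    pick <- pool[sample(nrow(pool), nrow(s)), ]
    data.frame(protein_id = pick$protein_id, position = pick$position,
               residue = res, status = "experimental", score = NA_real_,
               stringsAsFactors = FALSE)
  }))
  res <- substitution_enrichment(perm_sites, eff, sim$proteome,
                                 universe = "phosphoproteins")
  p <- res$p[!res$never_observed]
  expect_gt(length(p), 5)
  # no excess of small p-values relative to uniform (Fisher p-values on
  # discrete tables are conservative, so test the anti-conservative side)
  ks <- suppressWarnings(stats::ks.test(p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.05)
  expect_true(all(res$significant[!res$never_observed] == FALSE))
})
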