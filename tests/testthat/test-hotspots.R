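test_that("window scan counts sites, sums scores and deduplicates by S/T/Y content", {
  seqs <- paste0("SASASASAS", "A", strrep("A", 10))  # STY at 1,3,5,7,9
  sw <- scan_windows(seqs, 10, site_positions = c(1L, 3L, 5L, 7L, 9L))
  expect_identical(sw$score[sw$start == 1], 5)
  # windows 2..11 and 3..12 contain the same S/T/Y set {3,5,7,9}:
  # start 3 must be dropped, start 2 kept
  expect_true(2 %in% sw$start)
  expect_false(3 %in% sw$start)
  # predicted mode sums scores, negatives included
  seqp <- paste0("ASTYA", strrep("A", 10))
  swp <- scan_windows(seqp, 5,
                      scores = data.frame(position = c(2L, 3L, 4L),
                                          score = c(1.2, -0.3, 2.0)))
  expect_equal(swp$score[swp$start == 1], 2.9)
  # protein shorter than the window
  expect_warning(out <- scan_windows("MSA", 10), "shorter")
  expect_identical(nrow(out), 0L)
})

test_that("every reported window score can be recounted from the site table", {
  sim <- shared_sim()
  sites <- sim$sites_experimental
  for (pid in utils::head(names(sim$proteome), 10)) {
    pos <- sites$position[sites$protein_id == pid]
    sw <- scan_windows(sim$proteome[[pid]], 10, site_positions = pos)
    recount <- vapply(sw$start, function(s) {
      sum(pos >= s & pos <= s + 9)
    }, 0)
    expect_equal(sw$score, recount)
  }
})

test_that("background simulation is seed-deterministic and matches binomial expectation", {
  sim <- shared_sim()
  prof <- proteome_profile(sim$proteome, sim$sites_experimental,
                          "experimental")
  cfg <- hotspot_config("experimental", winsize = 10, n_background = 50,
                        seed = 5)
  bg1 <- simulate_background(prof, cfg)
  bg2 <- simulate_background(prof, cfg)
  expect_identical(bg1, bg2)
  # mean background window score ~ mean STY per window x phospho probability
  counts <- bg1$score_counts
  mean_score <- sum((seq_along(counts) - 1) * counts) / sum(counts)
  p_bar <- sum(prof$cat_prob[1:3] * prof$phospho_prob) / sum(prof$cat_prob[1:3])
  expected <- 10 * prof$sty_freq * p_bar
  expect_equal(mean_score, expected, tolerance = 0.15)
  # default background sizes follow the published procedure
  expect_identical(hotspot_config("experimental", seed = 1)$n_background,
                   10000L)
  expect_identical(hotspot_config("predicted", seed = 1)$n_background, 1000L)
})

test_that("a planted 6-in-10 cluster is detected and its windows merge into one run", {
  cfg <- sim_config(n_proteins = 60, length_meanlog = log(120),
                    length_sdlog = 0.35,
                    planted_hotspots = data.frame(protein = 3, start = 40,
                                                  winsize = 10, n_sites = 6),
                    seed = 321)
  sim <- generate_proteome(cfg)
  sites <- generate_sites(sim, cfg)
  hc <- hotspot_config("experimental", winsize = 10, n_background = 500,
                       seed = 99)
  scan <- detect_hotspots(sim$proteome, sites, hc)
  expect_true("P003" %in% scan$windows$protein_id)
  hit <- scan$windows[scan$windows$protein_id == "P003", ]
  expect_true(any(hit$start <= 49 & hit$start + 9 >= 40))
  expect_true(all(scan$windows$corrected_p < 0.05))
  expect_true(all(scan$windows$corrected_p >= scan$windows$raw_p))
  runs <- merge_runs(scan$windows)
  expect_true(all(runs$n_windows >= 1))
})

test_that("merging joins overlapping and adjacent windows and leaves gaps alone", {
  w <- data.frame(protein_id = c("P", "P"), start = c(10L, 15L),
                  winsize = 10L)
  expect_identical(merge_runs(w)$start, 10L)
  expect_identical(merge_runs(w)$end, 24L)
  w$start <- c(10L, 20L)  # bookended: [10,19] and [20,29]
  r <- merge_runs(w)
  expect_identical(nrow(r), 1L)
  expect_identical(r$end, 29L)
  w$start <- c(10L, 21L)  # one-residue gap: stays split
  r <- merge_runs(w)
  expect_identical(nrow(r), 2L)
  single <- merge_runs(data.frame(protein_id = "P", start = 5L, winsize = 10L))
  expect_identical(c(single$start, single$end), c(5L, 14L))
  # output runs are pairwise disjoint and non-adjacent
  set.seed(12)
  w <- data.frame(protein_id = "P", start = sort(sample(1:80, 12)),
                  winsize = 10L)
  r <- merge_runs(w)
  if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)] + 1L))
})

test_that("adding a site inside a window cannot lower its score or raise its p", {
  sim <- shared_sim()
  sites <- sim$sites_experimental
  prof <- proteome_profile(sim$proteome, sites, "experimental")
  cfg <- hotspot_config("experimental", winsize = 10, n_background = 100,
                        seed = 50)
  bg <- simulate_background(prof, cfg)
  pid <- names(sim$proteome)[1]
  seqs <- sim$proteome[[pid]]
  pos <- sites$position[sites$protein_id == pid]
  chars <- strsplit(seqs, "")[[1]]
  free_sty <- setdiff(which(chars %in% c("S", "T", "Y")), pos)
  sw0 <- scan_windows(seqs, 10, site_positions = pos)
  extra <- free_sty[1]
  sw1 <- scan_windows(seqs, 10, site_positions = c(pos, extra))
  common <- intersect(sw0$start, sw1$start)
  s0 <- sw0$score[match(common, sw0$start)]
  s1 <- sw1$score[match(common, sw1$start)]
  expect_true(all(s1 >= s0))
  # empirical tail p is monotone in the score under a fixed background
  p0 <- (phosnp:::background_tail(bg, s0) + 1) / (bg$n_windows + 1)
  p1 <- (phosnp:::background_tail(bg, s1) + 1) / (bg$n_windows + 1)
  expect_true(all(p1 <= p0))
  # a zero-score window is never significant
  expect_equal((phosnp:::background_tail(bg, 0) + 1) / (bg$n_windows + 1), 1)
})

test_that("predicted-mode candidates must carry the expected S/T/Y load", {
  sim <- shared_sim()
  scores <- score_proteome(sim$proteome)
  scores$status <- "predicted"
  hc <- hotspot_config("predicted", winsize = 10, n_background = 30,
                       seed = 13)
  scan <- detect_hotspots(sim$proteome, scores, hc)
  prof <- proteome_profile(sim$proteome, mode = "predicted")
  min_sty <- floor(10 * prof$sty_freq)
  if (nrow(scan$windows) > 0) {
    expect_true(all(scan$windows$n_sty >= min_sty))
  }
  expect_true(scan$m > 0)
})

test_that("domain overlap permutation test detects placement bias", {
  proteome <- c(P1 = strrep("A", 100), P2 = strrep("A", 100))
  domains <- data.frame(protein_id = c("P1", "P2"), start = c(1L, 1L),
                        end = c(10L, 10L), domain_id = "D")
  # all hotspots inside domains covering 10% of residues
  hs_in <- data.frame(protein_id = c("P1", "P2"), start = c(2L, 3L),
                      end = c(8L, 9L))
  res <- domain_overlap_test(hs_in, domains, proteome,
                             n_permutations = 2000, seed = 7)
  expect_identical(res$observed_overlap, 2L)
  expect_lt(res$p_enrichment, 0.05)
  expect_gt(res$p_depletion, 0.9)
  # toy intersection convention: [5,14] vs domain [10,20] overlaps
  hs <- data.frame(protein_id = "P1", start = 5L, end = 14L)
  d2 <- data.frame(protein_id = "P1", start = 10L, end = 20L,
                   domain_id = "D")
  res2 <- domain_overlap_test(hs, d2, proteome, n_permutations = 100,
                              seed = 1)
  expect_identical(res2$observed_overlap, 1L)
  # no domains at all: observed 0, depletion p = 1 by convention
  res3 <- domain_overlap_test(hs, d2[0, ], proteome, n_permutations = 100,
                              seed = 1)
  expect_identical(res3$observed_overlap, 0L)
  expect_equal(res3$p_depletion, 1)
})

test_that("detection output is identical across runs with one seed", {
  sim <- shared_sim()
  hc <- hotspot_config("experimental", winsize = 10, n_background = 100,
                       seed = 12321)
  s1 <- detect_hotspots(sim$proteome, sim$sites_experimental, hc)
  s2 <- detect_hotspots(sim$proteome, sim$sites_experimental, hc)
  expect_identical(s1$windows, s2$windows)
  expect_identical(s1$m, s2$m)
})
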