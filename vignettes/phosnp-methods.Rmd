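---
title: "Methods: SNP effects on phosphorylation sites"
author: "phosnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP effects on phosphorylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosnp)
```

This vignette documents the statistical models, the tunable parameters,
the numerical conventions and the design choices behind `phosnp`, and
states what the synthetic-data generator does and does not emulate.

## Coordinate conventions and variant mapping

All protein and genomic coordinates are 1-based and inclusive. A gene
model is an ordered set of non-overlapping coding exon blocks on one
strand; the spliced CDS is read in transcript orientation, so for
minus-strand genes the first CDS base is the rightmost exon base and both
the SNP reference and alternative alleles are complemented before codon
substitution. `genomic_to_cds()` is a bijection between exon bases and
`1..L` (introns map to a non-coding signal, not an error, because callers
routinely filter intergenic and intronic SNPs).

Effects are computed **per alternative allele against the reference CDS**.
Two SNPs inside one codon are evaluated independently and never combined:
per-SNP bookkeeping matches how non-redundant SNP panels are summarised,
and the reference codon — not an accession haplotype — is the baseline in
each case. A SNP under two overlapping gene models is evaluated once per
model. In the effect summary, a (protein, position) pair counts once in
the "affected amino acids" tally no matter how many alleles or accessions
hit it, while synonymous/non-synonymous counts tally substitution events;
affected stop codons are bookkept separately from amino acids, so
percentages use the amino-acid total only. Percentages are reported to two
decimals with round-half-to-even.

The substitution-cost matrix is computed by brute force over all codon
pairs: `cost(a, b)` is the minimum Hamming distance between any codon of
`a` and any codon of `b`, over the standard nuclear genetic code with the
stop codon as a first-class 21st symbol. The matrix is symmetric, zero
only on the diagonal, and bounded by 3; the test suite re-derives it with
an independent enumeration.

## Site statistics

**Count-distribution null.** The null model for phosphosite counts per
protein assumes one constant phosphorylation probability
`p = total pSTY / total STY` for every S/T/Y in the data set. The expected
count for protein *x* is `E_x = p·n_STY(x)`; the expected
frequency-of-count histogram aggregates `Binom(n_STY(x), p)` over
proteins. The binomial law is the minimal model consistent with a constant
per-residue probability; by construction the expected total equals the
observed total exactly (a regression test asserts this to numerical
precision).

**Residue proportions** are reported both at full precision and rounded
half-to-even to one decimal. For the canonical experimental counts
(5,078 S; 1,482 T; 618 Y) the computed pT share is 20.65%, which rounds to
20.6 — one-decimal displays are not forced to sum to 100.

**Fisher's exact test** is implemented directly (two-sided p as the sum of
hypergeometric probabilities not exceeding that of the observed table,
with the same `(1 + 1e-7)` tie tolerance used by the reference
implementation in `stats`), because the pipeline needs the *sample* odds
ratio `ad/bc` with a Haldane–Anscombe 0.5 correction and an explicit
zero-cell flag, which `stats::fisher.test()`'s conditional-MLE estimate
does not provide. The tests cross-check both the p-values (against
`stats::fisher.test` and against an exhaustive enumeration oracle, to
1e-12) and the degenerate-margin convention (p = 1, odds ratio
undefined).

**Substitution enrichment.** The 2×2 layout puts phosphorylated /
non-phosphorylated positions of the from-residue in the rows and
substituted-to-target / not in the columns, so an odds ratio above 1 reads
as "enriched at phosphosites". A position is "substituted" when at least
one accession carries the substitution (multi-accession alleles count once
per position). The universe defaults to proteins with at least one SNP on
a phosphosite of the analysed status — the narrower of the two natural
choices — with all phosphoproteins available as an option. Pairs observed
in neither class are reported as "never observed" and excluded from
testing; BH-FDR runs across the tested pairs at α = 0.05.

Because Fisher p-values on discrete tables are conservative, the
permuted-label calibration check uses a one-sided Kolmogorov–Smirnov test
against the uniform (rejecting only an *excess* of small p-values); a
two-sided test would reject on discreteness alone.

## Gain and loss of phosphosites

Experimental losses are recorded per accession whenever a substitution
replaces the phosphorylated residue. By default this includes exchanges to
another phosphorylatable residue (S→T) — multi-accession data show such
exchanges listed as losses — and gained stops, which remove the residue
outright; `strict = TRUE` restricts losses to non-S/T/Y targets.

Predicted-site calls follow two rules with the thresholds inclusive
(score ≥ 1 is a high-confidence site, ≤ −1 a high-confidence non-site):

* **status 2 (substitution-based):** a site residue exchanged for a
  non-phosphorylatable amino acid is a loss; a non-S/T/Y residue exchanged
  for S/T/Y whose accession-context score reaches ≥ 1 is a gain;
* **status 1 (score-based):** the central residue is retained but
  substitutions within the ±6 context drive the score from ≥ 1 to ≤ −1
  (loss) or from ≤ −1 to ≥ 1 (gain).

Scores landing strictly inside (−1, 1) yield no call, and a central S/T/Y
exchanged for a *different* S/T/Y is also a no-call: status 1 requires the
residue retained, status 2 requires a non-phosphorylatable target, and the
mixed case is undefined in the source procedure. Accession protein
sequences are reconstructed by applying **all** of that accession's coding
substitutions for the gene before scoring, so several nearby SNPs
influence one ±6 window correctly; a gained stop truncates the sequence.

The bundled `toy_scorer()` is a fixed weighted sum of residue propensities
over the ±6 window (weights 0.50, 0.30, 0.20, 0.12, 0.08, 0.05 for
distances 1–6, positions beyond the protein contributing zero), squashed
through `3·tanh()` into (−3, 3). The propensity table loosely follows
basophilic/proline-directed plant kinase motif preferences; its exact
values are an arbitrary published constant of the package, chosen so that
single substitutions can cross both ±1 thresholds — which is what makes
score-based gain/loss logic fully testable without an external predictor.
Any scorer with the same `(sequence, position) → value` contract can be
injected, including a lookup over precomputed decision values.

## Hotspot detection

Each protein is scanned with a step-1 window of fixed size (conventional
sizes: 5/10/15/20 residues for experimental sites, 10/20/30/40 for
predicted). Among consecutive windows containing the identical set of
S/T/Y residues only the first is kept — deduplication compares all S/T/Y
positions, not just phosphosites, following the stricter reading of the
procedure. Window scores are phosphosite counts (experimental) or sums of
prediction scores, negatives included (predicted).

The background is Monte-Carlo: replicate proteomes with the same number of
proteins, lengths resampled with replacement from the real length
multiset, residues i.i.d. from the global composition; S/T/Y residues are
phosphorylated with per-residue-type probabilities estimated from the real
data (experimental) or receive scores resampled from the proteome-wide
score pool (predicted). Window scores from all background proteomes are
pooled into one empirical distribution (pooling, rather than
stratification by protein length, matches a single proteome-wide "empiric
background distribution"; stratification would be a straightforward
variant). Defaults are 10,000 background proteomes for experimental mode
and 1,000 for predicted mode.

Candidate windows get the right-tail empirical p-value
`(#background ≥ observed + 1) / (#background + 1)` — the add-one estimator
never returns exactly zero — and Bonferroni correction with `m` equal to
the number of candidate windows tested proteome-wide, the most
conservative reading of "corrected for multiple testing". Windows with
corrected p below α (default 0.05) are significant. In predicted mode a
real candidate must additionally contain at least
`floor(winsize × proteome STY frequency)` S/T/Y residues; the filter does
not apply to the background. Significant windows merge into runs when they
overlap or are bookended (gap zero); runs are maximal, pairwise disjoint
and non-adjacent.

The hotspot–domain overlap test places each hotspot uniformly at random
within its own protein and counts overlaps (interval intersection with any
domain of the protein). Because placements are independent across
hotspots, the null count is simulated as a sum of independent Bernoulli
draws with each hotspot's exact overlap probability — distributionally
identical to explicit placement but far cheaper, which is how the default
of 10,000 permutations (raisable to millions) stays fast. Depletion
(hotspots outside domains) is the left tail, enrichment the right, both
with the add-one estimator.

## Term enrichment

Over- and under-representation use one-sided hypergeometric tails per
direction (`P(K ≥ x)` and `P(K ≤ x)`), the convention of the standard
ontology-enrichment tools, rather than one two-sided test — over- and
under-represented terms are reported separately. Proteins without any
annotation are discarded from query and reference before testing. BH-FDR
is applied within each direction by default (the family choice is
exposed); annotations are treated as a flat pre-propagated table, ontology
graph handling being out of scope.

## The synthetic-data generator

Every generator output is a pure function of the configuration, which
carries a mandatory seed; sub-generators use fixed offsets of that seed,
and the caller's RNG state is saved and restored. Defaults describe the
study conditions the package targets:

* protein lengths log-normal (`meanlog = log 300`, `sdlog = 0.45`, minimum
  40 residues) — a realistic proteome-like length spread;
* residue composition approximating a plant proteome (S 9.0%, T 5.1%,
  Y 2.9% among the 20 amino acids);
* per-residue phosphorylation probabilities S 0.100, T 0.052, Y 0.038,
  chosen jointly with the composition so the realized site split lands
  near the canonical 70.7 / 20.7 / 8.6 pS/pT/pY proportions;
* SNP rate 0.001 per coding base across 20 accessions with
  allele-sharing probability 0.15 (at least one carrier per SNP);
* genes of 1–3 exons with introns of 30–90 bp, alternating strands so
  splice and strand logic is genuinely exercised; CDS built by uniform
  synonymous-codon sampling plus a random stop codon;
* domains covering 30% of residues in 30–60-residue blocks; a 30-term
  annotation vocabulary with base rates 0.02–0.2.

Planted structure provides ground truth: phosphosite clusters forced into
chosen windows (the generator first guarantees the S/T/Y supply),
gain/loss events engineered by exhaustive search over single-base codon
changes — guaranteeing feasibility under the genetic code, with each
candidate verified against the caller so a planted SNP produces exactly
its intended event and nothing else — and T→N substitution excesses at
predicted phospho-threonines (restricted, in both the phosphorylated and
non-phosphorylated class alike, to the ACT/ACC codons that can reach
asparagine in one base change).

What the generator does **not** emulate: linkage and population structure
among accessions (alleles are shared independently), codon-usage bias
(synonymous codons are uniform), compositional autocorrelation along
sequences (residues are i.i.d.), and real spatial clustering of
phosphosites outside planted windows. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under its
stated assumptions — not that real proteomes satisfy those assumptions.

## Problem sizes and numerical choices

The calibration and recovery studies run at desk scale, chosen as the
smallest sizes at which the checks are statistically meaningful: the
family-wise-error study uses 200 null proteomes of 100 proteins (length
log-normal around 120 residues) with 1,000 background proteomes and window
size 10 per replicate; planted-hotspot power uses 50 such replicates with
a 6-sites-in-10 cluster; gain/loss recovery plants 10 events (mixed
status) in 40 proteins with background SNPs off, so recovered events can
be compared to truth exactly; the T→N study plants a five-fold excess
(rates 0.5 versus 0.1) in 250 proteins. The Fisher oracle comparison draws
1,000 random tables with total count at most 60 and requires agreement to
1e-12.

Other conventions: empirical p-values always use the add-one estimator;
odds ratios use the 0.5 correction only when a cell is zero, with a flag;
display rounding is half-to-even; windows shorter than the protein give an
empty scan with a warning rather than an error; zero-margin 2×2 tables
give p = 1 with the odds ratio undefined; and prediction-score thresholds
±1 are inclusive on both sides.

## Known limitations

Multiple SNPs in one codon are never combined into a joint codon change;
the reference CDS is the baseline for every allele. Splice variants beyond
the provided gene models, coordinate lift-over between genome releases,
and indels are out of scope. The toy scorer is a deliberately simple
stand-in for a trained site predictor and its scores have no biological
calibration; analyses of real data should inject the predictor actually
used. Hotspot backgrounds assume i.i.d. residue placement, so real
compositional structure (low-complexity regions, for instance) can make
the background anti-conservative for unusually repetitive proteins.
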