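---
title: "Generative modeling of V(D)J recombination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative modeling of V(D)J recombination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`repgenr` describes an immune-receptor sequence as the outcome of a
recombination *scenario*: a choice of germline segments, deletion counts at
their recombination-facing ends, and non-templated insertions at the
junctions.  Scenario probabilities factorize over a Bayesian network of
elementary events.  For VJ loci (TRA-like),

    P_recomb = P(V,J) P(delV|V) P(delJ|J) P(insVJ) prod_i P(n_i | n_{i-1})

and for VDJ loci (TRB/IGH-like),

    P_recomb = P(V) P(D,J) P(delV|V) P(delDl,delDr|D) P(delJ|J)
               x P(insVD) prod P(n_i|n_{i-1}) x P(insDJ) prod P(m_i|m_{i-1})

Gene usage for VDJ loci is always stored factorized as `P(V) P(D,J)`; the
fully joint three-way table is intentionally not implemented (the
factorized form is the default dependence structure for both TRB and IGH
here, and the D-J coupling is where the biology sits, e.g. the exclusion
of TRB D2 with J1-family J genes, expressed as structural zeros that no
learning step can repopulate).

Conventions worth stating precisely:

* **Deletions** range over `[-max_p, del_max]`.  Negative deletions retain
  P-nucleotides: each germline segment carries a `max_p`-long
  reverse-complement mirror appended at every recombination-facing end
  (3' for V, 5' for J, both for D), and deletion `-k` keeps `k` mirrored
  bases.  Defaults: `del ∈ [-4, 16]`, `max_p = 4`, per-gene cells that
  would delete more than the segment carries are structural zeros.
* **Insertions** have a length distribution (capped at `ins_max = 40`) and
  a dinucleotide Markov chain for nucleotide identity.  The first inserted
  base of the V-side chain is conditioned on the last retained V base; the
  D-J (and V-J) chain on the J side runs 3'→5' from the first retained J
  base.  There is consequently no free-standing initial-nucleotide
  distribution; the convention is recorded in the model file
  (`dj_chain rev`, `ins_first conditioned`).
* **Errors.**  Sequencing errors (or hypermutations treated as such) hit
  germline-covered positions only; inserted bases are free parameters of
  the scenario and carry no error factor.  A scenario with `k` mismatches
  over `L` covered positions contributes `(r/3)^k (1-r)^(L-k)`: the `1/3`
  is forced by the generative convention that a mutated base is uniform
  over the three alternatives, and makes `P_read` a proper probability of
  the observed read.
* **Reads are 3'-anchored windows.**  The last read base coincides with
  the 3' end of the retained J; the 5' end may truncate into the retained
  V (the hidden overhang is part of the scenario).  Windows that would cut
  into the junction itself are flagged by the generator
  (`junction_lost`) and fail annotation — they carry no recoverable
  junction information.

## Scenario enumeration

Candidate placements are generated per read: J genes have a single forced
diagonal (read end = J end), V genes are scanned over all truncation
offsets, and D segments are scanned directly over all
`(delDl, delDr, position)` triples with a mismatch-budget cap — a superset
of what thresholded D pre-alignment would give, which is what makes
exhaustive-oracle equality possible on toy models.  Candidates are scored
with match +5 / mismatch −14 and filtered at thresholds V ≥ 35, J ≥ 25
(`align_all`, the user-facing alignment module, additionally reports true
Smith–Waterman scores with gap penalty −50).  The thresholds are lower
than a long-read setting would use because with 60-bp junction-centric
windows the visible V stub of a long-junction read can be under 10 nt; at
a threshold of 50 such reads would be unanalyzable.

The join over (V row, D row, J row) explores candidates in descending
probability order with branch-and-bound: a branch is discarded when an
optimistic completion bound (row factors, maximal insertion-length factor
plus length × maximal transition log-probability) falls below
`prune_ratio` (default 1e-4) times the best complete scenario found so
far.  Scenarios evaluated below the cut are also discarded; everything
discarded is accumulated into `truncated_mass_bound`, a (loose) upper
bound on the probability mass missing from `P_read`.  Reads whose
`P_read` falls below `floor` (default 1e-40) are reported failed.  Ties
in the ranking are broken lexicographically on
(V, D, J, deletions, D placement), making annotation byte-deterministic.

All probabilities are handled in log space; `P_read` uses a running
rescaled accumulator, and posterior-weighted statistics are accumulated
relative to the best scenario found in a fast pre-pass.

## Learning

`em_learn` is expectation-maximization over the enumerated scenario lists:
the E step adds the posterior weight `P_scenario / P_read` of every
retained scenario into the count cell of each event it realizes; the M
step renormalizes counts row-wise, with `error_rate =
events / opportunities`.  Three numerical choices matter:

* **Support smoothing.** The M step adds a pseudocount of 1e-6 to every
  cell the previous model allows (never to structural zeros).  Without
  it, any event value never enumerated in the sample gets exactly zero
  probability and every divergence against the truth is infinite;
  with it, unobserved-but-possible cells keep negligible but positive
  mass.
* **Sparse schedule.** Candidate placements depend only on score
  thresholds, so the enumeration support is fixed across iterations;
  iteration 1 runs with a coarse `prune_ratio` (1e-2) and later
  iterations sharpen as the model concentrates.
* **Monotonicity tolerance.** The total `sum(log P_read)` is
  non-decreasing under exact EM; pruning makes the computed value an
  approximation, so a decrease of up to 1e-5 relative is tolerated and
  anything larger raises an error (contract violation).  Iteration 1 is
  excluded from the comparison because it runs at a different pruning
  level.  Convergence is declared when the per-read log-likelihood
  improves by less than `tol` (default 1e-3).

Restricting learning to out-of-frame (non-productive) rearrangements —
CDR3 length not a multiple of three, a junction stop codon, or a
destroyed anchor, computed from the conserved V-cysteine and J-anchor
codons annotated in the germline metadata — emulates learning free of
functional selection.

## Generation probability

`pgen(s)` sums `P_recomb` over every scenario whose read window equals
`s` exactly (mismatch-free enumeration, pruning disabled by default).
Under the window convention this is the probability that the generative
process produces an ancestral sequence whose 3'-anchored window of length
`nchar(s)` equals `s`; summed over all reachable windows of a fixed
length it totals the probability that the ancestral sequence is at least
that long (exactly 1 on toys built so that every product is long enough,
which is what the property suite asserts).

For hypermutated reads the ancestral sequence is uncertain, so
`pgen_mutated` reports the posterior-weighted geometric mean over
candidate ancestors: ancestors are grouped from the top-k enumerated
scenarios, each with weight `P_gen(a) P_err(a) / P_read` and with
`P_gen(a)` taken as the summed `P_recomb` of its scenarios; the estimate
is `exp(sum_a w_a log P_gen(a))`.  The maximum a posteriori ancestor is
available as an alternative (`method = "map"`).  Both the grouping and
`P_gen(a)` are truncated at `k_top` scenarios; the posterior mass beyond
is negligible in the regimes exercised here (a few mutations per read).

## Hypermutation models

The additive model scores each candidate site by its (2m+1)-mer context:
`P_mut / (1 - P_mut) = mu exp(sum_i e_i(pi_i))`, default 7-mers.  The PWM
is stored in the zero-sum gauge (`sum_sigma e_i(sigma) = 0` per
position), which makes `mu` the geometric mean of the mutation odds over
all contexts and the serialization unique.  `fit_pwm` maximizes the
posterior-weighted Bernoulli likelihood by IRLS logistic regression on
one-hot context features, then re-imposes the gauge — same objective as
a damped gradient ascent, but with a deterministic, well-conditioned
inner solver.  Contexts that straddle a junction use the scenario's
reconstructed ancestral sequence; sites whose context extends beyond the
ancestral sequence (e.g. within m of the read 3' end) fall back to the
overall rate `mu/(1+mu)` in likelihoods and are excluded from fitting.
The non-additive alternative (`fit_nmer`) tabulates raw per-n-mer rates
over all 4^n contexts and flags those under a weighted-coverage
threshold (default 100) as inestimable.

The co-localization index follows the radial-distribution definition:
`g(r) = (1/N_r) sum f(i,j,V) / f(i,V) f(j,V)` over position pairs with
sufficient posterior-weighted coverage; independent per-site mutations
give `g ≈ 1`, so departures diagnose model violations (the generator
never produces them — per-read mutation counts follow the
Poisson-binomial of the per-site probabilities, which the test suite
verifies).

## Model comparison

`kl_divergence` computes `D(theta1 || theta2)` exactly by the chain rule
over CPTs (log base 2): each conditional block is weighted by the
theta1-marginal of its conditioners, and the insertion-nucleotide chains
are handled exactly by propagating the theta1 distribution of the chain
state — seeded with the distribution of the conditioning boundary base
implied by theta1's gene and deletion tables — and weighting step k by
`P1(len >= k)`.  This exact treatment (rather than an expected-length
approximation) is what makes the chain-rule result agree with a
brute-force sum over the full scenario space to 1e-8 on toys.  Zeros in
theta2 where theta1 has mass yield +Inf with the offending cells listed.

## The synthetic world

Everything here runs on bundled synthetic germline libraries (files named
`*_synthetic_*`; they stand in for IMGT-style exports, which are not
shipped):

* TRB-like: 8 V (70 nt), 2 closely related D (16/14 nt), 6 J (20 nt) in
  two families with the D2–J1 exclusion; read length 60.
* IGH-like: 10 V (120 nt), 5 D (12–31 nt, two similarity families), 6 J
  (40 nt); read length 130.
* V genes are ~15–18% diverged copies of a common ancestor and J genes
  ~10–12% within family, so gene calling is non-trivial; D genes within a
  locus are related, as real D genes are.  Anchor codons are planted at
  fixed positions and recorded in the FASTA description lines.

Default event statistics are chosen once as a realistic regime: deletion
profiles are negative-binomial shaped with means ~1.5–3 deleted bases and
a P-nucleotide tail; insertion lengths are negative-binomial with mean
4.6 nt per junction for TRB-like and 7.5 nt for IGH-like models; the
insertion chain has a mild composition and stacking bias; sequencing
error is 1e-3 (typical) or 5e-3 (the degeneracy experiments); the
synthetic hypermutation PWM has hotspot-like structure (A/T-rich
upstream, C-biased site) with overall rate scale `mu = 0.02`–0.08
depending on the experiment.

What a green test establishes — and what it does not: the suite shows
that the engine's probabilities are exactly those of its declared
generative model (oracle equalities), that learning recovers a known
truth from its own synthetic output (including from out-of-frame reads
only and with undeclared structural zeros), and that scenario degeneracy
and Pgen estimation behave in the documented regimes.  It does not
establish anything about real repertoires: real gene-usage variability,
hypermutation motif content, co-localization decay lengths or tandem-D
enrichment require external data sets and are out of scope.  Known
limitations, by design: no indels in the hypermutation model (alignment
and enumeration are gapless; heavily gapped reads fail the likelihood
floor), single-D architectures only (tandem-D usage is detected
diagnostically, not modeled), no amino-acid-level Pgen aggregation, no
allele discovery, and no quality-aware read preprocessing.
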