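---
title: "Designing minimal-cost reusable degenerate primer sets by MCMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing minimal-cost reusable degenerate primer sets by MCMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primertile)
```

## The problem

Deep resequencing and marker projects routinely need hundreds of PCR
primers to tile a set of target genes with amplicons. Synthesized
nucleotides are what you pay for, so the natural objective is the *cost* of
a design $D$: the summed length of its **distinct** primers,

$$\mathrm{cost}_D \;=\; \sum_{i=1}^{k} l_i,$$

where the design uses $k$ distinct primers of lengths $l_i$. A primer that
primes several loci (on the same or different genes) is synthesized once
but closes several amplicons — *reuse* — and a primer carrying degenerate
positions is a pool of oligos able to serve variant alleles. Minimizing
$\mathrm{cost}_D$ over all admissible amplicon tilings while maintaining
acceptable coverage is a variant of the multiple degenerate primer
selection problem, whose decision versions are NP-complete; `primertile`
attacks it by Metropolis--Hastings sampling of design space, as a global
stochastic alternative to one-shot greedy construction.

Coverage — the base pairs of target lying inside amplicons, primer
footprints included — is *reported* but deliberately *not* optimized. As a
design approaches a cost optimum for a given coverage, the sampler will
happily trade coverage away to remove a primer pair; this is a property of
the method, not a bug, and it shapes several results below.

## Candidate primer preparation

For one integer target melting temperature $t$ the pipeline enumerates
every substring of every consensus gene, on both strands, with length in
`primer_len_min..primer_len_max` (defaults 18--27 nt), keeping those whose
rounded melting temperature equals $t$. Melting temperature is the
composition formula

$$T_m = 64.9 + 41\,(n_{GC} - 16.4)/N,$$

with $n_{GC}$ the count of G/C/S positions and $N$ the length. The choice
of a composition formula is *forced* by the degeneracy scheme: only the
IUPAC codes W (= A/T) and S (= G/C) are allowed as degenerate positions,
precisely because A↔T and G↔C substitutions leave the GC count — and hence
this $T_m$ — unchanged. A nearest-neighbour stacking model would assign the
expansions of a W/S pool different melting temperatures and break the
per-temperature design contract. The constant set (64.9/41/16.4) is a
conventional one for primer-sized oligos; it lives in a single function so
it can be swapped, and all absolute temperatures in this package are only
meaningful relative to it.

Two quantization facts follow from rounding a discrete formula and are
worth knowing: (i) some integer temperatures are unreachable — no oligo of
length 18--27 rounds to 65 °C — and the sweep reports `NA` there; (ii) a
given temperature is often reachable only at a few (length, GC-count)
pairs, so candidate density varies systematically along a sweep.

Candidates then pass through screens:

* **SNP constraints.** If a gene carries an *exceptions* sequence (its
  consensus with collated SNPs as IUPAC codes), footprint columns whose
  ambiguity set is {A,T} or {C,G} are forced to W or S; any other set (for
  example R = {A,G}) is not $T_m$-neutral and invalidates the candidate at
  that site. Forced positions count against the degeneracy budget
  (`max_degeneracy`, default 3 — with $2^3 = 8$ oligos the largest pool).
* **Hairpins and self-dimers.** An oligo is rejected if it contains two
  reverse-complementary segments of ≥ 4 nt separated by a loop of ≥ 3 nt,
  or if its 3′-terminal 5-mer's reverse complement occurs anywhere in the
  oligo, or it shares a ≥ 8 nt reverse-complement run with itself. The
  thresholds are conventional screening defaults, exposed as arguments of
  `check_hairpin()`/`check_dimer()`. Cross-primer dimer compatibility is
  *not* applied all-pairs across the catalogue — a forward candidate and
  the reverse candidate of an overlapping window are complementary by
  construction, so an all-pairs rule would empty the catalogue — but is
  enforced between the forward and reverse primer of every amplicon at
  design time.
* **Background redundancy.** Occurrences of any concrete expansion on
  either strand of a background sequence set are counted by exact substring
  search (the search is isolated behind one function so an external aligner
  could be substituted); candidates exceeding `max_redundancy` (default 10)
  are discarded as repeat- or low-complexity-borne.

Finally, candidates that become identical when A/T positions collapse to W
and G/C positions to S are generalized: every W/S pattern (within the
degeneracy budget) subsuming at least two distinct catalogue members is
added, with the union of its members' binding sites. Working inside these
collapse classes makes the generalization exact without enumerating all
$\binom{N}{3}$ patterns per primer.

Candidates are weighted by a total order: higher redundancy first, then
lower degeneracy, then *shorter length*, then sequence. The length
tie-break is this package's own addition: when reuse and degeneracy cannot
separate two candidates, the cheaper primer should win, since nucleotide
count is the objective. The final tie on sequence exists only for
determinism.

## The sampler

A design is a per-gene list of amplicons `[start, end)` (0-based,
half-open, primer footprints included), each with a forward primer binding
at `start` on the plus strand and a reverse primer whose minus-strand
footprint ends at `end`. Amplicon lengths are constrained to
`amplicon_min..amplicon_max` (defaults 50--250 bp); forward ≠ reverse as
sequences; every (forward, reverse) pair is unique across the design; the
pair must not form a primer-dimer.

**Initial design.** Genes are visited in random order; each is tiled from a
uniform random seed position, drawing amplicon sizes uniformly from the
allowed range, taking at the chosen locus the best-weighted primer, and
overlapping consecutive amplicons by `initial_overlap` bp (slack that the
optimization later removes). A seed landing in a stretch without usable
loci falls back to tiling from the gene start, so a coverable gene is never
left uncovered by bad luck of the seed.

**Proposals.** Three greedy generators:

1. *Global re-seeding* — a fresh complete design, as above.
2. *Per-gene refinement* — one uniformly chosen gene re-seeded, the rest
   kept.
3. *Repositioning* — one uniformly chosen primer locus moved to a random
   admissible alternative binding site, keeping the amplicon within its
   length bounds.

With `weight_greedy` on (default), the method matching the current third of
the run is drawn with probability 0.8 and the other two with 0.1 each —
coarse moves early, fine moves late, while every method stays reachable at
every iteration. The 0.8/0.1/0.1 split is a design choice; any weighting
that keeps all three reachable preserves the sampler's correctness.

**Acceptance.** With current cost $C$ and proposal cost $C'$,
$\delta S = C' - C$; cost-lowering proposals are always accepted and uphill
proposals with probability $\min(1, e^{-\delta S\,H})$, the standard
Metropolis normalization of "proportional to $e^{-\delta S H}$". The
heating $H$ (default 0.2) sets how strongly uphill moves are suppressed;
$\delta S = 0$ is accepted with probability 1. An alternative reading of
the heating — a fixed fraction $H$ of uphill proposals accepted — is
available as `heating_mode = "fraction"`.

**Slack removal.** After each iteration, any amplicon lying entirely inside
a neighbour is deleted independently with probability
`prob_remove_redundant`, controlling how quickly initial overlap slack
leaves the design.

The best-cost design ever visited is the result; the per-iteration trace
records method, costs, acceptance, best-so-far and coverage. Everything is
reproducible from `rng_seed`. Optional early stopping halts the run when
the best cost has improved by no more than `cost_tolerance` over a sliding
window of `n_iterations * early_proportion` iterations (both default off);
this is a documented interpretation of the "early proportion" knob, which
is only loosely specified upstream.

## The exhaustive oracle

`oracle_optimal_cost()` enumerates, depth-first with pruning, every valid
non-nested tiling on instances small enough (subset space ≤ about $10^6$),
restricts to maximal attainable coverage, and returns the minimum cost.
It bounds the sampler from below and, on suitable instances, the sampler
should reach it. One subtlety: the sampler minimizes cost *regardless of
coverage*, while the oracle minimizes cost *among maximal-coverage
tilings*. The two agree only on instances where every nonempty design
costs the same as the coverage-maximal optimum — which is why the packaged
comparison instance fixes all primers to length 20 (any single-amplicon
design then costs exactly 40 nt). On free-length instances the sampler can
legitimately report less cost at less coverage, and the oracle comparison
would be ill-posed.

## The synthetic data generator

`generate_gene_set()` builds consensus/exceptions/background FASTA trios
with known ground truth:

* i.i.d. bases at `gc_target` (default 0.55, a temperate-cereal coding
  composition), or — for studies spanning a melting-temperature range — a
  segmental GC mosaic (`gc_profile`, `segment_len`) emulating the local GC
  heterogeneity (GC3 gradients, domain structure) of real grass
  transcripts, without which high-$T_m$ priming sites all but vanish;
* planted motifs, each occurring at `site_multiplicity` loci (verified
  exactly by exhaustive scan), constructed at a caller-chosen rounded
  $T_m$ and re-rolled until they pass the hairpin/self-dimer screens — the
  ground-truth reusable priming sites; a vector `motif_tm` plants a ladder
  of such sites across a temperature range, denser at the low end, the way
  conserved repeats behave in real data;
* SNPs at `snp_rate` per column, 80% $T_m$-neutral ({A,T} or {C,G}) and
  20% non-neutral to exercise the rejection path, never inside planted
  footprints (so motif ground truth stays exact);
* a background of the genes plus a random decoy.

What the generator does **not** emulate: homologous gene families with
graded divergence, repeat families, indels (variants for the exceptions
builder must be pre-aligned and equal-length; alignment is out of scope),
or chimeric backgrounds. Tests passing on these fixtures therefore
demonstrate the algorithm's mechanics — enumeration correctness, screening,
reuse exploitation, convergence — not performance claims on any real
genome.

## Study conditions used by the test suite

Problem sizes were chosen so the full suite exercises realistic structure
at desk scale: convergence runs use the generator defaults (30 genes × 1 kb,
8 planted motifs × 3 loci, 5000 iterations, 10 chains); the
temperature-sweep study uses 12 genes × 840 bp on a GC mosaic
(0.40/0.80/0.55/0.80 in 60 bp segments, overall mean ≈ 0.64, the flavour of
a GC3-rich cereal transcriptome) with a motif ladder from 50 °C up, swept
50--70 °C at 1500 iterations per temperature; the reuse-benefit comparison
uses 6 genes × 500 bp with 6 motifs × 3 loci at 60 °C. The exhaustive-oracle
instance is a single gene ≤ 150 bp with a ≤ 12-candidate catalogue at fixed
primer length 20.

On sweeps, three behaviours are worth restating. Coverage declines
significantly with $T_m$ (sites rarefy), and the count of reused primers is
highest at the low end — both mirroring the expected biology. Total design
cost, however, is the product of two opposing forces: per-primer cost rises
with $T_m$ (longer primers, less reuse) while attained coverage — which the
algorithm does not defend — falls, removing whole primer pairs. On these
fixtures the two nearly cancel: total cost trends weakly upward (rank
correlation ≈ +0.05..+0.15, not significant at $\alpha = 0.05$), whereas
cost *per covered base* rises clearly. Larger or more repeat-rich inputs,
where coverage is easier to hold, tilt total cost further upward.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; minus-strand sites are
  stored by the plus-strand start of the reverse-complement match.
* Consensus tie-breaks in the exceptions builder are alphabetical
  (A < C < G < T); exception codes are exactly the IUPAC code of the
  observed base set.
* `round()` (half-to-even at .5, as in R) defines "a primer has target
  $T_m$".
* Positions containing N are disallowed inside any primer footprint; an
  empty FASTA file is an empty gene set, not an error; a gene with no
  feasible amplicon stays uncovered and contributes zero cost and coverage.
* `cost_per_covered_base()` errors at zero coverage rather than returning
  an infinity, and reports at 2 decimals, the precision at which such
  designs are compared.
* Gaps between adjacent amplicons larger than `max_gap` are warnings, not
  violations: the upstream definition of the knob is not operational, and
  a hard constraint would conflict with cost-only optimization.
* An amplicon nested inside a neighbour with both primers single-use is
  likewise flagged as a warning ("contributes nothing"), the operational
  reading of "no primer inside another amplicon unless it lowers cost".

## Limitations

* The $T_m$ model is compositional by design; absolute temperatures are
  not comparable to nearest-neighbour calculators, only the W/S-neutrality
  and the orderings matter.
* Background specificity is exact-match substring counting, not alignment;
  near-matches (mismatch-tolerant mispriming) are out of scope.
* Primer pairs are checked for dimers pairwise within an amplicon, not
  across the whole multiplex; tube partitioning is out of scope.
* The sampler is a cost optimizer only; when coverage matters, inspect the
  reported coverage per temperature and choose accordingly (the sweep
  summary and `plot()` make this trade-off visible).
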