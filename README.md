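# primertile

Minimal-cost, reusable, optionally degenerate PCR primer sets that tile a
collection of target genes with amplicons, found by Metropolis–Hastings
MCMC sampling of the design space.

## The problem

Projects that amplify many gene targets pay per synthesized nucleotide.
For a design `D` using `k` distinct primers of lengths `l_i`, the cost is

    cost_D = sum_{i=1..k} l_i

— a primer reused at several loci is paid for once, and a primer carrying
degenerate positions (only W = A/T and S = G/C, the two IUPAC codes that
leave a composition-based melting temperature unchanged) is one pool able
to serve variant alleles collated as SNPs. Jointly choosing reusable,
degenerate primers that tile many targets is a variant of the multiple
degenerate primer selection problem (NP-complete in its decision forms),
so `primertile` optimizes stochastically: candidate primers are
exhaustively enumerated per integer melting temperature under GC, hairpin,
self-dimer, SNP and background-redundancy constraints, generalized into
W/S-degenerate primers, and the per-gene amplicon tiling is then sampled
by a Metropolis–Hastings chain with three greedy proposal generators
(global re-seeding, per-gene refinement, single-primer repositioning),
accepting uphill moves with probability `min(1, exp(-deltaS * H))`.
Coverage is reported per temperature but not optimized; the objective is
cost alone.

The methods vignette (`vignettes/primer-design-methods.Rmd`) documents the
model, every tunable parameter, the synthetic-data generator and the
numerical choices in detail.

## Worked example

Everything runs on synthetic fixtures with known ground truth — no
downloads. `generate_gene_set()` plants reusable priming sites and SNPs;
`primertile()` fits a design across a melting-temperature range:

```r
library(primertile)

fx  <- generate_gene_set(n_genes = 8, length = 600, n_shared_sites = 4,
                         site_multiplicity = 3, seed = 42)
cfg <- primer_config(tm_min = 58, tm_max = 62, n_iterations = 2000)
fit <- primertile(fx$genes, background = fx$background, config = cfg, seed = 7)
fit
#> primertile design fit
#>   genes: 8 ( 4800 bp )
#>   Tm range: 58 - 62 C; 2000 MCMC iterations per Tm
#>  tm n_candidates cost coverage pct_coverage cost_per_base n_distinct_primers n_reused_primers
#>  58         4138  777     2498        52.04          0.31                 38                6
#>  59         3950  781     1925        40.10          0.41                 36                0
#>  60         3921  807     1952        40.67          0.41                 38                2
#>  61         3959  737     2112        44.00          0.35                 31                5
#>  62         2199  592     2118        44.12          0.28                 28                2
```

Per temperature: the number of screened candidate primers, the design cost
in nucleotides over distinct primers, covered base pairs, percentage of the
4800 bp target covered, cost per covered base, and how many primers are
reused (close ≥ 2 amplicons). The fitted primers themselves:

```r
head(primers(fit), 3)
#>                      seq length degeneracy reuse       tm
#> 1 ATCCGCACCTCCCCTCTCACGS     22          1     2 62.29091
#> 2     CCGGGACCGAGCAGCCGC     18          0     1 61.71111
#> 3    AACGCGGGGGTGGCAGCGG     19          0     1 61.87895
```

The first primer is degenerate (one S position) and reused — it closes two
amplicons but is synthesized once. `summary(fit)` adds the reuse histogram
and the no-reuse equivalent primer count per temperature, e.g. at 58 °C:

```
#>   Tm 58: reuse histogram [1x:32 2x:6], no-reuse equivalent 44 primers, reduction 13.64%
```

`plot(fit)` shows the cost/coverage trade-off against melting temperature;
`write_output(fit$sweep)` writes the plain-text results file (one block per
temperature: primer table with degeneracy flags, reuse levels and binding
loci, then covered bases, final cost and cost per covered base).

A thin command-line front-end over the same functions lives at
`inst/cli/primertile.R`:

    Rscript inst/cli/primertile.R synth --genes 8 --length 600 --seed 42 -o fx
    Rscript inst/cli/primertile.R run --config config.txt \
        --consensus fx.consensus.fasta --exceptions fx.exceptions.fasta
    Rscript inst/cli/primertile.R exceptions-generate variants.fasta -o out

The configuration file is one `key<TAB or =>value` pair per line with `#`
comments; both descriptive names ("Max degeneracy (base pairs)") and short
field names (`max_degeneracy`) are accepted.

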