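# telovar

Quantification of a variant telomere repeat (TTAGGT) in short
sequencing reads, estimation of *in vivo* telomerase repeat-addition
processivity from consecutive-repeat run lengths, and classification of
the 3′ terminal permutation of telomeres from C-tailed sequencing
reads — with a synthetic read generator so the whole pipeline can be
validated without access to protected human genomes.

The package is for sequence analysts studying telomerase template
variants: carriers of a TR/TERC template mutation deposit a
non-canonical hexamer alongside the wild-type TTAGGG, and the
composition, run structure, and terminal register of the resulting
telomeres are all informative about the variant enzyme's behavior in
living cells.

## The model

After each hexamer addition, telomerase either continues processively —
with probability *P(x)* for the allele currently engaged — or
dissociates; a re-associating enzyme carries the variant template with
probability ρ (0.5 under equal availability of both alleles).  The
probability that the next repeat matches the current one is

    P(Add) = P(x) + (1 − P(x))·ρ

so consecutive same-type repeat counts are geometric, and the run-length
survival fraction S(x) (proportion of maximal runs of length ≥ x) obeys

    log2 S(x) = (x − 1)·log2 P(Add).

A line of best fit through the empirical log2 survival curve yields
P(Add) = 2^slope, and inverting the model gives the in vivo
processivity P(x) = (P(Add) − ρ)/(1 − ρ).  For a non-processive enzyme
P(Add) = 0.5 (S(2) = 0.5, S(3) = 0.25); for P(x) = 0.9,
P(Add) = 0.95.

The three analysis stages:

* **Composition** (`telomere_composition`): reads with ≥ 13
  non-overlapping telomeric hexamers (TTAGGG, TTAGGT, CCCTAA, ACCTAA)
  anywhere in the read are trimmed to their first 60 bases, oriented to
  the G-strand, and scanned greedily; base fractions of wild-type,
  variant, and other sequence are reported.
* **Processivity** (`estimate_processivity`): run-length table →
  survival curve → log2-linear OLS fit, per repeat class (variant uses
  ρ, wild-type 1 − ρ).
* **Terminal permutation** (`terminal_spectrum`): C-tail reverse reads
  are filtered (≥ 5 CTAACC/CTAAAC, a ≥ 6-base G-run, 12 defined bases
  after it); the 12 bases after the G-run are reverse-complemented and
  the terminal hexamer is matched against the 12 rotations of
  TTAGGG/TTAGGT.

## Worked example

Simulate a heterozygous carrier (wild-type P(x) = 0.9, variant
P(x) = 0.4, ρ = 0.5, 15% degenerate repeats), generate 150 bp WGS-like
reads, and analyze them:

```r
library(telovar)

params <- model_params(p_x_wt = 0.9, p_x_var = 0.4, rho = 0.5,
                       degeneracy = 0.15)
arr <- simulate_telomere_array(params, n_units = 20000, seed = 1)
sim <- simulate_wgs_reads(arr, read_sim_params(n_reads = 4000, seed = 2))
telomere_composition(sim$reads)
#> Telomere composition
#>   reads: 4000 total, 3999 telomeric
#>   bases considered (trimmed): 239940
#>   frac wt 0.7196 | var 0.1265 | other 0.1539 (of bases)
#>   frac var 0.1495 (of counted repeats)
```

The 15% generating degeneracy is recovered in `frac other`; the variant
occupies ~13% of telomeric bases because the variant enzyme extends
runs far less often than the wild type.  Processivity recovery is
cleanest on uncensored repeat arrays (read windows truncate runs — see
the vignette):

```r
arr0 <- simulate_telomere_array(model_params(0.9, 0.4, 0.5, 0),
                                n_units = 100000, seed = 3)
estimate_processivity(arr0, rho = 0.5)
#> Processivity estimate [wt]
#>   slope -0.0760 (log2/repeat), P(Add) = 0.9487, P(x) = 0.8973
#>   rho = 0.500, 136 points, R^2 = 0.9987
#> Processivity estimate [var]
#>   slope -0.5015 (log2/repeat), P(Add) = 0.7064, P(x) = 0.4128
#>   rho = 0.500, 21 points, R^2 = 0.9972
```

Both generating processivities (0.9 and 0.4) are recovered from the run
structure alone.  Terminal permutations close the loop from simulated
C-tail reads:

```r
tsim <- simulate_terminal_reads(
  terminal_sim_params(c(GGTTAG = 0.8, GGTTTA = 0.2), n_reads = 2000,
                      junk_fraction = 0.1, seed = 4))
terminal_spectrum(tsim$reads)
#> Terminal permutation spectrum
#>   reads: 2000 total, 1800 passing (rejected: ctail_motifs=67, g_run=67, undefined_window=66)
#>   class fractions: wt 0.797, var 0.203, other 0.000
#>   top permutations: GGTTAG 1435, GGTTTA 365
```

`run_pipeline()` (and the thin CLI in `inst/cli/telovar.R`) chains the
stages with config files, TSV/JSON reports, and a provenance block;
identical config + seed gives byte-identical reports.

## Documentation

The methods vignette
(`vignettes/telomere-variant-analysis.Rmd`) describes the model and its
assumptions, every tunable threshold with its default and rationale,
what the synthetic generator does and does not emulate, and the known
limitations (read-boundary censoring of runs, i.i.d. degeneracy,
per-read rather than per-molecule terminal counting).
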