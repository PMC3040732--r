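# icamir

Independent-component-analysis based microRNA target prediction for bulk
transcriptomics.

## The problem

Expression-based miRNA target prediction classically orders mRNAs by their
Pearson correlation with a miRNA profile and asks whether seed-predicted
targets pile up near r = −1.  That fails whenever a miRNA's measured
expression does not track the transcriptional program in which its
repression acts — which is common, because miRNA log-ratios are small and
their regulation is often decoupled from their targets' program.

`icamir` implements the alternative: decompose the genes × samples
log-ratio matrix as

    E = C · M

by fastICA (negentropy maximization with the exponential contrast
G(u) = −exp(−u²/2); loads standardized to mean 0, variance 1 per
component), extract all n = min{G, S} independent components without PCA
pre-reduction, rank components against the experimental design by one-way
ANOVA on their mixes (Bonferroni-corrected p < 10⁻⁴), and test each
miRNA's 6mer seed-match targets (mature positions 2–7, reverse-complement
scan of 3'UTRs) for enrichment in the significant components' loads
(Wilcoxon rank-sum, BH FDR).  miRNA profiles are then represented as
least-squares superpositions of the component mixes (coefficients scaled
to absolute sum 1, quality as percent variance explained), and targets are
prioritized by pairwise miRNA cooperativity and pathway enrichment among
high-|load| genes.

Because the decomposition never consults the miRNA profile, load
enrichment detects repression that correlation cannot see.

## Worked example

Everything below runs on the bundled synthetic generator — no downloads.
The generator plants known miRNA→target regulation into sparse Laplace
programs mixed across a 3-factor × 3-replicate design (24 samples), and
emits sequence files whose seed-match structure reproduces the planted
target map exactly.

```r
library(icamir)

sim <- simulate_dataset(G = 1200, T_programs = 4, n_mirna = 4, n_decoys = 2,
                        n_pathways = 2, rng_seed = 1)
map <- build_target_map(sim$mirna_seqs, sim$utrs)
map
#> target_map: 6 miRNAs, 1200 genes in universe
#>   targets per miRNA: mir01=120, mir02=120, mir03=120, mir04=120,
#>   decoy01=120, decoy02=120

decomp  <- fast_ica(sim$mrna, rng_seed = 1)
ranking <- rank_components(decomp, sim$design)
head(ranking, 4)
#>     component    F        p p_bonferroni significant
#> IC3       IC3 47.7 1.54e-09     3.70e-08        TRUE
#> IC2       IC2 39.9 5.87e-09     1.41e-07        TRUE
#> IC4       IC4 26.9 1.04e-07     2.50e-06        TRUE
#> IC5       IC5 18.0 1.81e-06     4.34e-05        TRUE

sig <- ranking$component[ranking$significant]
enr <- ic_target_enrichment(decomp, map, sig)
attr(enr, "summary")
#>   mirna_id best_ic    q_min
#> 1    mir03     IC2 2.80e-59
#> 2    mir02     IC3 8.21e-55
#> 3    mir01     IC4 2.03e-48
#> 4    mir04     IC4 2.03e-48
#> 5  decoy01     IC3 3.16e-02
#> 6  decoy02     IC3 2.12e-01
```

The four planted miRNAs are recovered with q-values ~50 orders of magnitude
below the decoys: their seed-match targets sit far out in the load
distributions of the design-significant components.  The superposition fit
shows each profile is essentially a linear combination of the component
mixes:

```r
fits <- fit_all_mirnas(sim$mirna, decomp, ranking = ranking)
fits[, c("mirna_id", "r_squared", "variance_explained_pct")]
#>   mirna_id r_squared variance_explained_pct
#> 1    mir01    0.9977                  99.77
#> 2    mir02    0.9877                  98.77
#> 3    mir03    0.9980                  99.80
#> 4    mir04    0.9831                  98.31
#> 5  decoy01    0.6601                  66.01
#> 6  decoy02    0.9850                  98.50
```

The full pipeline (simulate → seed matching → miRNA selection → ICA →
enrichment → correlation baseline → superposition → cooperativity →
pathways) runs as stages with TSV outputs and JSON provenance sidecars:

```r
run_pipeline(list(paths = list(outdir = "icamir_run")), "all")
```

or from the shell:

```sh
Rscript -e 'icamir::icamir_main()' all --config run.json --seed 1
```

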