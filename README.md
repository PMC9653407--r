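# cidmem

Analysis of **cancer–immune doublet (CID)** experiments in which a single
natural killer (NK) cell and a single cancer cell are co-incubated in a
microfluidic chamber, imaged hourly for their cell–cell distance, and
sequenced as one library at the terminal timepoint. The package asks whether
the terminal transcriptome remembers earlier proximity — *transcriptional
memory* — and provides everything around that question: chamber
classification and QC filtering, the core correlation statistic, gene-module
discovery, an mRNA half-life association test, a doublet-specific
ligand–receptor co-expression screen, killing-event differential expression,
and a synthetic-data generator with ground truth for benchmarking.

## The statistic at the core

Given a filtered expression matrix **E** (|G| genes × |C| doublets, terminal
RSEM-style values) and a distance matrix **D** (|C| doublets × |T| hourly
timepoints, µm), the pipeline computes the gene × timepoint correlation map

ρ<sub>g,t</sub> = corr( E[g, ·], D[·, t] )   (Pearson, pairwise-complete
over doublets),

retains *memory genes* with max<sub>t</sub> |ρ<sub>g,t</sub>| ≥ 0.25, and
cuts their hierarchical clustering into k = 4 modules M1–M4 ordered by peak
timepoint. Module membership is then tested against mRNA half-lives (Welch
two-sample t-test, module vs non-module genes: long-lived transcripts should
preferentially carry memory), ligand–receptor pairs are screened for
co-expression specific to doublets (pairwise Pearson > 0.4 in the doublet
group, with a singlet rule-out), and killing vs non-killing doublets are
compared at adjusted p < 0.05 and |log2FC| ≥ 1.

## Worked example

Simulate a full experiment at the default study conditions (336 chamber
libraries, 3000 genes, 102 distance-tracked doublets over 16 image frames)
and run the pipeline end to end:

```r
library(cidmem)

sim   <- simulate_cid_experiment(sim_config(seed = 1))
paths <- write_simulation(sim, "sim")

cfg <- pipeline_config(manifest   = paths[["manifest"]],
                       expression = paths[["expression"]],
                       distances  = paths[["distances"]],
                       halflife   = paths[["halflife"]],
                       lr_pairs   = paths[["lr_pairs"]])
run <- run_pipeline(cfg, "results")
run
#> cidmem pipeline run -> results
#>   336 chambers: 46 excluded, 290 retained; |C| = 102
#>   302 memory genes in 4 modules ( 71/72/87/72 )
```

The 46 exclusions split into 4 start-empty chambers, 8 cancer-to-empty, 10
NK-to-empty, 2 NK-start doublets and 22 doublet-to-cancer-only; the retained
290 are 77 NK singlets, 71 cancer singlets, 132 intact doublets and 10
killing-event doublets, and 102 doublets carry distance trajectories into
the correlation map. Downstream:

```r
run$halflife$test[c("t", "p")]
#> $t
#> [1] 4.228505
#> $p
#> [1] 3.419764e-05          # memory genes have longer half-lives

head(run$lr$results[run$lr$results$qualified,
                    c("gene_A", "gene_B", "rho_CID", "rho_NK", "rho_cancer")])
#>    gene_A gene_B rho_CID  rho_NK rho_cancer
#> 9   G0940  G2356    0.83 -0.067    -0.0274   # coordinated only in doublets
#> 14  G2439  G2260    0.54  0.039    -0.0353
#> ...

run$counts$n_de_significant
#> [1] 21                    # killing-event signature (20 genes planted)
```

Because the data are simulated, every planted effect can be checked against
`sim$truth`: module membership and peak timepoints, per-gene half-lives,
coordinated ligand–receptor pairs, upregulated killing genes, and kill
times. `render_report(run)` writes a Markdown summary; figures (module
heatmap, half-life boxplot, per-pair barplots) are written when
`figures = TRUE`. A thin command-line wrapper ships in
`inst/scripts/cidmem.R` (`simulate`, `run`, `report` subcommands).

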