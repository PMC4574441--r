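# nucpos

Morphology-corrected analysis of 3D gene positioning relative to
heterochromatin in mammalian nuclei.

## The problem

In mouse nuclei, two heterochromatin compartments are candidate "silencing
compartments": the nuclear periphery (facultative heterochromatin at the
lamina) and chromocenters (DAPI-dense clusters of pericentric constitutive
heterochromatin). Testing whether a gene's distance to either compartment
relates to its expression is confounded by morphology: nuclei change shape
and size drastically during myogenic differentiation (myoblast → myotube),
and chromocenters fuse into fewer, larger bodies. Raw micrometre distances
are therefore not comparable across conditions.

`nucpos` implements the single-cell Monte Carlo normalization that removes
this confound, and every statistic downstream of it. For each nucleus,
10,000 random points are simulated uniformly over the segmented nuclear
volume and their distances to both compartments measured; an actual locus
distance *d* is re-expressed as its mid-rank percentile within that same
nucleus's background sample,

&nbsp;&nbsp;&nbsp;&nbsp;*d̃* = (#{bᵢ < d} + ½·#{bᵢ = d}) / n ∈ [0, 1].

Under random positioning *d̃* is uniform, so binning normalized distances
in 0.25 steps gives 25% per bin and divergence is tested by
χ² = Σ(Oᵢ−Eᵢ)²/Eᵢ on 3 df. Repositioning between conditions (ΔD, mean
normalized distance change per gene) is correlated with expression log2
fold changes by Pearson's R with Fisher-z confidence intervals, at four
genomic scales (gene, ~180-kbp BAC probe, 2-Mbp and 5-Mbp neighborhoods),
and gene positions are correlated with RIDGE/anti-RIDGE features of the
surrounding 2-Mbp window (CpG-island count, %GC, gene density, %SINE,
%LINE). Expression input is an RMA-style log2 matrix processed with a
Nalimov outlier filter (p = 0.001), antilog-mean fold changes, Student's
t tests and ANOVA, and selection at p ≤ 4×10⁻⁶.

A first-class synthetic-data generator (nuclei with myoblast-/myotube-like
chromocenter morphologies, rank-targeted locus placement, replicate
expression with planted effects, and a genome with RIDGE-like and
anti-RIDGE-like blocks) makes the whole pipeline testable end to end with
no external data.

## Worked example

```r
library(nucpos)

## a small synthetic study: 12 nuclei per condition, 40 genes,
## planted coupling rho = 0.8 between repositioning and expression
cfg <- synthetic_config(rng_seed = 1, n_nuclei = 12, n_genes = 40,
                        nucleus_semiaxes = c(4, 4, 2),
                        voxel_size = c(0.1, 0.1, 0.25),
                        n_background = 5000, planted_rho = 0.8)

study <- simulate_repositioning_study(cfg)   # place, measure, normalize
expr  <- generate_expression(
  synthetic_config(rng_seed = 1, n_genes = 40, noise_sd = 0.1,
                   planted_log2fc = setNames(study$planted$log2fc,
                                             study$planted$gene_id)))
est <- collapse_to_gene(fold_change(expr$matrix, expr$samples, "MB", "MT"),
                        expr$probe_map)

## is positioning random? (chi-square on 0.25-binned normalized distances)
nt <- study$norm_table
per_mb <- nt$value[nt$compartment == "periphery" & nt$condition == "MB"]
randomness_test(per_mb, gene_id = "all", condition = "MB",
                compartment = "periphery")
#>   gene_id condition compartment o1  o2  o3 o4   n   chi2 df      p_value
#> 1     all        MB   periphery 16 238 199 27 480 330.25  3 2.817048e-71
#>     verdict
#> 1 nonrandom

## does repositioning track expression change?
correlate_repositioning(
  study$delta[study$delta$compartment == "periphery", ], est,
  scale = "gene", system = "differentiation")
#>   scale          system compartment      feature         r  ci_lower  ci_upper
#> 1  gene differentiation   periphery delta_log2fc 0.8125164 0.6707877 0.8969914
#>        p_value  n
#> 1 1.939065e-10 40
```

The randomness test flags the planted, mid-nucleus-concentrated locus
distribution as nonrandom (loci are placed at target quantiles around 0.5,
so the two middle bins dominate), and the gene-scale correlation recovers
the planted ρ = 0.8 as R = 0.81 with a confidence interval covering the
truth. A positive R is the "silencing compartment" direction: up-regulated
genes move away from the compartment. With only 12 nuclei per condition
the run also logs a warning that it is below the 47-nuclei study benchmark
— expected for this toy size.

`run_pipeline(default_run_config(rng_seed = 1), outdir = "nucpos_run")`
executes the same logic end to end (two condition pairs, expression,
randomness summary, genomic context, both correlation reports) and writes
CSV reports plus a JSON manifest with seeds and file hashes; reruns with
the same seed are byte-identical.

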