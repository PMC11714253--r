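# fluxcyte

Metabolic flux estimation and CD8+ T-cell cytotoxicity correlation from
bulk transcriptomics.

Tumor metabolism shapes anti-tumor immunity: in colorectal cancer,
glutaminolysis and the glutamate-to-glutathione branch buffer reactive
oxygen species and suppress tumor antigen presentation, so the genes and
fluxes of this pathway tend to track *against* CD8+ T-cell cytotoxicity
across patient cohorts. fluxcyte implements the computational side of
that analysis for anyone with gene-by-sample expression matrices:

1. **Neural flux estimation on a metabolic factor graph.** Central
   metabolism is a directed bipartite graph of reaction modules (factors,
   each with a gene set) and metabolites (variables). The flux of module
   $m$ in sample $j$ is a small fully connected network of the module's
   genes, $Flux_{m,j} = f^m_{nn}(G^m_j \mid \theta_m)$, trained jointly by
   minimizing

   $$L=\sum_{j,k}\Big(\textstyle\sum_{m \in F_{in}(C_k)} Flux_{m,j}-\sum_{m' \in F_{out}(C_k)} Flux_{m',j}\Big)^2+\alpha\sum_{j,m}\big(|Flux_{m,j}|-Flux_{m,j}\big)+\beta\sum_j\Big(\textstyle\sum_m Flux_{m,j}-TA_j\Big)^2$$

   (flux balance at every intermediate metabolite, non-negativity, and
   anchoring of each sample's total flux to its total metabolic activity
   $TA_j$; defaults $\alpha = 1$, $\beta = 0.1$).
2. **Cytotoxicity scoring.** Marker-signature scores for CD8+ T-cell
   abundance (CD3E, CD2, CD3G, CD3D, SIRPG, CD6, TIGIT) and cytotoxic
   level (CD8A, SLA2, NKG7, PRF1, GZMA, GZMH), combined into the
   relative-cytotoxicity statistic: total cytotoxic level / total CD8+
   T-cell abundance.
3. **Cross-cohort ranking.** Per-cohort Pearson correlation of every gene
   (or module flux) against relative cytotoxicity, averaged across
   cohorts (unweighted) and ranked in increasing order — the most
   negatively correlated feature first — plus module-by-effector-gene
   correlation tables (GZMA, TNF, IFNG, PRF1).

A bundled curated-style network (31 modules, 16 intermediate + 15 end
metabolites, 253 genes; glutamate-to-glutathione is `M27`,
glutamate-to-2-oxoglutarate is `M28`) and a synthetic multi-cohort
generator with known ground truth make the whole pipeline testable
offline. See `vignettes/flux-cytotoxicity.Rmd` for the model, the
generator's stated world, and every numerical decision.

## Worked example

```r
library(fluxcyte)

g <- make_toy_graph("glnlike6")                    # Gln -> Glu -> {GSH, 2-OG} analog
truth <- simulate_balanced_flux(g, n_samples = 100, seed = 7)
expr  <- simulate_expression(truth, g, noise_sd = 0.2, seed = 7)
fit   <- fit_flux(expr, g, flux_config(seed = 7))
fit
#> <flux_fit> 100 samples x 6 modules; 1000 epochs (best at 1000), total loss 155669 -> 17608
round(diag(cor(fit$flux, truth)), 2)
#>   M1   M2  M27  M28   M5   M6
#> 0.81 0.83 0.89 0.88 0.87 0.86
```

The fitted sample-by-module fluxes correlate with the generating ground
truth at r = 0.81–0.89 per module. On a nine-cohort simulation with a
planted metabolic gene anti-proportional to latent cytotoxicity, the
ranking recovers it:

```r
sim <- simulate_cohorts(simulation_spec(n_samples = 100, seed = 1), n_cohorts = 9)
cc  <- as_cohort_collection(sim)
rank_features(cc, rownames(sim$cohorts[[1]]$expr)) |> head(3)
#>   feature cohort_01 cohort_02 ... avg_pcc rank
#> 1     GLS    -0.812    -0.895     -0.864    1
#> 2  M27_g2    -0.817    -0.771     -0.798    2
#> 3   M5_g1    -0.821    -0.789     -0.779    3
```

The planted `GLS` attains rank 1 (average PCC −0.86 across the nine
cohorts); the runners-up are genes of the anti-coupled glutathione-branch
modules. The branch discrimination readout separates the coupled and
uncoupled branches of the ground-truth flux:

```r
flux_effector_correlation(sim$cohorts[[1]]$true_flux, sim$cohorts[[1]]$expr)
#>   module   GZMA    TNF   IFNG   PRF1
#>      M27 -0.487 -0.423 -0.445 -0.493   # glutathione-branch analog: negative
#>      M28 -0.078 -0.024 -0.074 -0.025   # 2-OG-branch analog: near zero
```

`run_pipeline(config)` chains every stage (simulate or load -> validate ->
fit -> score -> rank -> flux/effector), writes one TSV per stage with a
version+seed header, and records a `manifest.json`; identical config and
seed reproduce all outputs byte-identically.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package — simulating a nine-cohort world, fitting fluxes,
scoring cytotoxicity, and ranking genes — and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
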