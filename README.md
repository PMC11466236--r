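# clpnet

Cross-lagged panel network (CLPN) analysis for two-wave ordinal symptom
data, built for comorbidity research on non-suicidal self-injury (NSSI),
depression and anxiety in adolescents.

A CLPN treats each directed edge *i → j* as the regression coefficient
β<sub>ij</sub> of wave-1 symptom *i* predicting wave-2 symptom *j* while
controlling for **all** wave-1 symptoms and covariates:

y<sub>j</sub><sup>(2)</sup> = α<sub>j</sub> + Σ<sub>i</sub> β<sub>ij</sub> y<sub>i</sub><sup>(1)</sup> + γ<sub>j</sub>ᵀ z + ε<sub>j</sub>

Each of the 24 wave-2 symptoms (12 NSSI behaviors, 6 depression items,
6 anxiety items, scored 0–4) is fit with an L1 (lasso) penalty — minimizing
(1/2n)·RSS + λΣ|β| with λ chosen by 10-fold cross-validation — so weak
edges shrink exactly to zero. The fitted directed network (552 cross-lagged
edges plus 24 autoregressive edges) supports:

- **expected-influence centrality**: out-EI(i) = Σ<sub>j≠i</sub> β<sub>ij</sub>,
  in-EI(j) = Σ<sub>i≠j</sub> β<sub>ij</sub>;
- **bridge edges** between symptom communities (e.g., NSSI → depression),
  ranked by |β|;
- **display thresholding** (strict |β| > 0.06 by default);
- **bootstrap edge accuracy**: subject resampling with percentile CIs;
- **network comparison**: edge-weight correlation, overlap percentages and
  the Jaccard index between group-specific (boys'/girls') networks.

Because no subject-level data are distributed, the package includes a
synthetic panel generator (latent multivariate normal + threshold
discretization) whose default ground truth encodes the emulated study
design: n = 884 (403 boys / 481 girls), two waves six months apart,
any-NSSI wave-1 prevalence calibrated to 23.3%, and the group-specific
bridge weights (e.g., boys' self-cutting N9 → feeling blue D2 = −0.57).
See the methods vignette (`vignettes/clpn-methods.Rmd`) for the model, the
generator and all numerical choices.

## Worked example

```r
library(clpnet)

truth <- default_ground_truth()
sim   <- simulate_panel(truth, n_subjects = 884, seed = 1)
nssi_prevalence(sim$data, wave = 1)
#> [1] 0.2081448

boys <- fit_clpn(simulate_panel(truth, 884, seed = 3, group = "boys")$data,
                 clpn_config(cv_seed = 3), group_filter = "boys")
boys
#> Cross-lagged panel network: 24 symptoms, 65/552 nonzero cross-lagged edges
#>   mean |autoregressive| = 0.00882;  mean |cross-lagged| = 0.00323
#>   fitted on 884 subjects

bridge_edges(boys, from = "NSSI", to = c("DEP", "ANX"), top_k = 3)
#> # A tibble: 3 × 5
#>   from  to     weight from_community to_community
#>   <chr> <chr>   <dbl> <chr>          <chr>
#> 1 N5    D4     0.0759 NSSI           DEP
#> 2 N9    D1    -0.0573 NSSI           DEP
#> 3 N9    D2    -0.0533 NSSI           DEP
```

The prevalence (20.8% in this seed, 23.3% on average across seeds) matches
the generator's calibration target. In the fitted boys' network the strong
negative self-cutting bridges (N9 → D1, N9 → D2) are recovered with the
correct sign but attenuated magnitude: regressing rare zero-inflated
ordinal items caps the observed-scale coefficient of a latent −0.57 effect
near −0.09 (the vignette quantifies this), and with the three true bridge
weights nearly tied, which one ranks first varies by sample — so read
top-k lists, not single winners.

`tidy()`, `glance()`, `autoplot()` and `plot_centrality()` work on fitted
networks; `bootstrap_edge_cis()` returns per-edge percentile intervals
with `tidy()`/`autoplot()` methods; `run_simulate()` / `run_analyze()` /
`run_compare()` write the full artifact set (network JSON, centrality and
bridge CSVs, comparison JSON, manifest), and `inst/cli/clpn.R` is a thin
command-line wrapper over them.

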