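# symptomnet

Network analysis of depression–anxiety comorbidity from ordinal symptom
questionnaires, for psychometric and clinical-epidemiology researchers.
Instead of treating the PHQ-9 (nine depression items, `D1`–`D9`) and GAD-7
(seven anxiety items, `A1`–`A7`) as indicators of two latent diseases, the
package estimates the *symptom network*: a Gaussian graphical model whose
edges are regularized partial correlations `ρ_ij· = −κ_ij / √(κ_ii κ_jj)`
between items after conditioning on all others, fitted by the graphical
lasso on the Spearman rank correlation matrix and selected over a penalty
path by the extended BIC (`EBIC_γ = −2ℓ + E log n + 4 E γ log p`,
`γ = 0.5`).

On top of the estimated network it computes the quantities this analysis
family reports:

- **Expected influence** (signed sum of a node's edges) and **bridge
  expected influence** (signed sum of its cross-community edges), with
  bridge symptoms selected by an 80th-percentile rule;
- **Predictability** (share of an item's variance explained by its
  neighbours);
- a **flow decomposition** of all paths into one focal symptom (by
  default `D9`, suicidal ideation);
- the full bootstrap **accuracy/stability suite**: percentile edge-weight
  CIs, case-dropping correlation-stability (CS) coefficients, and
  pairwise bootstrapped difference tests;
- a **synthetic cohort generator** (latent Gaussian + per-item thresholds,
  known sparse truth network, planted bridge symptoms) so every stage is
  testable by parameter recovery;
- item-level plumbing: validation with complete-case exclusion, total
  scores, severity bands, Cronbach's alpha.

## Worked example

```r
library(symptomnet)

# a 566-subject synthetic cohort with the default two-community truth
coh <- sample_cohort(generator_spec(seed = 1))
coh
#> <synthetic_cohort> <item_matrix> 566 subjects x 16 items (anxiety: 7, depression: 9)

net <- estimate_network(coh$responses)
net
#> <symptom_network> 16 nodes, 28/120 edges (lambda = 0.119, EBIC gamma = 0.5, n = 566)
```

Of the 120 possible edges among 16 symptoms, the EBIC-selected network
keeps 28. The strongest edges and the selected bridge symptoms:

```r
head(edge_list(net)[order(-abs(edge_list(net)$weight)), ], 3)
#>    from to    weight
#> 19   D7 A6 0.2019991
#> 3    D2 D4 0.1977213
#> 16   D7 A3 0.1674267

prof <- centrality_profile(net)
prof[prof$is_bridge, c("node", "community", "bei", "bei_z")]
#>    node  community       bei     bei_z
#> 7    D7 depression 0.5187058 2.9544316
#> 15   A6    anxiety 0.2019991 0.6780804
#> 16   A7    anxiety 0.2649368 1.1304496
```

`bei` is each node's summed cross-community edge weight; the three nodes
at or above the 80th percentile are flagged as bridge symptoms (here two
of the three planted bridges, `D7` and `A7`, plus `A6` — at n = 566
sampling noise can displace a marginal bridge, which is exactly what the
stability suite is for). Predictability, the flow view of suicidal
ideation, and the case-dropping stability of expected influence:

```r
node_predictability(coh$responses, net)
#> <predictability_profile> mean R2 = 0.131 over 16 nodes

flow_network(net, "D9")
#> <flow_decomposition> focal D9: 1 direct, 14 indirect

cs_coefficient(coh$responses, "expected_influence",
               drop_proportions = seq(0.05, 0.75, by = 0.1),
               nboots = 50, seed = 1)
#> <cs_report> CS(expected_influence) = 0.25 (threshold 0.7, confidence 0.95, nboots 50)
```

CS = 0.25 means the expected-influence ranking still correlates ≥ 0.7
with the full-sample ranking (with 95% certainty) after dropping a
quarter of the subjects — the conventional minimum for interpreting a
centrality ordering. `run_pipeline(pipeline_config(...))` chains all of
the above and writes the scored table, correlation matrix, edge list,
GraphML, centrality/predictability CSV, CI and difference-test reports,
CS curves, flow JSON, layout and a deterministic manifest into one output
directory.

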