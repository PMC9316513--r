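# painnet

Regularized partial-correlation network analysis for mixed
continuous/binary questionnaire cohorts, built around the symptom-network
phenotyping of post-COVID pain: 14 nodes (age, gender, weight, height,
months since symptom onset, EQ-5D-5L, PainDETECT, S-LANSS, CSI, HADS-A,
HADS-D, PCS, TSK-11, PSQI), a Gaussian graphical model estimated by
graphical lasso with EBIC model selection, weighted-graph centrality
indices, and bootstrap stability analysis. The package is aimed at
biostatisticians and clinical researchers who want a tested, reproducible
implementation of this workflow together with a synthetic-cohort
generator that makes every stage verifiable against a known ground truth.

## The model

Observations are assumed multivariate normal with precision matrix
`K = Σ⁻¹`. The edge weight between nodes *i* and *j* is the partial
correlation

```
ρ_ij = −κ_ij / √(κ_ii κ_jj)
```

i.e. the association between two variables after conditioning on all
other nodes. `K` is estimated by maximizing the L1-penalized
log-likelihood

```
log det K − tr(S K) − λ Σ_{i≠j} |κ_ij|
```

(graphical lasso; diagonal unpenalized) over a 100-point log-spaced grid
of penalties, selecting λ by the Extended Bayesian Information Criterion
`EBIC = −n·ℓ(K) + E·log n + 4·γ·E·log p` with γ = 0.5. The input `S` is
Pearson for continuous pairs and polyserial (latent-scale maximum
likelihood) for pairs involving the binary gender node. Centrality is
computed on the weighted graph: strength `Σ_j |w_ij|`, closeness
`1/Σ_j d(i,j)` and betweenness (fraction of shortest paths through a
node), with shortest-path distances `1/|w|`. Stability is quantified by
a nonparametric edge-weight bootstrap (95% percentile CIs) and the
case-dropping subset bootstrap summarized by the CS coefficient: the
largest proportion of participants that can be dropped while subsample
centralities keep correlating ≥ 0.7 with the full-sample ones in 95% of
replicates.

## Worked example

```r
library(painnet)

# a synthetic study cohort: 146 records from the planted 8-edge network,
# 3 PainDETECT + 3 S-LANSS cells missing completely at random
cohort <- simulate_cohort(n = 146, seed = 2026)
flt <- complete_case_filter(cohort)
S <- mixed_matrix(flt$table)           # Pearson + polyserial
net <- select_network(S)$network       # EBIC-glasso
print(net)
```

```
<pcor_network> 14 nodes, 6 edges (lambda = 0.2184)
  Gender -- CSI: +0.211 (unsigned-categorical)
  HADS_A -- HADS_D: +0.467 (positive)
  HADS_A -- CSI: +0.225 (positive)
  PainDETECT -- S_LANSS: +0.133 (positive)
  PainDETECT -- CSI: +0.052 (positive)
  PCS -- TSK_11: +0.267 (positive)
```

At this sample size the penalty prunes the two weakest planted edges and
shrinks the rest toward zero — the expected behavior of regularized
estimation on ~140 records. Centralities and their stability:

```r
centrality_table(net)                  # strength/closeness/betweenness
cd <- case_dropping(flt$table, B = 100, seed = 302)
cs_coefficient(cd)
```

```
<cs_coefficient> (cor >= 0.7, confidence 0.95)
  strength: 0.5  closeness: 0  betweenness: 0.2
```

Strength is the most stable index; closeness collapses under
case-dropping — the same qualitative ordering reported for this design.
The numbered scripts under `analysis/` run the full workflow
(simulation, estimation, centrality, stability, recovery benchmark) and
write their tables under `results/`.

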