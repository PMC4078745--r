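# dyncausal

Constraint-based causal structure discovery for dynamic processes, with
explicit treatment of latent common drivers, and exact Gaussian
vector-autoregressive analytics for Granger causality.

## The problem

Effective-connectivity analysis asks which directed causal interactions exist
among a set of simultaneously recorded time series — for example
electrophysiological or neuroimaging signals from different brain regions.
Two traditions address this question. Granger causality tests, for a pair of
processes $X, Y$ in a context $Z$, the conditional-independence criterion

$$p(Y_{i+1} \mid \{V\}^i) = p(Y_{i+1} \mid \{V\}^i \setminus X^i),$$

quantified by the transfer entropy
$T_{X \to Y \mid Z} = I(Y_{i+1};\, X^i \mid Y^i, Z^i)$ and complemented by the
instantaneous-causality measure
$T_{X \cdot Y \mid Z} = I(X_{i+1};\, Y_{i+1} \mid X^i, Y^i, Z^i)$.
Constraint-based ("inductive causation") structure learning instead searches,
for every pair of variables, for a conditioning set that renders them
independent, and assembles the answers into a graph representing the whole
class of causal structures compatible with the data — including, in its
latent-variable form, explicit marks for hidden common causes.

`dyncausal` implements both traditions and their combination:

* **Graphs.** Process graphs (one node per process, lagged directed edges,
  latent flags), their time-unrolled DAGs, and the typed outputs of the
  inference algorithms (patterns, embedded patterns with
  potential/genuine/bidirectional arrows, mixed macroscopic graphs).
* **Separation.** d-separation on all graph flavors (including hybrid edge
  types), the ancestral-pruning procedure, and graphical sufficient
  conditions for Granger and instantaneous non-causality on macroscopic
  graphs.
* **Inference.** The IC and IC\* algorithms, the temporal simplification of
  IC for latent-free dynamic processes, and ICG\*, which runs the
  conditioning-set search over transfer-entropy and instantaneous-causality
  queries and outputs one node per process, marking latent common drivers
  with bidirectional arrows.
* **Gaussian analytics.** Linear Gaussian VAR(1) models with observation
  maps (mixing, additive noise, subsampling), stationary covariance
  sequences from the discrete Lyapunov equation, and exact computation of
  all information measures from covariance determinants.
* **Aggregation study.** A quantitative reproduction of how measurement
  noise, time aggregation and especially spatial aggregation of signals
  create *inconsistent positives* — positive Granger causality with no
  corresponding arrow in the generating structure.

## Worked example

A bivariate system in which `Y` drives `X` but not conversely:

```r
library(dyncausal)

m <- var_model(rbind(c(0.8, 0.5),
                     c(0.0, 0.8)), names = c("X", "Y"))
transfer_entropy(m, src = "Y", dst = "X")
#> 0.185097 nats (0.267039 bits), L = 20 lags, converged: yes
transfer_entropy(m, src = "X", dst = "Y")
#> 5.55112e-15 nats (8.00857e-15 bits), L = 20 lags, converged: yes
```

The uncoupled direction is exactly zero (up to determinant round-off); the
coupled direction is positive. When the two observed processes are instead
driven by a hidden common cause, ICG\* reports exactly that:

```r
sys <- fixture_var("common_driver")        # latent autocausal driver of X and Y
icg_star(granger_oracle_gaussian(sys$model, sys$obs))
#> Mixed macroscopic graph: 2 nodes, 1 edges
#>   X <-> Y
```

The bidirectional arrow states that no conditioning set of observed
processes cancels the instantaneous causality, which is possible only if at
least one latent common driver exists. The same graph is obtained from the
purely graphical oracle (d-separation on the ground-truth unrolled
structure), as the algorithm's answers depend only on the independence
structure:

```r
icg_star(granger_oracle_graphical(fixture("common_driver_pair")))
#> Mixed macroscopic graph: 2 nodes, 1 edges
#>   X <-> Y
```

Spatial aggregation: when each recorded signal is a weighted average of two
underlying processes and every true interaction runs from area X to area Y,
the reverse-direction transfer entropy is nonetheless positive, and its
relative magnitude $r = T_{Y\to X}/T_{X\to Y}$ can exceed 1 on parts of the
coupling plane:

```r
rg <- r_map()    # c12, c21 in [-1, 1], step 0.05; 20 lags
rg
#> r grid: 41 x 41 cells, 494 excluded (non-stationary)
#>   recorded r: min 1.02e-07, median 0.0448, max 1.47
```

A causal analysis performed on aggregated signals therefore characterizes
intra-areal mixing at least as much as inter-areal interaction, and no
inference algorithm operating on the aggregates can undo this.

A thin command-line front end over these functions is installed at
`inst/scripts/dyncausal.R` (subcommands `dsep`, `ic`, `icstar`, `icgstar`,
`te`, `simulate`, `experiment`, `fixtures`).

## Package layout

* `R/graph-classes.R`, `R/graph-ops.R` — graph containers, unrolling,
  skeletons, v-structures, observational equivalence.
* `R/dsep.R` — d-separation (section-aware traversal on hybrid graphs),
  pruning procedure, graphical non-causality conditions.
* `R/var-model.R`, `R/information.R` — VAR models, observation maps,
  stationary covariances, transfer entropy and instantaneous causality.
* `R/oracles.R`, `R/ic.R` — conditional-independence and Granger oracles;
  IC, IC\*, temporal IC, ICG\*.
* `R/experiments.R` — the aggregation studies and observation-effect
  demonstrations.
* `R/fixtures.R`, `R/io.R` — worked-example systems; JSON/DOT/YAML I/O.
* `vignettes/causal-discovery-dynamics.Rmd` — the methods vignette.
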