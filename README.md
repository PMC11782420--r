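# glykin

Quantitative analysis of protein N-linked glycosylation: reaction-network
pruning, four-compartment Golgi kinetic modelling with competing protein
entities, and staged ABC-SMC parameter estimation.

## What it does, and for whom

As a glycoprotein transits the Golgi, a high-mannose precursor (M9) is
matured by eleven resident enzymes into complex-type N-glycans. The
biosynthesis is a directed acyclic graph — nodes are glycan structures in
LinearCode, edges are reactions labelled by enzyme — but template networks
built from enzyme specificities are far larger than anything one cell
actually realises. `glykin` is aimed at glycoengineers and systems
biologists who want to go from an observed glycoprofile (tag-level relative
abundances such as `M5`, `FA2`, `FA2G2S1`) to a parameterised mechanistic
model:

* **Prune** a template network to the observed structures, by the union of
  all shortest source-to-sink paths (SPF) or by minimum-flow reachability
  (MFR, one flow unit per sink at minimal total flow); compare the results
  by overlap, attribute-aware isomorphism, subgraph containment and graph
  edit distance.
* **Simulate** the pruned network as four well-mixed Golgi compartments in
  series. Glycosidases follow Michaelis–Menten kinetics; every
  glycosyltransferase follows sequential-order Bi-Bi kinetics,

  r = k_f [ENZ] [NSD] [OS] / ( K_m K_md [ 1 + ([NSD]/K_md)(1 + Σ [OS]_c/K_m,c) ] ),

  with the competition sum coupling all substrates of the enzyme across
  protein entities (e.g. an antibody and the host-cell protein pool
  competing for the same transferases). Transit velocity is inversely
  proportional to molecular weight; the steady state is solved
  compartment-wise with a MINPACK root finder and analytic Jacobians.
* **Estimate** enzyme levels and dissociation constants with an automated
  staged strategy: critical nodes (strictly above-median betweenness *and*
  dominance-frontier membership) split the network into stages, each stage
  gets an accumulation target profile, and an ABC-SMC sampler
  (multivariate-normal KDE proposals, weighted-median ε schedule, RMSE
  distance) is run per stage with MAP estimates fixed for later stages.

A 17-node toy network and a synthetic-profile generator make the whole
pipeline runnable and testable without any external data.

## Worked example

```r
library(glykin)

net <- make_toy_grn()
net
#> <glyco_grn> 17 nodes, 19 edges
#>   source: M9
#>   sinks: FA2G2S2, FA4

identify_critical_nodes(net)
#> <critical_node_report>
#>   critical tags: M5A1 -> FA2 -> FA2G2
#>   critical nodes: M5A1, FA2, FA2G2

model <- assemble_golgi_model(net, toy_entities(), params = toy_parameters())
res <- simulate_golgi(model)
res
#> <simulation_result> converged: TRUE  residual norm: 1.52e-16
#>   IgG: FA2=36.9 FA2G1=28.9 FA2G2=7.6 A2=5.6 FA3=3.4 M5=3.4 M6A1=2.4 ...
#>   HCP: M9=64.8 M8=29.3 M6=4.6 M5=0.7 M6A1=0.5 M5A1=0.1 ...

molar_balance(res)
#>   entity inlet outlet rel_error
#> 1    IgG   5.0    5.0         0
#> 2    HCP   1.5    1.5         0
```

The three critical tags are the convergence hubs of the maturation
pathway; the heavy entity (IgG, 150 kDa) matures to a core-fucosylated
complex-type profile dominated by FA2, while the light, low-affinity
host-cell pool stays high-mannose (M9/M8) — the qualitative contrast seen
in biomanufacturing cultures. Zero relative error in the molar balance
confirms glycans are only interconverted, never created or destroyed.

Pruning and comparing:

```r
compare_graphs(prune_spf(net), prune_mfr(net))
#> <graph_comparison>
#>   node overlap: 14   edge overlap: 13
#>   isomorphic: FALSE
#>   GED: 25 (upper bound)   normalised: 1.562
#>   subgraph 1-of-2: FALSE   2-of-1: TRUE
```

MFR resolves the either-arm galactosylation fork to a single arm, so it is
a strict labelled subgraph of SPF.

For the estimation pipeline, see `derive_strategy()`, `run_sequential()`
and the methods vignette
(`vignettes/golgi-glycosylation-modelling.Rmd`), which documents the
model, its assumptions, the staged targets and the calibration of the
ABC sampler.

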