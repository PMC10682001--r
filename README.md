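# sgdynamics

Time-resolved analysis of stress-granule (SG) proteome composition.

Stress granules are cytoplasmic RNA-protein condensates that form
under stress by phase separation. Their protein content is not
static: across a heat-shock time course, some constituents are shed
early while others accumulate late. `sgdynamics` implements, as a
tested R package plus a numbered analysis workflow, the full
quantitative pipeline for dissecting that life cycle from
tandem-mass-tag (TMT) pull-down proteomics of two SG markers (G3BP1
and CAPRIN1) sampled at HS0–HS180 min of heat shock and 5/10 min of
recovery, together with an unstressed G3BP1-overexpression condensate
condition ("SG-ls") used as a stress-independence control.

It is written for proteomics / cell-biology analysts who want each
stage as a reusable, unit-tested function: quantitative table I/O and
record filtering, normalization, dynamic-protein classification,
temporal clustering with kinetic fits, condensate enrichment scoring,
biochemical-property and protein-interaction-network comparisons, and
granule image quantification. Seeded synthetic-data generators with
known ground truth stand in for the raw study data, so every stage is
verifiable end to end without downloads.

## The models at the core

* **Normalization.** Column scaling to the mean total; parametric
  empirical-Bayes batch correction across TMT replicates (per-batch,
  per-protein location/scale effects `γ`, `δ` shrunk to normal /
  inverse-gamma priors; condition groups early/middle/late as
  covariates); trimmed-mean-of-M-values (TMM) factors with a
  rank-based double trim (30 % on M = log2 x/ref, 5 % on
  A = ½·log2 x·ref) and precision weights 1/(1/x + 1/ref).
* **Dynamic/invariable rule.** Per protein,
  `fc_up = max(HS10..Re10)/HS0` and `fc_down = HS0/min(HS10..Re10)`
  on replicate means; *dynamic* ⇔ fc_up > 1.2 or fc_down > 1.2 in
  **both** pull-down datasets.
* **Temporal groups.** Unit-variance z-profiles of dynamic proteins
  (CAPRIN1 dataset), hierarchical clustering with Chebyshev distance
  and average linkage cut at k = 2, and group-mean kinetics fitted
  with the four-parameter logistic
  `v(t) = lower + (upper − lower)/(1 + e^{−slope·(t − t0)})`,
  whose `t0` is the inflection time of SG entry/exit.
* **SG-ls enrichment.** `z(log2(SGls / max(HS10..Re10)))`
  standardized across the cohort: positive = stress-independent
  recruitment to G3BP1 condensates, negative = heat-shock-dependent.
* **Network topology.** Degree, density 2E/(N(N−1)), average
  shortest path, and Newman–Girvan modularity
  `Q = Σ_c [e_c/m − (d_c/2m)²]` contrasted between the early core
  and the late modules.
* **Imaging.** Otsu-within-mask segmentation with 8-connected
  components, granule/cell enrichment ratios, greedy
  nearest-neighbour particle tracking, and fusion-event detection
  (two tracks converging into one surviving track that conserves at
  least 80 % of the summed area).

## Worked example

The `analysis/` directory is a numbered workflow over the package;
each script prints what it found and writes tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize.R
Rscript analysis/03_classify_cluster.R
```

Output from a run of steps 1–3:

```
simulated 330 proteins (150 early, 100 late, 80 invariable; 30 ribosomal-like)
G3BP1: 30 samples (incl. SG-ls); CAPRIN1: 27 samples
G3BP1: 330 proteins kept (...); batch gammas (log2) 0.000/-0.037/0.037
265 dynamic, 65 invariable proteins
early group: 150 proteins, decreasing sigmoid, inflection 18.9 min
late group:  115 proteins, increasing sigmoid, inflection 30.5 min
early/late agreement with planted truth: 1.000
```

Read: of 330 simulated proteins, 265 exceed the 1.2-fold rule in both
baits (all 250 planted dynamics plus a minority of flat proteins that
leak past the threshold — see the vignette on the compositional
normalization bias); clustering splits them into a decreasing early
group inflecting ~19 min into heat shock and an increasing late group
inflecting ~30 min, matching the planted 21/30-min kinetics, and
every planted early/late protein lands in the right group. Steps 4–6
continue with SG-ls scoring (planted early proteins score positive,
late negative, the ribosomal-like subset negative), network contrasts
(dense low-modularity early core, sparse high-modularity late
modules: density 0.256 vs 0.168, best-partition Q 0.20 vs 0.73) and
movie quantification (granule counts and planted fusion events
recovered exactly; fusion frequency 21/25 vs 8/25 regions,
chi-square 13.9).

The methods vignette (`vignettes/sg-proteome-dynamics.Rmd`) documents
the models, parameter choices, numerical details and limitations.

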