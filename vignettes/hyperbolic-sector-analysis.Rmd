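---
title: "Hyperbolic geometry of protein interaction networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic geometry of protein interaction networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarPIN)
```

## The model

Scale-free, strongly clustered networks — the human protein interaction
network (hPIN) among them — are well described by the popularity–similarity
(PS) model. Every node occupies a point $(r, \theta)$ of the hyperbolic
plane $\mathbb{H}^2$ (curvature $-1$; we fix the curvature parameter, so
all lengths are dimensionless hyperbolic lengths). The radius encodes
*popularity*: old, high-degree hubs sit near the centre. The angle encodes
*similarity*: functionally related proteins occupy nearby angles. Two nodes
at hyperbolic distance

$$x = \operatorname{arccosh}\left(\cosh r_p \cosh r_q -
      \sinh r_p \sinh r_q \cos\Delta\theta\right)$$

are connected with the Fermi–Dirac probability

$$p(x) = \frac{1}{1 + e^{(x - R)/(2T)}},$$

where $R$ is the connection radius and the temperature $T \in [0, 1)$
controls clustering: $T = 0$ is a sharp step (maximal clustering), and the
kernel softens as $T \to 1$. In the growth formulation, node $t$ is born at
radius $r_t = 2\ln t$ with a uniform angle, earlier nodes fade outward as
$r_s(t) = \beta r_s + (1 - \beta) r_t$ with popularity fading
$\beta = 1/(\gamma - 1)$ tied to the degree exponent $\gamma$, and each new
node establishes $m$ links. This is exactly what `generate_ps_network()`
simulates, and what the embedding inverts.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `score_threshold` | interaction-confidence cut | 0.71 | conventional high-confidence cut of curated interaction scores (unitless, in $[0,1]$) |
| `gamma` | degree exponent | 2.97 | maximum-likelihood tail fit of the filtered hPIN degree sequence |
| `temp` | temperature | 0.83 | hPIN clustering strength under the PS model |
| `w` | HM search window (radians) | $2\pi$ | global angular search; smaller values give local refinement |
| `g` | angular gap threshold (radians) | tuned | cut the similarity circle at gaps larger than `g` |
| `min_size` | minimum sector membership | 5 | smallest sector worth testing for enrichment |
| `p_max` | DE significance cut | 0.05 | standard selection of enriched transcripts (`log2FC > 0`, `p < 0.05`) |
| PWM `threshold` | log-odds cutoff (bits) | 6 | conventional scanning cutoff; a perfect deterministic 3-mer match scores exactly $3\log_2 4 = 6$ |

`m`, the PS link budget per node, is estimated from the data as
`max(1, round(mean_degree / 2))` when not supplied, because each arriving
node contributes $m$ links to the growing network.

## Embedding: LaBNE + HM

`labne()` builds the symmetric normalized Laplacian
$L = I - D^{-1/2} A D^{-1/2}$ and uses the eigenvectors of its two smallest
strictly positive eigenvalues as planar coordinates whose polar angle is
the initial similarity estimate. We chose the *normalized* Laplacian
because PIN degree sequences are heavy-tailed and the unnormalized spectrum
is dominated by hubs. Radii are assigned by degree rank,
$r_i = 2\beta\ln i + 2(1-\beta)\ln N$, and are never refined afterwards —
the two-step scheme fixes popularity by degree and only optimizes
similarity. Eigenvector signs are canonicalized (largest-magnitude entry
positive), which removes run-to-run reflection nondeterminism; the layout
remains meaningful only up to a global rotation/reflection, so all quality
measures used in this package (pairwise-distance correlations, angular
gaps) are rotation- and reflection-invariant.

`hm_refine()` then sweeps the nodes in decreasing degree order and moves
each node to the angle maximizing its local Bernoulli log-likelihood
against all other nodes, evaluated on a deterministic uniform grid of
`n_candidates` angles in a window `w` around the current angle, incumbent
included. Because the incumbent is always a candidate, the total
log-likelihood is non-decreasing across sweeps; the trace is recorded and
asserted. The refinement likelihood uses the full adjacency row (edges and
non-edges, no subsampling) — exact at the network sizes this package
targets; with 100 candidate angles a one-sweep refinement of a 500-node
network takes a few seconds, and a ~15,000-node network is the scale where
a coordinates cache (supported by the pipeline) becomes worthwhile.

A trade-off we measured and document rather than hide: with the global
window ($w = 2\pi$) and a coarse 100-angle grid, the refinement can
*increase* the likelihood substantially while leaving the
ground-truth-distance correlation essentially unchanged or a percent
lower than the spectral initialization — likelihood and metric recovery
are correlated but not identical objectives. Used as a *local* refinement
(e.g. $w = \pi/8$), HM improves both. The defaults keep the global window;
the window is a parameter precisely so users can choose.

Probabilities entering any likelihood are clipped into
$[10^{-12}, 1 - 10^{-12}]$ so that non-edges at tiny distances cannot
produce $-\infty$; the clip perturbs totals negligibly. Distances switch
from the exact $\operatorname{arccosh}$ form to the asymptotic
$r_p + r_q + 2\ln\sin(\Delta\theta/2)$ form when $r_p + r_q > 40$ (guarded
below by $|r_p - r_q|$): $\cosh$ overflows near 710, while at 40 the two
branches agree to much better than $10^{-6}$.

## Sectors in the similarity dimension

`angular_gap_clusters()` sorts nodes by inferred angle (ties broken by
node identifier, and zero gaps never split), computes consecutive gaps
including the wrap-around gap — the circle has no privileged origin, so
the wrap gap is cuttable like any other — and cuts wherever a gap exceeds
`g`. Sector identifiers start just after the largest gap and increase with
angle.

Undersized sectors are a policy question, deliberately separated from the
cutting mechanism. `"keep"` retains them with a warning. `"merge"` absorbs
an undersized sector into its neighbour across the smaller of its two
boundary gaps, repeatedly. `tune_gap_threshold()` scans every distinct
observed gap value as a cut level and returns the largest strict threshold
reproducing the partition with the most sectors subject to the size floor.
Under `"keep"` this reproduces the published procedure of choosing `g` so
that all sectors have at least five members — but a single angularly
isolated protein can veto every multi-sector partition. The pipeline
therefore tunes and clusters under `"merge"` by default, which we found
robust across synthetic replicates, at the price of producing finer
sectors than a hand-picked single `g`; passing an explicit `g` in the
configuration reproduces the fixed-threshold behaviour.

## Per-sector enrichment

`enrich_sectors()` tests each (sector, term) pair with $k \ge 1$ shared
genes by the hypergeometric upper tail
$P(X \ge k),\ X \sim \mathrm{Hypergeom}(N, K, n)$, followed by
Benjamini–Hochberg correction *within* each sector, since sectors are
reported as separate functional units. The universe defaults to the full
embedded network (sectors live in the hPIN geometry, not in the
subnetwork); both raw and adjusted values are emitted, and significance is
flagged at raw $p < \alpha$ with $\alpha = 0.05$. The hypergeometric test
is discrete: for sparse overlaps the realized null rate of $p < 0.05$ sits
below 5% (conservative), approaching the nominal level only for dense
sector/term overlaps — worth remembering when comparing raw-p counts
across sectors of very different sizes.

## Seed subnetworks

`seed_neighborhood()` builds the disease PIN as the matched seeds, their
first neighbours, and *only the seed-incident edges*. The alternative —
the full induced subgraph on seeds plus neighbours — is available behind
`mode = "induced"`. We made incident-edges the default because a
seed-centred PIN with an edge/node ratio near 1.1–1.2 (as published
disease PINs of this type have) is near-tree-like, which is what the
incidence construction produces; full induction yields far denser graphs.
Coordinates of subnetwork nodes are *restricted* from the full-network
embedding, never re-computed: similarity positions are only meaningful in
the geometry of the whole interactome.

## Transcript-side computations

`fragment_sequences()` tiles long transcripts into `L = 100` nt windows
with step `s = 50` (50% overlap), anchoring the final window at `M - L` so
every fragment is full length and every base is covered. The step is
configurable because published fragment counts depend on it and on the
transcript set; we treat any specific fragment total as dataset-specific,
not an invariant. `scan_pwm()` scores single-stranded RNA in bits,
$\sum_j \log_2 \frac{(f_j(s_{o+j}) + c)/(1 + 4c)}{b}$, with uniform
background $b = 0.25$, pseudocount $c = 10^{-3}$, and reports offsets
scoring at least the PWM threshold (default 6). `N` bases contribute 0
(background). Motif *discovery* — enumerating enriched patterns against a
shuffled control — is out of scope by design; this package consumes the
resulting PWMs.

## The synthetic module: what it emulates, what it does not

The generators produce inputs with the statistical structure the analysis
assumes, with recorded ground truth:

* **PS networks** with known coordinates. Finite-temperature attachment
  samples exactly $m$ targets without replacement, weighted by the
  Fermi–Dirac probabilities at the growing radius $R_t$ — a deterministic
  edge budget of $m(N - m) + \binom{m+1}{2}$ edges that keeps tests sharp;
  the network is connected by construction.
* **Gene sets** planted on contiguous angular blocks that partition the
  circle (plus uniform random terms), emulating the angular coherence of
  functional modules.
* **Motif sequences** with i.i.d. uniform background (matching the
  scanner's default background) and one PWM-sampled word per planted
  sequence at a logged offset.
* **DE tables** from a z-model: null `log2FC ~ N(0, 1)`, planted
  `N(effect, 1)`, two-sided p from the standard normal, BH adjustment.
  Count-model internals (dispersion, library size) are intentionally not
  simulated — downstream code consumes DE *results*, so only the table's
  statistical shape matters.

Study-scale defaults, used by the bundled demo and the acceptance script:
$N = 500$, $m = 4$, $\gamma = 2.5$, $T = 0.1$ for embedding-recovery work
(a low-temperature, strongly geometric regime where recovery is
well-defined); $N = 2000$ for degree-exponent recovery; 30 gene sets with
a fifth planted; 10% planted DE genes at effect size 6; 50 transcripts of
500 nt with a width-8, 0.97-consensus planted motif. These sizes keep the
full suite in the minutes range on one CPU while leaving every recovery
test statistically comfortable.

What passing these tests does *not* show about real data: real
interactomes carry study bias and false positives that no PS network
models; real functional modules are neither disjoint nor angularly
contiguous; real DE p-values inherit count noise; and real transcript
backgrounds are not uniform. The synthetic results validate the
machinery, not the biology.

## Numerical and degenerate-input choices

* Coordinates and sector tables are serialized with 12 decimal places so
  a write/read round trip reproduces values to better than $10^{-12}$
  absolute; enrichment p-values use 12 significant digits.
* Interaction-table duplicates collapse to the maximum score *before*
  thresholding (conservative retention); self-interactions are dropped
  after.
* Degree ties in radius assignment and angular ties in sector sorting are
  broken lexicographically by node identifier — every pipeline stage is a
  pure function of its inputs, and reruns are bit-identical (asserted on
  manifest checksums).
* A gap threshold candidate of zero (tied angles) is never selected; tied
  angles always share a sector.
* Welch's unequal-variance t-test is used for two-group comparisons —
  the safer default at triplicate scale; with zero variance in both
  groups the degenerate limits ($t = 0, p = 1$ for equal means) are
  returned explicitly.
* The connection radius follows the PS closed form
  $R = 2\ln N - 2\ln\!\big(\tfrac{2T}{\sin T\pi}\cdot
  \tfrac{1 - N^{-(1-\beta)}}{m(1-\beta)}\big)$, with the $T \to 0$ and
  $\beta \to 1$ limits substituted analytically. Note $R$ *increases* with
  $m$: a larger per-node link budget requires a larger radius.

## Known limitations

* The Laplacian eigendecomposition is dense ($O(N^3)$): fine to a few
  thousand nodes, slow at full-interactome scale, where the pipeline's
  coordinates cache is the intended workflow.
* Identifier harmonization (symbol vs accession) is the caller's
  responsibility; the edge-table reader only falls back from empty symbols
  to numeric identifiers.
* Sector granularity under merge-tuning is finer than a hand-chosen single
  gap threshold; when comparing against a published sector count, pass the
  published `g` explicitly.
* The scanner has no E-value calibration and no reverse strand (RNA).
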