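# polarPIN

Hyperbolic embedding and angular-sector enrichment analysis of protein
interaction networks (PINs).

## The problem

When a disease process sequesters a set of transcripts or proteins — for
example, RNA molecules trapped in polyglutamine intranuclear inclusions —
the question is which cellular machines are perturbed downstream. One
productive way to answer it is geometric: scale-free, clustered
interactomes are well described by the popularity–similarity (PS) model,
in which every protein occupies a point $(r, \theta)$ of the hyperbolic
plane. The radius $r$ tracks popularity (hubs sit near the centre, with
$r_i = 2\beta\ln i + 2(1-\beta)\ln N$ by degree rank,
$\beta = 1/(\gamma-1)$); the angle $\theta$ tracks similarity, so proteins
serving related functions occupy nearby angles. Connections arise with
Fermi–Dirac probability

$$p(x) = \frac{1}{1 + e^{(x-R)/(2T)}}, \qquad
  x = \operatorname{arccosh}(\cosh r_p \cosh r_q -
      \sinh r_p \sinh r_q \cos\Delta\theta).$$

polarPIN infers these coordinates for a confidence-filtered interactome
(LaBNE: Laplacian-eigenmaps angles with degree-ranked radii; HM:
windowed maximum-likelihood angular refinement), builds the
seed-neighbourhood subnetwork around disease-associated gene products,
cuts the similarity circle into **sectors** wherever consecutive sorted
angles jump by more than a gap threshold $g$, and asks which gene sets are
over-represented in each sector (hypergeometric upper tail +
Benjamini–Hochberg within sector). Supporting stages cover the
transcript side (overlapping fragmentation, PWM log-odds scanning at the
conventional threshold of 6 bits) and small assay quantifications
(2^–ΔCt relative expression, reporter ratios, Welch comparisons). A
synthetic-data module generates every input with planted ground truth, so
the whole chain is testable offline.

It is aimed at computational biologists who consume standard inputs —
tab-separated confidence-scored edge tables, DE result tables, GMT gene
sets, FASTA transcripts, CIS-BP-style PWMs — and want a reproducible,
seeded, manifest-logged pipeline rather than a chain of ad-hoc scripts.

## Worked example

Embed a synthetic PS interactome, cut it into angular sectors, and test
planted functional modules:

```r
library(polarPIN)

ps  <- generate_ps_network(N = 300, m = 3, gamma = 2.5, temp = 0.1, seed = 7)
emb <- embed_labne_hm(ps$network, gamma = 2.5, temp = 0.1)
print(emb)
#> embedded_network: 300 nodes | gamma = 2.5 | T = 0.1 | R = 12.6013
#> log-likelihood trace: -17498.7 -> -5688.054

g    <- tune_gap_threshold(emb$coords, min_size = 5, policy = "merge")
part <- angular_gap_clusters(emb$coords, g = g, min_size = 5, policy = "merge")
cat("tuned g =", round(g, 4), "->", nrow(part$sectors), "sectors\n")
#> tuned g = 0.0164 -> 36 sectors
head(part$sectors, 3)
#>   sector_id size theta_start theta_end
#> 1         1    6   0.7374407 0.8256982
#> 2         2    8   0.8785451 0.9972601
#> 3         3    9   1.0289933 1.1381826

gs  <- generate_sector_gene_sets(ps$ground_truth, n_terms = 12,
                                 enriched_sector_fraction = 0.25, seed = 8)
enr <- enrich_sectors(part, gs, universe = emb$coords$node)
head(enr[enr$significant, c("sector_id", "term", "k", "K", "n", "p", "q")], 3)
#>    sector_id       term k  K n        p        q
#> 1          1 PLANTED_03 6 99 6 0.001164 0.004655
#> 5          2 PLANTED_03 8 99 8 0.000116 0.000578
#> 10         3 PLANTED_03 9 99 9 0.000036 0.000216
```

Reading the output: the likelihood trace shows the HM refinement
improving the PS-model fit of the spectral layout; the tuned gap
`g = 0.0164` rad slices the 300 inferred angles into 36 sectors of at
least 5 proteins; and the first three sectors are each dominated by the
same planted angular block (`PLANTED_03`, a 99-gene module), with sector
overlaps `k` out of sector sizes `n` whose hypergeometric p-values
survive per-sector BH correction (`q`).

The full chain — edge-table filtering, LCC extraction, embedding (or a
cached coordinates file), DE-based seed selection, seed-incident
subnetwork, sectors, enrichment, JSON manifest with checksums — runs from
one flat configuration:

```r
b <- synthetic_bundle("demo", seed = 1)   # writes all inputs + ground truth
run_pipeline(list(edges = b$files$edges, de_table = b$files$de_table,
                  gene_sets = b$files$gene_sets, out_dir = "demo/out",
                  gamma = 2.5, temp = 0.1, use_adjusted = FALSE, seed = 1))
```

or from a shell via `inst/scripts/run_pipeline.R --config FILE`.

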