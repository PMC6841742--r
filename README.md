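# comorbnet

Comorbid diseases — pairs of conditions that co-occur in patients more
often than chance predicts — may share molecular machinery even when
their genome-wide association signals barely overlap. `comorbnet`
implements a complete analysis for finding and characterizing that
shared machinery for a disease pair (the motivating case is asthma and
hypertension): it integrates six heterogeneous evidence channels into
per-disease gene sets, intersects them into an evidence-labelled
shared-gene table, detects overlapping functional modules on the
shared-gene interaction network, and tests two mechanistic hypotheses —
that the diseases share eQTL-mediated regulatory control, and that drugs
treating one disease harm the other through common targets.

The package is aimed at systems-biology analysts who have local,
ID-harmonized extracts of the usual resources (a GWAS catalog, per-study
eQTL SNP–gene tables, phenotype-ontology annotations, differential
expression reports, curated/text-mined gene lists, drug indication and
target tables, a typed gene–gene edge list, GMT gene-set collections).
No web retrieval is performed; a synthetic-data generator emulates all
of these schemas with planted structure, so the entire pipeline is
testable offline.

## The methods at its core

**Evidence integration.** Each gene–disease association carries one or
more channels from a closed vocabulary: `monogenic` (phenotype
annotations with "frequent" disease terms, plus curated lists),
`coding_gwas` (variants with transcript-affecting consequences and
p < 1e-5, strict), `eqtl` (genes regulated at FDR ≤ 0.05, inclusive, by
any of the disease's GWAS SNPs — not only coding ones), `diff_expr`
(a trusted profiling signature, or ≥ 2 distinct text-mining sources),
`text_mining` (≥ 2 supporting studies) and `drug_target` (human targets
of the disease's beneficial and harmful drug groups).

**Overlapping modules.** On the shared-gene network (co-expression,
physical and pathway edges), modules are found by a clique-seeded
agglomerative algorithm (EAGLE): maximal cliques of size ≥ 10 seed
communities, all other nodes start as singletons, and community pairs
merge greedily by the similarity

    S(C1, C2) = (1/2m) Σ_{v∈C1\C2} Σ_{w∈C2\C1} [A_vw − k_v k_w / 2m].

Every dendrogram level is scored by the extended modularity

    EQ = (1/2m) Σ_modules Σ_{v,w ∈ module} [A_vw − k_v k_w / 2m] / (O_v O_w),

where `O_v` counts a vertex's module memberships, and the maximal-EQ
cover is reported (modules under 10 genes dropped). Genes may belong to
several modules.

**Statistics.** All overrepresentation questions use the one-sided
Fisher exact test (hypergeometric upper tail) with Benjamini–Hochberg
correction per test family. The eQTL-sharing question uses a matched
permutation null: 10000 random SNP-set pairs drawn from the pooled eQTL
SNP universe with the observed sizes and intersection preserved exactly,
so the many-to-many SNP→gene fan-out that inflates sharing is respected;
the empirical p-value is `(r + 1) / (n_perm + 1)`.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
bundled synthetic conditions:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_integrate_evidence.R
Rscript analysis/03_network_modules.R
Rscript analysis/04_drug_analysis.R
Rscript analysis/05_eqtl_sharing.R
```

Output of step 2 (evidence integration on the noisy bundle):

```
asthma: 195 genes; hypertension: 195 genes; shared: 90
all 60 planted shared genes recovered: TRUE
60 of 90 shared genes are novel vs the reference resource
strongest cross-disease channel co-occurrence: text_mining (p = 2.57e-33)
```

90 genes carry evidence for both diseases: the 60 planted shared genes
plus 30 created by random background-evidence collisions — exactly the
behaviour the noisy condition is designed to show. Step 3 finds the four
planted 12-cliques (grown by a few noise-attached periphery genes, EQ =
0.663), each significantly enriched for its own planted gene-set term;
step 4 recovers the three planted cross-disease drugs (p = 0.0285) and
all six planted overrepresented targets; step 5 reports 21 shared
eQTL-regulated genes against a null mean of 6.8 (empirical p ≈ 1e-3,
the floor of the add-one estimator at 1000 permutations).

The same machinery is available programmatically:

```r
library(comorbnet)
spec <- demo_fixture_spec(noise = FALSE, seed = 1)
gen_fixture(spec, "demo")
bundle <- run_pipeline(validate_config("demo/config.yaml"))
bundle$shared          # evidence-labelled shared-gene table
bundle$cover           # overlapping module cover with EQ
bundle$permutation     # matched permutation result
```

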