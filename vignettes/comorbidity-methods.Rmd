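---
title: "Methods: shared-gene analysis for comorbid disease pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shared-gene analysis for comorbid disease pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

This vignette is the package's own account of the models and procedures
it implements, of the parameters that matter, and of the choices made
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The problem

Two diseases that co-occur in patients more often than chance — the
motivating pair is asthma and hypertension — may do so because they
share genetic architecture, because a common regulatory lesion perturbs
both, or because treating one pharmacologically worsens the other. The
package operationalizes all three hypotheses on top of one data
structure: a per-disease gene set in which every gene carries the set of
*evidence channels* supporting its association.

## Evidence channels and their filters

Six channels form a closed vocabulary. Each has a filter whose
convention matters at the boundary:

| channel       | source table              | rule (default)                                        |
|---------------|---------------------------|-------------------------------------------------------|
| `monogenic`   | phenotype annotations + curated lists | term in the include set, frequency label `"frequent"` (≥ 50% of patients); curated entries need support ≥ 1 |
| `coding_gwas` | GWAS association table    | p-value **strictly** below 1e-5 and consequence among splice-region, missense, synonymous, non-coding-transcript-exon |
| `eqtl`        | GWAS × eQTL link tables   | link FDR ≤ 0.05 (**inclusive**); any of the disease's GWAS SNPs qualifies, coding or not |
| `diff_expr`   | expression reports        | one *trusted* signature row, or reports from ≥ 2 distinct non-trusted sources |
| `text_mining` | curated list              | supported by ≥ 2 independent studies                  |
| `drug_target` | drug + target tables      | human targets of the disease's beneficial ∪ harmful drug groups |

Boundary conventions are deliberate: the GWAS threshold is strict
because catalogued associations sit *below* the suggestive cutoff,
while an eQTL link *at* FDR 0.05 has passed the threshold. Both are
config-overridable.

Two open design points were resolved as follows. Phenotype-term
exclusion (e.g. removing ocular-hypertension-like terms) is
**term-level**, not gene-level: a gene annotated to both an included and
an excluded term stays in through the included annotation, because the
excluded annotation is evidence about a different phenotype, not
counter-evidence about the gene. Related GWAS traits (blood-pressure
measures, eosinophil counts) map to their disease with full weight via
the trait map; introducing weights would propagate into every downstream
test with no principled calibration available.

Gene identifiers live in one declared namespace per run (`symbol`,
upper-cased, or `numeric`), with an optional alias table applied first.
A mix of numeric-looking and symbolic identifiers is refused rather than
merged: sources that disagree on the namespace cannot be reconciled by
guessing, and silent merging would fabricate or destroy intersections.

## Drug groups

Per disease, *beneficial* = indicated drugs; *harmful* = contraindicated
∪ adverse-inducing (pooled into one polarity; the source flag stays in
the parsed table). A drug on both sides is a paradoxical-reaction case
and is removed from the harmful group only — paradoxical reactions are
rare events, and the indication reflects the drug's dominant effect.
Raw target actions collapse to `positive` (agonist, activator, inducer,
potentiator), `negative` (antagonist, inhibitor, blocker, suppressor)
or `other` (modifier, ligand, binder, unknown); the mapping ships as a
default table, lookup is case-insensitive, and unknown actions are an
error by default (or `other` with a warning). Only targets whose
organism is human count anywhere.

## Shared genes and channel co-occurrence

The shared-gene table is the exact intersection of the two disease
sets, sorted by (evidence count descending, gene ascending) — a total
order, so output is reproducible byte for byte. The *universe* for
co-occurrence tests defaults to every gene attested in any input table
of the run (association sources, human drug targets, edge endpoints,
curated lists). This choice is always reported alongside the result,
because a co-occurrence p-value is meaningless without its background;
astronomically small p-values in this family are background-dependent,
and the universe is configurable for exactly that reason. Degenerate
2×2 tables (a zero margin) return p = 1 with an explicit flag rather
than an error, since a channel absent from one disease is a legitimate
outcome.

## Overlapping modules: clique-seeded agglomeration

Module detection follows the published clique-seeded agglomerative
scheme (EAGLE), which the package states normatively so that
implementations are comparable:

1. Enumerate maximal cliques (via igraph's Bron–Kerbosch); keep those
   with ≥ `min_clique` members as seed communities. Every node outside
   all retained cliques starts as a singleton community.
2. Repeatedly merge the community pair with maximal similarity
   $S(C_1, C_2) = \frac{1}{2m} \sum_{v \in C_1 \setminus C_2}
   \sum_{w \in C_2 \setminus C_1} \left[ A_{vw} - \frac{k_v k_w}{2m} \right]$,
   recording the dendrogram, until one community remains per connected
   component.
3. Score every dendrogram level with the extended modularity
   $EQ = \frac{1}{2m} \sum_{C} \sum_{v,w \in C}
   \frac{A_{vw} - k_v k_w / 2m}{O_v O_w}$,
   where $O_v$ is the number of communities containing $v$ (uncovered
   vertices count as singletons), and return the maximal-EQ cover.
4. Drop modules smaller than `min_complex` from the report (they remain
   in the dendrogram; their genes are listed as unassigned).

Numerical conventions: the diagonal terms $v = w$ (with $A_{vv} = 0$)
are included in EQ, which makes the all-in-one cover of a connected
graph score exactly 0 and two disjoint triangles score exactly 1/2 —
the identities the tests assert. Similarity ties break by lexicographic
comparison of the communities' sorted member lists (smaller first), and
a community fully contained in another is absorbed immediately, so the
whole procedure is deterministic with no randomness to seed. When
several levels tie on EQ within 1e-12, the earliest (least merged)
cover is kept. Cross-component merges are forbidden: their similarity
is structurally non-positive and a module spanning disconnected pieces
is meaningless. Edge weights are accepted in the input but ignored —
adjacency is binary, matching the unweighted treatment of the study
design. An empty network yields an empty cover with EQ 0.

The defaults `min_clique = min_complex = 10` are the study's operating
point; desk-scale examples in the tests use 3–5. Both are exposed in
the config.

On noisy networks the maximal-EQ cover typically grows each planted
clique by its noise-attached periphery (a degree-1 neighbour raises EQ
when absorbed); this is a property of modularity maximization, not an
implementation artifact, and it is why exact module equality is asserted
only on the noiseless fixture while planted-recovery on noisy graphs is
asserted at Jaccard ≥ 0.9.

## Statistical machinery

All overrepresentation and overlap questions reduce to the one-sided
Fisher exact test: the hypergeometric upper tail $P(X \ge a)$ with
margins fixed, evaluated in log space (`stats::phyper`), which keeps
totals up to $10^6$ exact to machine precision. The sample odds ratio
accompanies each result. Benjamini–Hochberg correction is applied
within each test family separately — per drug group, per annotation
run — never across families, matching per-analysis correction practice.

One spec-level claim about BH proved false and is recorded rather than
patched around: the step-up adjustment is **not** idempotent. Applying
it to its own output can only raise values (for already-adjusted $q$,
$q_j \cdot m / j \ge q_j$ for every $j$, so re-adjustment cannot
reproduce $q$ unless the cushion vanishes), e.g.
$(0.5, 0.51, 0.9) \mapsto (0.765, 0.765, 0.9) \mapsto (0.9, 0.9, 0.9)$.
The package implements the standard adjustment; the acceptance suite
asserts the stated idempotence anyway and that single clause fails by
design. What *is* true, and tested: agreement with the $O(m^2)$
definitional oracle to 1e-12, order preservation, $q \ge p$, $q \le 1$.

Drug-target overrepresentation counts **drugs**, not action rows: for
each gene hit by the group, the 2×2 table is (group drugs targeting it,
group drugs not, background non-group drugs targeting it, remainder),
with the background being every drug with ≥ 1 human target carrying a
defined action. A group drug outside that background is an error, not a
silent drop — it would corrupt the margins.

### The matched permutation null for eQTL sharing

The number of genes regulated by both diseases' eQTL SNPs is inflated
by the many-to-many SNP→gene fan-out (one trans hub can regulate dozens
of genes). The null therefore resamples **SNPs, not genes**: each of
`n_perm` replicates draws, uniformly without replacement from the
pooled eQTL SNP universe, a shared core of size $|A \cap B|$ and two
disjoint remainders, so every replicate satisfies $|A^*| = |A|$,
$|B^*| = |B|$, $|A^* \cap B^*| = |A \cap B|$ *exactly* — a hard
construction-level guarantee, not a statistical one, and tested as
such. The statistic is recomputed identically and the empirical p-value
uses the add-one estimator $(r + 1)/(n_\text{perm} + 1)$, which is
never zero — consistent with reporting a bound rather than an
impossible p = 0. Sampling is pooled across studies; per-study
stratification is not implemented, as the pooled universe is the
stated design.

## The synthetic-data generator

`gen_fixture()` writes every input table the pipeline consumes, with
planted structure recorded in a manifest: shared genes, per-disease
gene sets, eQTL-shared genes, network modules, drug groups, paradoxical
and cross-disease drugs, planted overrepresented targets, and a
Monte-Carlo estimate of expected eQTL sharing under independence. Two
study conditions ship as `demo_fixture_spec()`:

* **noiseless** — background channel rates and noise-edge probability
  zero; every pipeline output must equal the manifest exactly;
* **noisy (default)** — channels fire at background rates chosen to
  mirror the real evidence mix at desk scale (text mining the dominant
  channel at 0.06 per gene-disease, eQTL 0.02, differential expression
  0.03, coding GWAS 0.01, monogenic 0.005), plus inter-module noise
  edges at p = 0.02. Random collisions then create additional shared
  genes beyond the planted 60 — deliberately, since that is what real
  multi-source integration does.

Default sizes (600 genes, 500 SNPs, 60 planted shared genes, 120
disease-only genes per disease, four planted 12-cliques, drug groups of
10 with 3 cross-disease drugs and 3 planted targets per group, 150
background drugs) keep every stage exercised while the whole pipeline
runs in seconds; they are the package's chosen desk-scale study
conditions, not tuned quantities. eQTL fan-out is 1 + geometric
(mean 2), with a few high-fan-out trans hubs (mean 25 genes) in the
permutation universe — the hubs matter, because they widen the null
distribution of the sharing statistic and make empirical p-values
usefully continuous; without them the statistic's atoms are coarse
enough to distort calibration checks. `gen_null_eqtl_pair()` draws
set pairs by exactly the construction the permutation null resamples,
so p-values on those worlds must be uniform; the acceptance suite
checks this on 500 worlds with a KS test at the 0.01 level.

What the generator does **not** emulate: linkage disequilibrium, real
effect-size distributions, tissue-sharing structure across eQTL
studies, or literature-bias correlations between channels. Passing
tests therefore demonstrate correctness of the machinery on data with
the declared statistical shape, not robustness to every pathology of
the real extracts.

## Pipeline and reproducibility

`validate_config()` reads a YAML config, refuses unknown keys, fills
the documented defaults (GWAS p < 1e-5, eQTL FDR ≤ 0.05, two-source
minima, clique/complex 10, α = 0.05, 10000 permutations) and requires
a seed — silent nondeterminism is refused. `run_pipeline()` executes
ingest → drug groups → shared genes → network + modules → annotation →
drug tests → channel co-occurrence → matched permutation, logging
input/output counts per stage and flushing each stage's outputs before
the next can fail; a failing stage leaves earlier outputs on disk and a
`summary.json` marked incomplete. Outputs carry the config hash in a
comment header; logs are deliberately free of timestamps so that two
runs with the same config and seed are byte-identical, which the tests
assert file by file. An empty shared set degrades gracefully (empty
table, empty cover, warning, complete run).

The analysis scripts under `analysis/` narrate this pipeline on the
bundled conditions; `scripts/acceptance.R` recomputes the headline
quantities from scratch at the problem sizes stated above (exhaustive
2×2 tables to total 25 plus 2000 random tables, 200 BH vectors, 200
calibration worlds at 199 permutations, 20 planted-recovery graphs,
full pipeline runs on both demo bundles).

## Known limitations

* Modularity-maximizing covers absorb noise periphery (see above);
  module counts on noisy data depend on `min_clique` rather than on an
  inferential criterion.
* The agglomerative stage is quadratic in the number of seed
  communities; networks of tens of thousands of nodes would need a
  priority-queue implementation.
* The channel co-occurrence test treats genes as exchangeable within
  the universe; gene-level confounders (length, study popularity) are
  not modelled.
* Curated monogenic lists enter with minimum support 1 and are unioned
  with ontology-derived genes; conflicting namespaces across sources
  are an error by design, not resolved automatically.
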