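---
title: "Comparing enzyme complements across organisms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing enzyme complements across organisms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keggcomp)
```

## The comparison model

`keggcomp` compares a query list of Enzyme Commission (EC) numbers — the
typical output of enzyme-identification tools run on a new genome or
metagenome bin — against the KEGG pathway annotation of a reference
organism. Three questions are answered per metabolic pathway:

1. **Membership**: which query enzymes belong to the pathway, which of the
   reference organism's enzymes do, and how do the two sets partition into
   *shared*, *unique to the query* and *unique to the reference*?
2. **Representation**: is the pathway over- or under-represented in the
   query relative to the reference genome?
3. **Visualization**: a KEGG `show_pathway` URL that colors the pathway map
   by the partition (yellow shared, red query-only, green reference-only).

Enzymes belonging to no pathway at all form a fourth, separate comparison
(the *non-mapped* section): for obligate parasites and other reduced
genomes these are often the most interesting enzymes, and folding them into
pathway statistics would hide them.

### Membership: the universal-set mapping rule

A pathway has two EC sets: the *universal* set (every EC linked to the
pathway in the definitions, regardless of organism) and the reference
organism's *annotated* set (a subset in practice). A query EC counts as "in
pathway *p*" when it belongs to *p*'s universal set. This matters for the
unique-to-query column: a query enzyme the reference organism lacks can
still be placed in the pathway — which is precisely the comparative signal
(e.g. an enzyme a free-living relative carries that a parasite lost, or
vice versa). Mapping only through the reference's own annotation would
force the unique-to-query column to zero everywhere.

Matching is exact on the canonical EC string (`1.1.1.1`; trailing
unspecified fields rendered `-`, as in `1.14.13.-`). A partial EC never
matches a complete one: hierarchical expansion looks convenient but
silently inflates overlap counts with annotations of unknown resolution, so
the package refuses to guess. The canonical class range is 1–7; class 9 is
additionally accepted and reserved for synthetic identifiers (below), so
example data can never be mistaken for a real enzyme.

### Representation: the two-tailed Fisher exact test

For pathway *p* the contingency table is

|                 | in *p* | not in *p* |
|-----------------|--------|------------|
| query enzymes   | *a*    | *b*        |
| reference genes | *c*    | *d*        |

with *a* = distinct query ECs in *p*'s universal set, *a + b* = all
distinct query ECs, *c* = the reference organism's gene count for *p*, and
*c + d* = its total gene count: the background is the entire gene list of
the reference genome. The two rows are deliberately in different units.
Pathway size, as KEGG annotates it, is a gene-level quantity (several genes
may carry one EC, one gene several ECs), while the query exists only at EC
resolution; the report therefore also carries the pure EC counts per row so
users can recompute an EC-vs-EC table if they prefer a unit-consistent
background. A configuration switch (`background = "mapped-query"`)
restricts *a + b* to query ECs that map to at least one pathway, for
queries dominated by non-mapped enzymes.

The test is two-tailed because both directions are biologically meaningful
— enrichment flags capabilities concentrated in the query, depletion flags
pathway loss. The two-tailed p-value uses the minimum-likelihood ("method
of small p-values") definition: with margins fixed, sum the hypergeometric
probabilities of every table whose point probability does not exceed the
observed one. Point probabilities within a relative factor `1e-7` of the
observed probability count as ties and are included; this matches the
convention of the classic exact-test routines and makes the observed-is-mode
case come out exactly 1.

Raw p-values are adjusted with the Benjamini–Hochberg step-up FDR
correction over the *reported* pathway set (pathways with at least one
enzyme from query or reference — rows that do not exist cannot be tested),
so *m* equals the number of report rows. Bonferroni and no correction are
selectable behind the same interface; BH is the default because pathway
screens are exploratory and FDR is the error rate practitioners act on.

### Numerical choices

* The hypergeometric pmf is computed in log space by binomial-coefficient
  accumulation (`lchoose`) and exponentiated, so genome-scale margins
  (*d* ~ 10⁴–10⁵) neither overflow nor underflow; the unit test compares it
  to `dhyper` (an independent saddle-point algorithm) at `1e-12`.
* Support enumeration is exact and complete; *k* outside the support has
  probability 0 by definition, not by error.
* An all-zero table is rejected (the test is undefined); a query count
  exceeding its own margin or a pathway gene count exceeding the genome
  total are rejected as corrupt definitions rather than clamped.
* EC lists are sorted with C-locale (radix) ordering everywhere — report
  rows, serialized files, URLs — so output is byte-stable across platforms
  and locales.
* Probabilities print with 6 significant digits, switching to scientific
  notation below `1e-4`; the report parser accepts its own output exactly
  (render → parse → render is byte-identical).

## Definitions, caching, offline operation

All inputs are flat tab-delimited files in a definitions directory:
organism list (`kegg_org.txt`), pathway list with categories
(`kegg_pathways.txt`), universal EC↔pathway links (`kegg_ec.txt`) and one
`org_<code>.txt` per reference organism (genome gene total, per-pathway
gene counts, per-pathway EC sets, global EC list). Serialization is
canonical — sorted records, LF endings — so save → load is the identity
and directories diff cleanly.

The client refreshes these from a KEGG-style REST service (`list` and
`link` endpoints, plain text). Namespace prefixes (`path:`, `ec:`, the
colon-less `map` on pathway ids) are stripped per an explicit table;
unknown prefixes are an error, because KEGG has changed prefixes over time
and silently keeping them would corrupt identifiers. Updates are atomic
(staged files renamed only after every fetch succeeds), a failed update
never touches existing definitions, and requests are sequential with a
minimum inter-request delay (0.35 s by default) in deference to the
service's no-bulk-download policy. Which endpoints supply per-organism
gene counts is not part of any published contract; this package's
resolution — `list/<code>` for the gene total, `link/ec/<code>` joined
with `link/pathway/<code>` for per-pathway ECs and gene counts, a gene
with several ECs contributing each EC while counting once — is its own
declared reconstruction, as is the acceptance of an optional third
(category) column on `list/pathway`. Once a directory is populated,
nothing downstream touches the network.

## The synthetic-data generator

`fixture_spec()` + `generate_definitions()` + `generate_query()` emulate
the structure of a KEGG annotation so that the whole pipeline, including
power and calibration studies, runs offline and deterministically
(Mersenne–Twister, seed-scoped so callers' RNG state is untouched).

Defaults describe a compact microbial-scale study: 50 pathways of 6–14
enzymes drawn from a shared pool (~60% of the slot count, so pathways
overlap as real KEGG maps do), three organisms annotating each pathway
enzyme independently with probability 0.85, 10–19 genes per enzyme, 40
orphan enzymes in no pathway, and a genome total equal to the summed
enzyme genes plus a 20% non-enzymatic remainder — about 5,000 genes.
Queries draw each universal enzyme with a baseline probability (default
0.3), overridden per enriched pathway, and return truth labels so
detection studies are self-contained. Synthetic ECs occupy the reserved
class 9 (`9.x.y.z`; orphans use a disjoint subclass range), making
collisions with real enzymes impossible.

What the generator does **not** emulate: real pathway topology, the
long-tailed size distribution of KEGG maps, correlated annotation errors
between related organisms, or EC-resolution biases of upstream enzyme
callers. Passing tests on fixtures therefore demonstrate the correctness
of the arithmetic, the partitions, the statistics and the file contracts —
not that any particular biological query is well-calibrated.

## Calibration: a caveat that the simulations quantify

The package's own null simulations (see the test suite and
`scripts/acceptance.R`, which recompute them) draw queries uniformly from
the synthetic enzyme universe and measure the fraction of pathway tests
with p < 0.05. That fraction comes out slightly **above** the nominal
level (≈ 0.06 under the default study design) rather than below it, despite
the discreteness of the exact test. The reason is structural, not a bug:
the background is the whole genome, whose non-enzymatic fraction (20% in
the generator; far more in real genomes) never appears in an enzyme-only
query, so a null query's in-pathway odds exceed the gene-fraction
background odds by roughly that factor. This is a general property of
enrichment tests that contrast a restricted query universe with a
whole-genome background, and users comparing enzyme lists should read
near-threshold adjusted p-values accordingly — or switch to the
EC-vs-EC table the report's columns allow them to rebuild.

## Known limitations

* Gene-level and EC-level counts cannot be reconciled exactly (`n_ref_genes`
  vs `n_ref_ecs` measure different things); the report exposes both and
  the universal pathway enzyme count (`n_all_genes`) rather than pretending
  they balance.
* A query EC in several pathways is counted in each; column sums across
  pathways may exceed the query size by design.
* Wildcarded ECs participate only by exact canonical match.
* The map-URL dialect (named colors, `%09` separators, `ec`-namespace maps)
  follows KEGG's documented coloring syntax but is not claimed byte-exact
  against any particular tool's historical output, and the KEGG website may
  change it; the base URL is configurable.
* KEGG Orthology (KO) based mapping, KGML parsing and per-gene identifiers
  are out of scope.

## Problem sizes used by the checks

The shipped verification runs use: exhaustive Fisher-oracle agreement over
all 46,375 tables with N ≤ 30 plus 1,000 sampled tables with N ≤ 10,000;
1,000 random margin sets for pmf normalization; 1,000 random vectors
(m ≤ 500) against a quadratic step-up oracle for BH; 1,000 null queries ×
50 pathways for calibration; 200 replicates for small-pathway detection
power; 200 random definitions round-trips and 50 report round-trips. These
sizes were chosen as the smallest at which the asymptotic claims visibly
stabilize.
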