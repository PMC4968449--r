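---
title: "Methods: multi-strain variation analysis with strainvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-strain variation analysis with strainvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainvar)
```

# The analysis model

`strainvar` operates on the downstream half of a multi-strain variation
study: it consumes a joint genotype catalogue (multi-sample VCF) and
per-caller structural-variant call sets, and produces private-variant
lists, damage-scored consequence tables, merged SV clusters, candidate
gene sets and pathway enrichment results. Primary calling (alignment,
mpileup/call, VEP, SV discovery engines) is upstream and out of scope; its
outputs are consumed, not recomputed.

## Genotype classification

Every strain's call at every decomposed alternate allele is assigned one
of five classes. A call is *high quality* when the site passed its soft
filters (`FILTER` is `PASS`) and the genotype quality is at least `min_gq`
(default 20, configurable through `quality_config()`). The upstream soft
filters themselves are consumed as given: their defining thresholds live
in the calling pipeline, not here, so the package treats "passed all
filters" as an upstream contract rather than re-deriving it.

Multi-allelic rows are decomposed into one record per alternate allele. A
genotype homozygous for a *different* alternate allele of the same row is
classified `HET_HQ`-equivalent with respect to the record's allele: it is
positive evidence that a second allele segregates at the site, so it must
neither count as reference support nor be ignored. This is the
conservative choice for privacy calling — it prevents a site from being
called private to one strain while another strain carries a different
alternate allele there.

## The privacy rule

A site is private to strain $X$ under `privacy_rule(m, \ell)` when

* $X$ is the only `HOM_ALT_HQ` call at the site,
* at least $m$ of the other strains are `HOM_REF_HQ` (default 30),
* at most $\ell$ of the other strains are `LOW_QUALITY`/`MISSING`
  (default 5), and
* no other strain is `HET_HQ` (or a second `HOM_ALT_HQ`).

The two published phrasings of the rule — "at least 30 other strains
hom-ref" and "the remaining 35 strains, allowing a maximum of five
missing/low-quality" — coincide for a 36-strain panel. Both parameters
are exposed; passing `min_homref_others = NULL` derives
$m = S - 1 - \ell$ for a general panel of $S$ strains, which reconciles
the phrasings at any size. The treatment of residual high-quality
heterozygotes is not specified in the published rule text; this package
disqualifies them (they are neither confident reference evidence nor
ignorable), and that choice is pinned by tests.

Site identity is the exact tuple (chrom, pos, ref, alt); indels are
assumed upstream-normalized (left-aligned), and no fuzzy matching is
attempted. Exclusion in the subtraction pipeline (below) likewise requires
allele identity, so different alternate alleles at one position never
cross-exclude.

## Damage scoring

Grantham distances are computed from the physicochemical property values
of the cited original publication (side-chain composition, polarity,
molecular volume for the 20 standard residues), with
$\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$. The scaling
constant $\rho$ is *not* hard-coded: it is solved so that the mean over
the 190 unordered residue pairs equals exactly 100, which is the published
normalization contract, and the suite asserts both the normalization and
agreement with the published distance table within ±1 (two pairs — L/M and
I/V — differ by exactly one unit from the printed table, a rounding
artifact of the original publication). Band boundaries are inclusive on
the right: conservative ≤ 100 < moderately radical ≤ 150 < radical.

SIFT classification gives precedence to a categorical upstream call when
the annotation carries one; otherwise score ≤ 0.05 is deleterious. When a
single per-variant label is needed across transcripts
(`summarize_per_variant()`), the most damaging annotation wins (maximum
GMS; deleterious over tolerated over unscored) — the conventional
worst-case aggregation, chosen because published per-variant damage counts
do not state their aggregation rule. Both per-variant and per-transcript
tallies are available, since it is genuinely ambiguous which one a given
published count uses.

## Structural-variant post-processing

Reciprocal overlap of two intervals is
$\min(\mathrm{ov}/\mathrm{len}_A, \mathrm{ov}/\mathrm{len}_B)$. Deletions
merge by single-linkage transitive closure over the relation
"RO strictly greater than the threshold" (default 0.9): a pair at exactly
0.9 does not merge, and a boundary test pins this. Single linkage is the
natural reading of "merging" when no clustering scheme is named; its
chaining risk is capped by an optional `max_span` argument. Each cluster
reports *primary* breakpoints from a representative member — chosen by a
configurable caller priority (`breakdancer > lumpy > cnd`, ties broken
deterministically by coordinates then caller name) — and *secondary*
breakpoints, the outer bounds over members. Merging is order-invariant and
idempotent; both properties are tested against an $O(n^2)$ brute-force
closure oracle.

Reciprocal overlap is degenerate for point insertions, and no published
insertion merge criterion exists; insertions therefore cluster when
breakpoints lie within a window (default 100 bp, single linkage). This is
a declared artifact decision, exposed as `--ins-window`.

Cross-strain privacy re-applies the merge relation between one strain's
clusters and every other strain's clusters, using the clusters' secondary
(outer) bounds as the faithful extent of the collapsed call; a cluster no
other strain can merge with is private. Proximity filtering removes calls
within 500 bp of an assembly gap or 20 kb of a telomere/centromere
(separation of exactly the pad still removes, "within" read inclusively)
and calls longer than 1 Mb. Validation sensitivity counts a validated
interval as found under any 1-bp overlap by default — matching the
published wording "overlapped with" — with a reciprocal-overlap mode
available since the published procedure does not state a threshold.

## Concordance

Panel entries with missing expected genotypes are removed on load
(mirroring the published procedure). On the call side, positions that are
low-quality, missing, or absent from the catalogue are *uncallable* and
excluded from the denominator rather than counted discordant — the
published text removes missing genotypes on the panel side only, so the
call-side rule is a declared choice; `include_homref = FALSE` provides the
variant-sites-only alternative.

## Candidate discovery and ORA

The private-missense pipeline intersects a strain's private SNPs with
missense annotations and unions the annotated genes. The subtraction
pipeline starts from the target's `HOM_ALT_HQ` SNPs, removes sites where
any exclude strain is `HOM_ALT_HQ` for the same allele — a low-quality or
missing genotype in an exclude strain does **not** remove a site, because
"shared with" requires a positive call — then optionally retains only
missense + SIFT-deleterious sites. Adding an exclude strain is provably
anti-monotone, and the whole pipeline is tested against literal set
algebra on every synthetic replicate.

Pathway over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ computed through the log-space survival function, checked
against exhaustive draw enumeration for every parameter combination with
$N \le 15$ to a relative error below $10^{-10}$. Benjamini–Hochberg is the
standard step-up, hand-implemented and cross-checked. The universe
defaults to all genes annotated to at least one loaded pathway — the
behaviour of common ORA web tools, declared here because the original
analyses delegated the universe to an external service whose snapshot is
unrecoverable; an explicit universe mode is provided. Pathways with zero
candidate overlap are reported untested and kept out of the BH family;
KEGG and REACTOME enter a single BH family by default (published
enrichment tables mix the databases in one corrected list). Because the
2015-era annotation snapshots and universe are external and versioned,
exact published enrichment p-values are out of reach by design; the
procedure, not the snapshot, is what the package reproduces.

# The synthetic world

The generators state one fixed world rather than tunable fixtures:

* **Panel** (`simulate_strain_panel`): 36 strains × 10,000 sites in the
  acceptance configuration, on a 2 × 10 Mb synthetic genome. Shared
  variants attach to clades of a nested strain grouping (recursive halving
  by default), emulating blocks of shared ancestry; 20 private variants
  per strain are planted; missing/low-quality/heterozygous calls are
  injected at 2 % / 2 % / 0.5 % per call — within the range a deep-coverage
  inbred panel shows after soft filtering. Injection never touches the
  focal call of a planted private site, and when a rule is supplied the
  comparator injections at planted sites are capped so the planted verdict
  survives. Noise can still erode a *shared* site to a single confident
  carrier; such sites are genuinely private under the rule, and the truth
  sidecar records the rule-level verdict for every site so tests can
  distinguish planted from emergent privates.
* **Annotations** (`simulate_annotations`): 30 % of SNP sites missense
  (30 % of those SIFT-deleterious), 2 % stop-gained, with a fraction
  annotated on a second transcript to exercise per-transcript semantics.
* **SV call sets** (`simulate_sv_callsets`): well-separated true events,
  one jittered call per caller per carrying strain; the jitter SD must not
  exceed the truncation cap that guarantees intra-cluster RO > 0.92, and
  generation fails otherwise.
* **Pathways** (`simulate_pathway_db`): 20 pathways of 50 genes over a
  1000-gene universe; candidates of size 50 drawn with weight 20 on the
  planted pathway's genes (weight 1 is the null). At these sizes the
  planted pathway's expected overlap is ≈ 26 of 50 candidates, a
  large-effect regime in which top-ranking is essentially certain — which
  is the point: the test verifies machinery, not statistical power at the
  margin.

What a green test does *not* establish: the generators model neither
linkage disequilibrium, realistic site-frequency spectra, mutation-rate
heterogeneity, alignment artifacts near repeats, nor annotation-database
bias. They establish that the rules, filters and statistics of this
package compute exactly what their definitions say on data whose truth is
known by construction.

Determinism: every generator seeds the RNG on entry and its written
outputs are byte-identical under a fixed seed; `fanout_seed()` derives
independent sub-seeds (kept below $2^{31}$) from one global seed so
modules regenerate in isolation.

# Numerical and degenerate-input choices

* Privacy, sharing and subtraction operate on integer class codes; no
  floating point is involved, so all equalities in those layers are exact.
* `shared_fraction` with an empty denominator returns `NA` flagged
  `defined = FALSE` rather than erroring (self-comparison returns 1).
* `validation_sensitivity` with nothing comparable is flagged undefined;
  zero found is 0 %.
* Hypergeometric inputs are validated (`0 ≤ k ≤ min(n, K)`, `K, n ≤ N`);
  `k = 0` short-circuits to 1. BH rejects values outside (0, 1].
* Cluster ordering is normalized to (chrom, secondary bounds, primary
  bounds) so results are independent of input order; representative ties
  break on (priority, start, end, caller name).
* Grantham scoring of non-standard residues (X, `*`, U) yields `NA` and a
  flag, never an error, so one unscorable annotation cannot abort a run.

# Known limitations

* The soft-filter definitions of the upstream calling pipeline are not
  recomputed; `FILTER`/`GQ` are trusted as given.
* Cross-strain SV privacy compares collapsed clusters, not raw calls; a
  strain pair whose raw calls would chain through a third interval can in
  principle differ from a pooled-raw-call merge.
* The concordance module compares homozygous panel genotypes only (the
  external resource it mirrors is homozygous by design).
* Exact reproduction of published enrichment p-values would require the
  contemporaneous annotation snapshots and universe; only the procedure is
  reproducible, and the acceptance targets are therefore the two in-paper
  arithmetic quantities plus the oracle/property suite.
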