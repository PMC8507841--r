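---
title: "Profiling membrane transporter traits in metagenomic time series"
author: "TransporterTraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling membrane transporter traits in metagenomic time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TransporterTraits)
```

## The problem

Microbial uptake of dissolved organic matter and mineral nutrients happens
at the cell membrane, through transporter proteins. In a seasonal
metagenome (MG) / metatranscriptome (MT) survey of marine picoplankton,
the abundance of transporter genes per taxon and per substrate is a
trait-level readout of who is equipped to take up what, and when. Getting
from raw ORF annotations to that readout takes a chain of curation steps —
finding transporter-related protein families, merging subunit families
into whole transporters, assigning substrates and transport direction,
normalising counts, resolving taxonomy — and each step has rules that
matter for the result. This package implements that chain as tested,
reusable functions, and ships a synthetic-data generator with planted
ground truth so every stage can be validated end to end.

## The pipeline and its rules

**1. Family screen** (`screenFamilies`). PFAM/TIGRFAM/COG-style family
metadata is scanned for transporter-related text. The default terms are
`transport`, `efflux`, `uptake`, `symport`, `antiport`, matched
case-insensitively as substrings so that "transporter" and "symporter"
hit; a word-boundary mode is available for stricter screens. Both the
name and the description are searched because COG entries often put the
informative text in the name. The default term list is deliberately small
and configurable: published screens of this kind used a larger curated
pattern, so absolute candidate counts depend on the pattern and database
snapshot and are not comparable across configurations.

**2. Transport clusters** (`buildCoannotationGraph`, `pruneHubs`,
`clusterFamilies`). A functional transporter is the full set of subunits,
not one gene. Families become nodes; every unordered pair of candidate
families co-annotating the same *reviewed* cross-reference entry or the
same operon becomes an edge (an edge counts once towards a node's degree
regardless of how many records support it; provenance is kept per edge).
Generic families such as ubiquitous ATP-binding domains would glue
unrelated transporters together, so nodes with more than six distinct
neighbours are removed. Three rules here were genuinely open and are
fixed as package policy:

* *Pooled evidence*: operon and cross-reference edges enter one graph
  before pruning; they are treated as one body of clustering evidence.
* *Single-pass pruning*: hubs are judged on input degrees only. A node
  whose degree drops below the cutoff merely because another hub was
  removed is still pruned; no fixed-point iteration.
* *Singletons are clusters*: candidates with no edges become singleton
  clusters, because downstream quantification needs every family to map
  somewhere and single-family transporters are common.

Clusters are the connected components of the pruned graph, with ids
assigned by sorting on the smallest member accession so record order can
only relabel, never change, the partition. The test suite checks the
partition against an independent union-find oracle on hundreds of random
graphs.

**3. Substrate and direction annotation** (`annotateClusters`,
`classifyTransportClass`). Each cluster gets one of nine substrate
categories (amino acids/peptides + ammonium, carbohydrate, nucleoside,
anion, cation, nitrate, urea, phosphate, phosphonate) with resolution
order: curated override, then a majority vote over member TIGRFAM-role
hints (TIGRFAM takes precedence), then GO hints, else `unannotated` —
which excludes the cluster from all abundance analysis. Vote ties break
to the lexicographically smallest category and are flagged for audit;
the tie-break is an invented convention, hence the flag. Transport
direction uses ordered keyword rules — metal first (direction of metal
transporters is often ambiguous, so they stay their own class), then
toxin secretion, utility export, import — with a fall-through class
`other`. Secretion types (I/II/III/V/VI) are detected from member text
for toxin exporters; TCDB mechanism classes come from the override table
only, since they are reported classifications, not inferable from text.
Manual literature curation is represented by the machine-readable
override table so the human step is reproducible.

**4. Quantification** (`tpmNormalize`, `mapOrfsToClusters`,
`clusterAbundance`). Counts are TPM-normalised per sample:
$\mathrm{tpm}(i,s) = 10^6 \, \frac{c(i,s)/L(i)}{\sum_j c(j,s)/L(j)}$,
with $L(i)$ the ORF nucleotide length (no effective-length correction —
this is per-ORF counting on an assembly, not isoform quantification).
Columns sum to $10^6$ to within $10^{-9}$ relative tolerance and are
invariant to depth rescaling. Each ORF maps to exactly one cluster — the
hit with source priority TIGRFAM > COG > PFAM, ties lexicographic — so
no TPM mass is double counted. A transporter is *abundant* when its
share of total transporter TPM strictly exceeds 0.5 % in at least one
sample of either dataset (union over MG and MT, never the intersection);
relative denominators are per dataset.

**5. Taxonomy** (`voteContigTaxonomy`, `propagateTaxonomy`,
`aggregateByTaxon`). Contigs vote a lowest common ancestor from their
ORFs' assignments: descend rank by rank, keep a label only when
supported by a *strict* majority (fraction > 0.5 by default,
configurable) of the ORFs classified at that rank and consistent with
the path so far; an exact 50/50 split truncates the path. The voted path
overrides every ORF's own hit. Abundance aggregates into a taxon x
category x sample tensor; unclassified mass is kept in its own bucket so
the tensor always conserves total cluster abundance. Domain grouping
reports Cyanobacteria (by phylum label) separately from the remaining
Bacteria, and treats the Eukaryota domain as picoeukaryotes in this size
fraction.

The strict-majority vote has a quantifiable recovery property worth
knowing: for a 6-ORF contig whose ORF labels are independently wrong at
the order rank with probability 0.2, the true order is recovered iff at
least 4 of 6 ORFs are correct, i.e. with probability
$P(\mathrm{Bin}(6, 0.8) \ge 4) \approx 0.90$. A non-strict ($\ge 50\%$)
vote would push this to 0.98, but would also let an exactly split contig
claim a label; the package keeps the strict rule and documents the
ceiling. With clean labels the vote is exact.

**6. Seasonal ecology** (`compositionStability`, `successionSummary`,
`mgMtCorrelation`, `spearmanEnvScreen`). Per-taxon substrate composition
is summarised by its mean and per-category s.d. over samples (restricted
to samples where the taxon exceeds an abundance floor, avoiding 0/0);
the stability score is the maximum s.d. — near 0 means the repertoire
mix is constant while total abundance swings. Succession is the sequence
of per-taxon peak dates (argmax of total abundance; ties to the earlier
date). MG-MT coupling is a per-(taxon, category) correlation across the
dates sampled in both panels — Pearson by default, Spearman optional;
zero-variance series are reported missing, and with only a handful of
matched dates these coefficients are descriptive, not inferential. The
environment screen computes Spearman's rho on average-ranked data for
every (transporter, variable) pair, dropping missing values pairwise; a
pair passes at |rho| > 0.5 and p < 0.05 by default. Screening on |rho|
keeps strong negative correlations (a signed mode exists), and no
multiple-testing correction is applied by default, with a
Benjamini-Hochberg option for conservative use.

*Spearman p-values*: for n > 8 the t approximation with n - 2 degrees of
freedom is used (adequate at the ~33-sample panel size); for n <= 8 the
p-value is computed by exhaustive enumeration of all n! rank
permutations, which stays correct in the presence of ties where the
classical exact S-distribution does not apply. The tests verify the
enumeration against an independently coded oracle for all n up to 8.

## What the synthetic data emulates

`simulateReference` plants a known cluster partition: each multi-family
cluster is wired as a chain of alternating reviewed cross-reference and
operon records, sharing no record with any other cluster; hub families
are co-annotated with at least seven partners drawn across clusters so
they exceed the pruning cutoff; decoy families carry descriptions free
of screen keywords; unreviewed cross-cluster records are planted as
negative evidence. Descriptions deterministically embed a screen
keyword, the class keyword, and (for toxin exporters) a secretion-type
token, and hint tables are generated consistent with the planted
categories — so exact recovery of the partition, the hub set, the
categories and the classes is the expected outcome and is what the
tests assert.

`simulateCommunity` emulates a temperate coastal sampling design: by
default 33 MG samples spanning roughly day 60-355 and 25 monthly MT
samples with four dates shared with the MG panel. Each taxon's expected
relative abundance follows a Gaussian bump in day-of-year (the simplest
unimodal seasonal model; day-of-year is computed circularly so
multi-year panels reuse the cycle), split across substrate categories by
a fixed per-taxon profile. Reads are one multinomial draw per sample
with per-ORF probability proportional to intended TPM share times ORF
length — lengths are uniform on 300-3000 bp, so TPM differs from raw
count proportions and the length correction is genuinely exercised. MT
counts are drawn independently from the same composition, optionally
rescaled by per-taxon expression multipliers, which makes
gene-abundance/expression coupling testable under known conditions.
Environmental variables linked to a taxon track its trajectory (scaled,
signed) plus Gaussian noise; unlinked variables are pure noise.

What the generator does *not* emulate: read-level data (no FASTQ,
assembly or mapping errors), sequence content, overdispersion beyond
multinomial sampling, taxonomic mislabelling (added explicitly only in
the voting experiments), and real covariance structure among
environmental variables. Passing recovery tests therefore demonstrates
the correctness of the pipeline's logic under its stated assumptions,
not robustness to annotation error or compositional artefacts in real
surveys.

One such artefact is worth flagging: TPM is compositional, so a taxon's
apparent peak date is its peak *share*, which shifts away from its
absolute peak when competitors bloom nearby. The planted succession
*order* is recovered robustly in the simulations; planted peak *dates*
are not asserted, by design.

## Numerical and degenerate-input choices

* TPM columns of zero-depth samples stay all-zero, with a warning; the
  same applies to relative abundance in samples with no transporter
  signal.
* The abundant filter and the read-support mask (> 500 reads) use strict
  inequalities; the richness visibility quantile is the
  linear-interpolation sample quantile (R type 7) with a
  greater-or-equal comparison.
* Vote ties, category-vote ties, and peak-date ties each have one
  documented deterministic tie-break (truncate; lexicographic; earlier
  date).
* Constant series yield missing correlations rather than 0, and are
  excluded from screens.
* Cluster ids, sample ids and all generator outputs are deterministic
  given seeds; identical seeds give identical tables.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to make sampling error negligible relative to
the asserted tolerances: 50-cluster references over 10 seeds for
partition recovery; depth $10^6$ for profile recovery (multinomial s.e.
well under the 3-percentage-point bound); depth $10^5$ over 20 seeds for
succession order; 100-200 random graphs for the oracle equivalences; 400
contigs for the voting experiments; 100 seeds for the null MG-MT
correlation.

## Limitations

Absolute published counts of screened families or clusters depend on
specific database snapshots and the full curated screen pattern, and are
out of reach of (and out of scope for) a reduced default term list; the
package validates the *rules* on planted truth instead. The LCA vote is
a deliberate simplification of alignment-score-weighted voting schemes
used by assembly annotation pipelines. Manual curation enters only as an
override table; the package performs no literature mining. Plotting is
left to the caller — all profile outputs are plain matrices, arrays and
long-format tables.
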