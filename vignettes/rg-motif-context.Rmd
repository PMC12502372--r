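---
title: "Sequence-context analysis of RG motifs: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-context analysis of RG motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Arginine/glycine-rich (RG) motifs — also called RGG boxes or GAR motifs — are
low-complexity regions built from RG and RGG repeat units interspersed with
other residues. They are among the most common RNA-binding elements in human
proteins and are prominent drivers of liquid–liquid phase separation (LLPS).
Because they live inside intrinsically disordered regions (IDRs), they resist
homology- and structure-based analysis: the informative signal is
*compositional* and *contextual* — what the motif and its disordered
neighborhood are made of, and where the motif sits relative to structured
domains.

`rgcontext` implements a complete, offline pipeline for this kind of
analysis. Given a proteome (FASTA) and per-protein annotation snapshots
(disorder intervals, Pfam-style domains, GO terms, a scalar phase-separation
propensity, PTM sites), it:

1. scans sequences for RG motifs and filters them against disorder;
2. partitions each protein into four region classes (motif, motif-containing
   IDR, other IDRs, structured);
3. classifies motif proteins into a positive ("functional": predicted to
   phase separate *and* annotated as nucleic-acid binding) and a negative set
   (neither);
4. compares the two sets: per-region amino-acid enrichment, physicochemical
   block properties, IDR-constrained sliding-window composition profiles,
   motif–domain distances, aromatic motif-region subsets with GO enrichment,
   and PTM enrichment normalized by mIDR length;
5. generates synthetic proteomes with planted ground truth so every stage can
   be validated end to end.

# Coordinates and input conventions

Internally every interval is **0-based half-open**; every file read or
written uses **1-based inclusive** coordinates (the UniProt convention). The
round trip is exercised by tests. `X` residues are kept in sequences and
count toward region lengths, but are never counted as any specific amino
acid. Proteins lacking any disorder annotation are treated as fully
structured — the conservative reading of an absent disorder record. Live
database retrieval is deliberately out of scope: annotation snapshots are
read from a single TSV format, making every run reproducible offline.

# The motif model

The external motif-finder tool that popularized the GAR definition does not
publish its exact pattern, so the package states its own, fully configurable
model and records the parameters with every run:

* **Units.** A greedy left-to-right scan matches an RGG triplet first, then
  an RG duplet, else advances one residue. Matched units never overlap, and
  an RG immediately followed by G cannot occur — it would have matched RGG.
  This makes duplet and triplet counts disjoint, which is exactly the
  counting rule needed when the two are compared between sets.
* **Motifs.** A motif is a maximal chain of at least `min_units` (default 3)
  units in which the gap between consecutive units is at most `max_spacer`
  (default 4) residues. Maximal chains cannot be extended, so motifs are
  pairwise disjoint; ties cannot arise.
* **Statistics.** Per motif: RGG and RG counts, total units, and *impurity* —
  the fraction of motif residues that are neither R nor G.
* **Filters.** A motif is kept only if at least one residue overlaps a
  disorder interval; the disorder interval with maximal overlap becomes its
  mIDR (ties go to the N-terminal interval). Collagens are removed before
  analysis (description containing "collagen", or gene `COL` + digit),
  because the G-X-Y collagen repeat matches the unit/spacer model.

Both the unit scan and the chain assembly are verified against brute-force
oracles (a regex-based scanner and an exhaustive chain enumeration) on
thousands of random R/G-rich sequences.

# Segmentation

Each protein is tiled exactly by four classes: motif residues (motif class
takes precedence, and a motif that pokes out of its IDR keeps the motif class
for all its residues), remaining residues of IDRs containing at least one
motif (mIDR), residues of motif-free IDRs (oIDR), everything else
(structured). Two conventions are deliberate and recorded:

* **mIDR length includes the embedded motif residues** in the IDR-level
  statistics — the comparison of interest is between whole IDRs. The
  *composition* tables, by contrast, use the tiling classes, so mIDR
  composition excludes motif residues; mixing the motif's extreme R/G content
  into its host IDR would mask the flank signal.
* **Interval centers round toward the N-terminus** for even lengths
  (`floor((start + end - 1)/2)`), used both for relative motif position
  within the IDR and for motif–domain center-to-center distances.

# Study sets

A protein is PS if its phase-separation score is present and strictly above
the threshold (default 0.5; a score exactly at the threshold is non-PS), NAB
if it carries at least one GO term from the supplied nucleic-acid-binding
list (descendant closure is assumed already applied to the list), RG if it
has at least one filtered motif. The positive set is PS ∧ NAB ∧ RG; the
negative set is RG ∧ ¬PS ∧ ¬NAB. A missing score is treated as non-PS: this
keeps the negative set's definition ("not predicted to phase separate")
meaningful rather than silently discarding unscored proteins.

# Profiling

* **Block properties.** Four properties on the motif span and on the
  10-residue blocks immediately N- and C-terminal (emitted only when fully
  inside one disorder interval): NCPR `(#R + #K − #D − #E)/length` with
  histidine neutral; aromaticity (fraction of F/Y/W); hydropathy — mean
  Kyte–Doolittle rescaled to [0, 1] via `(KD + 4.5)/9`; and the fraction of
  disorder-promoting residues (T, A, G, R, D, H, Q, K, S, E, P). One block
  per side is computed (successive blocks along the flank are not): the block
  is meant to characterize the immediate context of the motif.
* **Sliding-window profiles.** "A window of 4 residues" is read as
  *half-width* 4: at offset *d* from the motif edge the window is the 9
  residues centered on the focal position. A window contributes only when it
  lies fully inside the sequence and fully within one disorder interval.
  Counts are pooled across all contributing windows (residue-weighted), not
  averaged per protein, and the number of contributing windows is recorded
  per offset. The all-IDR background (pooled composition over the disorder
  residues of *every* protein, not just motif proteins) provides the
  reference line.
* **Enrichment heatmap.** For each amino acid × region class: log2 fold
  change of pooled proportions with an add-one pseudocount on the raw counts
  (the pseudocount handles empty cells, on which the data are silent);
  a two-sided Mann–Whitney test on per-protein proportions (proteins with no
  counted residue in a class are excluded from that class's tests); BH
  adjustment across the 20 × 4 cells of the table — each results table is
  its own BH family.

# Statistics

The statistical layer is implemented in the package with explicit, tested
contracts:

* **Mann–Whitney U**: exact two-sided p by full enumeration of the
  permutation distribution when the combined sample size is ≤ 12 and there
  are no ties; otherwise the normal approximation with tie correction and
  continuity correction. The exact branch is verified against enumeration and
  `stats::wilcox.test` for every rank configuration up to n = m = 6. Full
  enumeration also pins down the approximation's true worst-case deviation
  from exact at n = m = 6: 0.0155, attained mid-distribution.
* **Benjamini–Hochberg**: step-up adjustment, input order preserved, verified
  against `stats::p.adjust`.
* **Effect sizes**: log2 fold change of means where both means are positive,
  else Cohen's d with pooled (n−1)-weighted standard deviation; the fallback
  is signalled, never silent.
* **Significance labels**: the conventional 0.05/0.01/0.001/0.0001 star
  scheme is the default; a `"printed"` preset with cuts 0.5/0.1/0.01/0.001
  ships as well because that scheme appears verbatim in prior descriptions of
  this analysis — it is almost certainly a misprint of the conventional one,
  so it is preserved as a named preset but not used by default. A p-value
  exactly at a cut takes the less significant label.
* **Pearson matrices** over per-motif amino-acid counts; constant columns are
  flagged rather than imputed.

GO enrichment of the aromatic subsets is a one-sided
hypergeometric/Fisher test against an explicit background (default: all
RG-motif proteins in the run) — an external enrichment service would break
offline reproducibility. PTM enrichment counts sites inside a configurable
scope — default `mIDR_inclusive` (the motif-containing IDRs together with
their motifs), with `motif_flank` (motif ± 30 residues) as the alternative —
and reports rates per 1,000 scope residues plus a Mann–Whitney test on
per-protein site counts (counts, not per-residue rates, are compared; the
rate normalization is reported alongside).

Domain context: domains-per-protein histograms count instances, with the
distinct-type count reported separately; motif–domain distances are signed
(positive = domain C-terminal of the motif) center-to-center values over all
motif × domain pairs; the per-type summary includes types with at least 10
*pairs* (pairs, not proteins). No distance clustering is performed — only
medians, quartiles and side bias are reported.

# The synthetic-data generator

The generator is first-class, tested code and the package's validation
surface. Each study protein gets: a structured N-terminal segment, one
mIDR hosting a planted motif (built from RGG/RG units with spacers drawn
from the configured laws, flanked by 30 biased residues per side plus
unbiased IDR residues), a structured segment long enough to host planted
domains, and a random number of additional oIDR/structured segments scaled
to a log-normal target protein length. Key design points:

* **Planted effects follow the directions the analysis is meant to detect**:
  the positive group has longer proteins and mIDRs, more units per motif, a
  higher RGG:RG ratio, flank enrichment of F (×3), Y (×2), N and D (×1.8),
  and higher arginine-methylation and phosphotyrosine rates (5× for
  phosphotyrosine). A *flank multiplier means the realized proportion*: the
  biased composition sets each planted residue to exactly `multiplier × base`
  and rescales the rest, so a ×3 knob is testable as a ×3 composition.
* **Planted motifs are exactly recoverable by construction.** Flank residues
  close enough to the motif to chain a spurious unit onto the planted span
  (R within `max_spacer + 3` of either edge, or a G immediately after a
  duplet-terminal motif) are substituted with chemically similar residues
  (R→K, G→S); each generated protein is then verified against the configured
  detector and re-drawn (bounded retries) if the planted span is not
  recovered exactly. Spontaneous motifs elsewhere in the protein are kept —
  they are genuine detections and are counted against precision, not recall.
* **Base compositions**: a disorder-biased vector (G, S, P, E, K, R elevated)
  for IDRs and ordinary globular frequencies for structured segments;
  both configurable.
* **The null configuration** (`sim_config_null()`) equalizes every
  group-dependent law, making the groups exchangeable — the calibration
  experiments rely on this, and the defaults there are a single shared
  parameter set, not tuned per group.
* Collagen decoys (G-X-Y repeats with RG-matching spacing, `COLnA1` gene
  names) are appended to exercise the exclusion filter.

**What the generator does not emulate** — and therefore what passing tests do
*not* show about real data: real proteome length/disorder marginals and their
correlations, GO co-annotation structure, motif impurity textures beyond the
spacer law, paralog redundancy, PTM site chemistry (sites are placed
uniformly within mIDRs, not on chemically plausible residues) and any real
predictor's biases. Recovery results certify the *pipeline's correctness*,
not biological effect sizes.

# Problem sizes and numerical choices

The default study is 200 positive + 200 negative proteins — large enough that
the planted heatmap signals reach q ≪ 0.01 while a full generate-and-analyze
cycle stays in seconds. The validation suite uses 1,000 random sequences for
the scanner oracles, 500 proteins for segmentation conservation, 200 for the
sliding-window oracle, and 20 seeds for the null calibration of the heatmap
(mean fraction of q < 0.05 cells at or below 0.05). Composition vectors must
sum to 1 within 1e−9; Pearson/Cohen equivalences are checked to 1e−12.
Everything is deterministic given a seed; pipeline reruns are byte-identical,
which the tests assert by hashing every output file.

# Known limitations

* The motif definition is this package's stated default, not a replication of
  any unpublished external pattern; results on real proteomes depend on it
  and it is recorded in every run summary.
* "Structured" means only "not annotated as disordered"; no secondary
  structure is predicted.
* GO handling is flat set membership — no ontology graph, no ancestor
  propagation (assumed pre-applied to the annotation input).
* The negative set is defined by the *absence* of predictions/annotations,
  so annotation incompleteness leaks into it by construction.
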