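# rgcontext

Sequence-context analysis of arginine/glycine-rich (RG / RGG, "GAR") motifs
in protein sequences.

RG motifs are low-complexity regions built from RG and RGG repeat units and
are among the most common RNA-binding elements in human proteins; they are
also prominent drivers of liquid–liquid phase separation (LLPS). Because they
sit inside intrinsically disordered regions (IDRs), homology and structure
prediction say little about them — the informative signal is compositional
and contextual. `rgcontext` is for computational biologists who want that
analysis as a tested, fully offline pipeline: motif discovery, disorder-aware
filtering, region segmentation, set classification and the comparative
statistics, end to end, on a FASTA plus annotation snapshots.

## What it computes

* **Motif model.** A motif is a maximal chain of ≥ `min_units` (default 3)
  units — RGG triplets matched greedily before RG duplets, so the two counts
  are disjoint — with inter-unit gaps ≤ `max_spacer` (default 4). Per motif:
  RGG/RG counts and *impurity*, the fraction of residues that are neither R
  nor G. Motifs entirely outside disorder are discarded; collagens are
  excluded.
* **Segmentation.** Each protein is tiled by four classes: motif,
  motif-containing IDR (mIDR), other IDRs (oIDR), structured.
* **Study sets.** Positive = RG motif ∧ phase-separation score > 0.5 ∧ ≥ 1
  nucleic-acid-binding GO term; negative = RG motif ∧ neither.
* **Comparisons.** Per-region amino-acid enrichment
  (log2 fold change of pooled proportions, Mann–Whitney p on per-protein
  proportions, Benjamini–Hochberg q per table), physicochemical blocks
  (NCPR, aromaticity, Kyte–Doolittle hydropathy rescaled to [0,1],
  disorder-promoting fraction), IDR-constrained sliding-window composition
  profiles with an all-IDR background, signed center-to-center motif–domain
  distances with per-type summaries, F-rich / Y-rich motif-region sets with
  hypergeometric GO enrichment, and PTM enrichment at rates per 1,000 mIDR
  residues.
* **Synthetic studies.** `generate_study()` emits FASTA + annotations +
  ground truth with planted motifs, flank composition biases, domain offsets
  and PTM rates; `truth_check()` scores recovery. This is how the package
  validates itself without any database access.

## Worked example

The numbered drivers under `analysis/` run a complete synthetic study:

```sh
Rscript analysis/01_simulate_study.R    # 200 positive + 200 negative proteins
Rscript analysis/02_run_pipeline.R      # full pipeline -> results/run/
Rscript analysis/03_truth_recovery.R    # compare against planted truth
Rscript analysis/04_null_calibration.R  # exchangeable-groups calibration
```

which prints (seed 17, fixed in the scripts):

```
Pipeline complete. Study sets: 200 positive / 200 negative proteins; 404 motifs in 400 proteins.
Phenylalanine enrichment (positive vs negative): log2FC 1.70 (motif, q=8.8e-11) / 0.95 (mIDR, q=1.7e-21)
Motif span recall 1.000, precision 0.990; set accuracy 1.000
Heatmap sign agreement for planted residues: 1.00
  domain_type planted_offset n_pairs recovered_median side_bias
1        KH_1             40     343               40 0.9912536
2    ZnF_C2H2            -90     139              -89 0.0000000
Mean fraction of heatmap cells with q < 0.05 under the null: 0.0000 (8 seeds)
```

Reading this: every planted motif span was re-detected exactly (recall 1.0;
the four extra detections behind precision 0.990 are genuine spontaneous
RG chains in random IDR sequence); the planted ×3 phenylalanine flank bias
surfaces as a strong, highly significant positive log2 fold change in the
motif and mIDR regions; domains planted 40 residues C-terminal of the motif
center are recovered at a median distance of 40 with near-total C-terminal
side bias; and with all group differences switched off, essentially no
heatmap cell reaches q < 0.05.

The same machinery works on real data: point `run_config()` at a proteome
FASTA and an annotation snapshot TSV (`accession  kind  payload` rows for
`disorder`, `domain`, `go`, `saps`, `ptm`; 1-based inclusive coordinates) and
call `run_all()`.

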