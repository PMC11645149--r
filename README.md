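# coborrow

Tumor cells in the bone marrow sit in direct contact with mesenchymal
stromal cells (MSCs) and can acquire — *borrow* — RNAs and proteins from
them through contact-dependent routes such as gap junctions and tunneling
nanotubes. `coborrow` implements the multiomic inference pipeline that
identifies such borrowed molecules from a four-arm co-culture design and
carries them through network integration, signature scoring and patient
stratification. It is written for computational biologists analyzing
tumor–stroma contact co-culture experiments (bulk RNA-seq plus
differential proteomics), and ships a synthetic-data generator with
planted ground truth so every stage can be validated end to end without
access to the original sequencing data.

## The method

The design has four arms: donor (MSC) monoculture, recipient (tumor)
monoculture, recipient contact culture (CC) and recipient
conditioned-media culture (CM). The pipeline:

1. **Differential expression.** Counts are normalized to
   log2 CPM; two-group contrasts use limma's moderated t
   (or an exactly reproducible Welch t), with Benjamini–Hochberg
   adjustment. A gene is *induced* when log2FC ≥ 2 and adjusted
   *p* < 0.05 (both configurable).
2. **Triage.** With `up_CC` the union of RNA- and protein-level
   inductions in contact culture, `up_CM` the conditioned-media
   inductions, and `MSChigh` the catalog of genes expressed highly in the
   donor but not the recipient:

   - borrowed = `up_CC ∩ MSChigh`
   - intrinsic = `up_CC \ MSChigh`
   - CM-unique = `up_CM \ up_CC`

   Genes induced in both CC and CM stay in their contact-derived bin with
   a `cm_shared` flag. The RNA∩protein cross-platform overlap defines the
   high-confidence contact signature.
3. **Network.** The signature seeds a protein–protein interaction network
   (STRING-style edge table, confidence ≥ 0.4, seeds + first neighbors);
   borrowed and intrinsic sets are projected as layers, and inter-layer
   connectivity is tested by an upper-tail hypergeometric
   *P*(X ≥ overlap) on the closed neighborhoods of the two layers within
   the network's node universe.
4. **Refinement.** Candidates are filtered by per-gene ROC AUC
   (Mann–Whitney identity, ties 0.5) between contact and monoculture
   samples, kept only when AUC > 0.85 in *every* validation dataset.
5. **Scoring and survival.** A composite signature score is the mean of
   per-gene z-scores; groups are compared by one-way ANOVA with Tukey HSD.
   Patient cohorts are stratified high vs low at a StepMiner-style
   one-step threshold (split minimizing two-segment squared error) and
   compared by Kaplan–Meier / log-rank.

## Worked example

The default synthetic fixture plants 150 transferable genes (high in the
donor, induced 2.5 log2 units in contact-cultured recipients), 80
intrinsic-response genes and 10 conditioned-media genes among 2000 genes,
with negative-binomial noise (dispersion 0.1) and 3 replicates per arm:

```r
library(coborrow)

truth <- simulation_truth()       # seed 7 defaults
expr  <- simulate_coculture(truth)
lg    <- normalize_log2cpm(expr)

mono  <- em_samples(expr, "recipient_mono")
msc   <- build_msc_high_catalog(de_test(lg, mono, em_samples(expr, "donor_mono")))
rna_cc <- filter_deg(de_test(lg, mono, em_samples(expr, "recipient_cc")))
rna_cm <- filter_deg(de_test(lg, mono, em_samples(expr, "recipient_cm")))
prot   <- filter_deg(simulate_proteome(expr, truth))

ev   <- union_evidence(rna_cc, prot)
part <- classify_induced(ev$genes, rna_cm, msc, ev$provenance)
part
#> TriagePartition: 150 donor-high / 150 borrowed / 90 intrinsic / 0 CM-unique (10 CM-shared flagged)
```

The 150 borrowed genes are exactly the planted transfer set; the 90
intrinsic genes are the 80 planted intrinsic genes plus the 10
CM-shared genes, which carry their flag. Connectivity of the two layers
in a simulated interactome, against a degree-matched rewired control:

```r
p_of <- function(wiring) {
  net <- network_from_edges(simulate_network(truth, wiring = wiring))
  net <- project_layer(net, truth$transfer_genes, "borrowed")
  net <- project_layer(net, truth$intrinsic_genes, "intrinsic")
  layer_connectivity_test(net)
}
p_of("planted")
#> Layer overlap: 251 of universe 640 (layers 419 / 342), upper-tail hypergeometric p = 4.56e-06
p_of("rewired_control")
#> Layer overlap: 247 of universe 640 (layers 454 / 341), upper-tail hypergeometric p = 0.211
```

The planted inter-layer wiring is detected (p ≪ 0.001); the
degree-matched control is not. Scoring and survival:

```r
overlap <- cross_platform_overlap(rna_cc, prot)
sc <- composite_score(lg, overlap)
anova_tukey(sc)$p
#> 2.82e-13                       # contact ≫ mono/CM composite score

ct <- simulate_cohort(truth, overlap)  # hazard ratio 2, 40% censoring
sv <- stratified_survival(ct, overlap, method = "step")
sv$logrank
#> $chi2 4.43 ; $p 0.0353         # high-score stratum does worse
```

The same analysis runs end to end from one call:
`run_pipeline(outdir = "run1")` writes DEG tables, the triage GMT/TSV,
the network exports and a `manifest.json` whose reported sizes are
asserted against the written artifacts.

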