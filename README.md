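# brainmet

Two-factor transcriptomic classification of brain-metastasizing primary
tumors, for computational oncology groups studying organotropism of
metastasis.

A primary tumor that seeds a brain metastasis must (i) cross the
blood–brain barrier and (ii) survive the brain microenvironment. `brainmet`
turns both requirements into quantitative, testable feature sets:

1. **Cell-surface physical chemistry.** For each differentially expressed
   transmembrane protein *i*, the extracellular residue composition
   **N**(*i*) (segments of ≥ 10 residues only) yields

   - *EP*(*i*) = *N*<sub>R</sub> + *N*<sub>H</sub> + *N*<sub>K</sub> (positive charges),
   - *EN*(*i*) = *N*<sub>D</sub> + *N*<sub>E</sub> (negative charges),
   - *EC*(*i*) = *EP* − *EN*,
   - *EW*(*i*) = **W** · **N**(*i*) (molecular weight, Da),
   - *EH*(*i*) = **H** · **N**(*i*) (Kyte–Doolittle hydropathy),

   aggregated per sample *s* with TPM weights *P<sub>i</sub>*(*s*):
   *S*<sub>EP</sub>(*s*) = Σ<sub>*i*</sub> *P<sub>i</sub>*(*s*) · *EP*(*i*),
   and analogously *S*<sub>EN</sub>, *S*<sub>EW</sub>, *S*<sub>EH</sub>.

2. **Enzyme expression programs.** SVM-RFE (linear-kernel recursive
   feature elimination) ranks enzyme genes by their contribution to the
   BMP/NBMP separation; the top *k* (default 20) feed a Gaussian-kernel SVM
   with balanced class weights under stratified 5-fold cross-validation,
   evaluated by pooled out-of-fold ROC/AUC. A reaction-equation parser
   checks the selected enzymes' catalyzed reactions for net H⁺ production
   (only explicit proton terms count; water and hydroxide are never
   decomposed).

A seeded negative-binomial synthetic-cohort generator reproduces the study
design (44 brain-metastasized vs 529 other-site primaries, ~100 planted
transmembrane DEGs of which 97% are down, 20 informative enzymes, a
64-gene Fenton-reaction-style set), so the whole pipeline runs and is
tested without external data. See `vignettes/brainmet-methods.Rmd` for the
full model description and design choices.

## Worked example

```r
library(brainmet)

cfg <- pipeline_config(cohort = cohort_config(seed = 7), seed = 7)
rep <- run_pipeline(cfg)

rep$summary$n_deg_tm          # planted transmembrane DEGs recovered
#> [1] 100
round(rep$summary$auc, 3)     # cross-validated AUCs, three feature sets
#> physical   enzyme combined
#>        1        1        1
print(rep$group_medians, digits = 4)
#>         group   n    S_EP    S_EN      S_EW     S_EH
#> 1         BMP  44  416554  291007 3.843e+08 -1379905
#> 2        NBMP 529 1612453 1127206 1.487e+09 -5299115
#> 21  NBMP-bone  89 1636111 1141183 1.504e+09 -5327770
#> 3  NBMP-liver 195 1614469 1128411 1.488e+09 -5304603
#> 4   NBMP-lung 245 1604386 1121072 1.479e+09 -5280225
unlist(rep$summary$reaction_counts)
#> producing consuming   neutral
#>        16         0         0
```

Reading the output: all 100 planted transmembrane genes are recovered as
DEGs; the BMP group has by far the lowest medians of the non-negative
aggregate features (its surface proteome is lighter and less charged, the
planted downregulation at work); with a strong planted signal all three
classifiers reach AUC 1 on this synthetic cohort; and every one of
the 16 curated enzymatic reactions is net proton-producing. The
Fenton-set score is higher in BMP (0.356 vs 0.250 here, *p* ≈ 4e-60),
matching the alkalosis-response interpretation.

Individual stages are exported too: `differential_expression()`,
`compute_feature_vectors()`, `aggregate_sample_features()`,
`gene_set_score()`, `svm_rfe_rank()`, `run_classifier()`,
`parse_reaction()` / `classify_h_producing()`, and plain-text readers and
writers for TSV/FASTA/GMT interchange.

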