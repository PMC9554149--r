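---
title: "Methods: two-factor classification of brain-metastasizing primary tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-factor classification of brain-metastasizing primary tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainmet)
```

## The scientific question

For a primary tumor to seed a brain metastasis, two independent hurdles must
be cleared: the metastasizing cells must cross the blood–brain barrier
(BBB), and once inside they must survive a microenvironment that is hostile
to most non-neural cells. `brainmet` operationalizes both hurdles as
transcriptome-derived feature sets and asks whether they separate
brain-metastasized primary tumors (BMP) from primaries that metastasized
elsewhere (NBMP):

1. **BBB crossing** is modeled through the physical chemistry of the cell
   surface. Molecules that cross the BBB easily tend to be small,
   lipophilic, and positively charged, so the extracellular domains of the
   transmembrane proteins a tumor expresses summarize its surface character.
2. **Survival in brain** is modeled through the expression of intracellular
   enzymes. Tumors under chronic intracellular alkalosis (proxied by a
   Fenton-reaction gene-set score) activate proton-producing metabolic
   programs; a small set of enzymes whose expression best discriminates the
   two classes is selected and inspected for net H⁺ production in the
   reactions they catalyze.

## Extracellular physicochemical features

For protein $i$ with extracellular residue-composition vector
$\mathbf{N}(i)$ (counts of the 20 standard amino acids over its qualifying
extracellular segments):

$$EP(i) = N_R + N_H + N_K, \qquad EN(i) = N_D + N_E, \qquad EC(i) = EP - EN,$$
$$EW(i) = \mathbf{W} \cdot \mathbf{N}(i), \qquad EH(i) = \mathbf{H} \cdot \mathbf{N}(i),$$

with $\mathbf{W}$ the per-residue molecular weight (Da) and $\mathbf{H}$
the per-residue hydropathy index. Conventions, each of which was a genuine
design choice:

- **Segment filter.** Extracellular segments shorter than 10 residues are
  omitted (they hug the membrane and carry little surface information). The
  filter is applied per topology segment, not to the concatenation: because
  all five features are additive over segments, pooling the surviving
  segments is the natural reading, and splitting a segment into qualifying
  halves changes nothing (a property the tests verify). The boundary is
  inclusive at 10: a 10-residue segment counts, a 9-residue one does not.
- **Charge sets.** Positive = {R, H, K}, negative = {D, E}. Histidine is
  counted as positive even though it is only partially protonated at
  physiological pH; this matches the charge bookkeeping the feature
  definitions assume and can be overridden via `aa_property_table()`.
- **Property tables.** Hydropathy defaults to Kyte–Doolittle, the standard
  "hydropathy index". Molecular weights default to the average masses of the
  free amino acids (G = 75.07 Da), with dehydrated residue masses available
  (`weights = "residue"`). Absolute $EW$ values — and any median-$EW$
  summary built from them — depend on this choice; comparisons between
  protein groups are insensitive to it.
- **Ambiguity codes** (X, U, B, Z, J, O) are excluded from every count and
  contribute 0 to $EW$/$EH$, with a warning. This is conservative: no
  assumption is made about what the ambiguous residue is.
- Coordinates are 1-based inclusive (the UniProt convention).

## Expression-weighted aggregation

Per sample $s$, with $P_i(s)$ the TPM expression of protein $i$ over an
explicit protein set (in the intended analysis, the differentially
expressed transmembrane proteins):

$$S_{EP}(s) = \sum_i P_i(s)\,EP(i)$$

and analogously $S_{EN}, S_{EW}, S_{EH}$. The weights are raw TPM — no
z-scoring or other transform — and up- and downregulated proteins are
summed together. The protein set is an argument, not recomputed inside the
function, which keeps the stage pure and testable. Both homogeneity
(scaling expression scales every feature) and additivity over disjoint
protein subsets hold exactly and are asserted against a double-loop oracle.

One consequence worth stating explicitly: extracellular loops are
predominantly hydrophilic, so per-protein $EH$ is usually negative and the
expression-weighted sum $S_{EH}$ is negative. When the positive class
downregulates these proteins, $S_{EP}$, $S_{EN}$ and $S_{EW}$ fall but
$S_{EH}$ rises toward zero (its magnitude shrinks). The group-median tests
therefore check "lowest in BMP" for the three non-negative features and
"smallest magnitude in BMP" for $S_{EH}$.

## Statistical stages

- **Differential expression.** Median-of-ratios size factors followed by a
  two-sided Welch t-test on $\log_2(\text{normalized}+1)$. This
  self-contained test is behaviorally close to a negative-binomial Wald
  test at these sample sizes; its type-I error on null simulations is
  within the tested band (0.05 ± 0.02). Fold changes use a pseudocount of
  one on the normalized class means (zero-safe, slightly shrinking).
  DEG calling is $|\log_2 FC| \ge 1$ (inclusive) and $p < 0.05$ (strict,
  raw — deliberately no FDR correction, which mirrors the thresholds the
  analysis is built around and is documented as a deviation from common
  practice).
- **Co-expression.** Pearson correlation with retention only for
  $PCC > 0.6$ and $p < 10^{-4}$, read one-sidedly: strong *negative*
  correlation does not qualify. Constant genes are skipped with a warning.
- **Gene-set score.** An ssGSEA-style rank-weighted running sum (exponent
  $\alpha = 0.25$) stands in for GSVA kernel estimation: the downstream
  claim (higher Fenton-reaction level in BMP) is directional, and any
  monotone rank score recovers it. The score is invariant under monotone
  within-sample transforms; a set covering every gene scores 0 by
  definition.
- **Enrichment.** Upper-tail hypergeometric test against user-supplied GMT
  collections, enriched at $p < 10^{-4}$.

## Classification

- Gaussian-kernel SVM, $C = 1$, kernel width by the auto-scale rule
  $\gamma = 1/(n_\text{features}\cdot\overline{\mathrm{var}})$ on
  standardized training features, class weights balanced
  ($n / (2 n_c)$) to absorb the 44-vs-529 imbalance.
- **SVM-RFE** ranks enzyme genes with a linear-kernel SVM: features are
  scored by the squared primal weight $w_j^2$, the lowest is eliminated,
  and the fit is repeated — one feature per iteration. Constant features
  are eliminated first and flagged; exact ties (duplicated columns) break
  by column order.
- **Cross-validation.** Stratified 5-fold; out-of-fold decision values are
  pooled into a single ROC curve (deterministic at small positive counts,
  unlike per-fold averaging). AUC is computed by the Mann–Whitney rank
  formula with half credit for ties, which the trapezoidal integral of the
  returned curve matches to $10^{-9}$.
- **Leakage policy.** RFE runs inside each training fold by default;
  `rfe_inside_cv = FALSE` reproduces a global pre-selection. The test suite
  includes a probe on pure-noise features showing inside-fold selection
  stays at chance while global selection inflates AUC.
- Three feature configurations are cross-validated: the four physical
  features, the expressions of the selected enzymes (default $k = 20$), and
  their combination.

## Reaction chemistry

Reaction strings are flat stoichiometric equations split on a spaced
forward arrow (`" → "` or `" -> "`); `" + "` separates terms so
species-internal plus signs (`NAD+`) survive, and integer prefixes are
coefficients (`3 S-adenosyl-L-methionine`). Net H⁺ is the product-side
minus substrate-side proton coefficient; the spellings `H+`, `H^+^` and
`H⁺` are normalized, and neither water nor hydroxide is ever decomposed
into protons — only explicit proton terms count. Bidirectional arrows are
rejected (the curated table uses only forward reactions). The package
bundles the curated table of the 16 enzymatic reactions
(`bmp_enzyme_reactions()`), all of which are net proton-producing, with
the EZH2 methyltransferase reaction producing 3 H⁺.

## The synthetic cohort generator

Real cohort data cannot ship with the package, so `generate_cohort()`
emulates the statistical structure the analysis assumes, with defaults
fixed at the study conditions:

| Parameter | Default | Rationale |
|---|---|---|
| `n_pos` / `n_neg` | 44 / 529 | the BMP/NBMP cohort sizes |
| subgroup proportions | 113:215:261 | bone/liver/lung destination counts, normalized |
| `n_tm_de`, `frac_tm_down` | 100, 0.97 | 100 DE transmembrane genes, 97 down |
| `n_enzymes` | 200 | enzyme universe, scaled down from the full human complement (~2,800) for desk-scale runs |
| `n_enzyme_signal` | 20 | planted informative enzymes, elevated in the positive class |
| `n_fr_genes`, `fr_log2fc` | 64, +0.75 | Fenton-style set size; a moderate planted elevation |
| `effect_log2fc` | 2 | planted effect for TM/enzyme genes — comfortably above the DEG calling threshold of 1, as a realistic strong signal |
| `nb_dispersion` | 0.1 | typical bulk RNA-seq overdispersion |
| library sizes | log-normal, sd 0.2 | moderate depth variation |
| gene lengths | log-normal around 1.5 kb | for the TPM-like companion matrix |

Counts are negative-binomial with log-normally drawn gene means (planted
genes are drawn from the moderately-to-highly expressed range so their
empirical fold change tracks the planted effect rather than shot noise);
the TPM-like matrix length-normalizes counts and fixes every column sum at
$10^6$. At these sample sizes an individual planted gene's empirical
log2 fold change has a standard deviation near 0.075, so while the
planted-set median sits tight on the configured effect, the worst of 100
genes can stray beyond ±0.25 — the generator tests assert the set-level
property.

The generator does **not** emulate tumor purity, batch effects,
gene–gene correlation beyond the planted structure, subgroup-specific
signal, or survival follow-up. Passing tests therefore demonstrate that
the pipeline recovers signal of the planted form under realistic
overdispersion and imbalance — they say nothing about classification
performance on real patient cohorts, which depends on cohort composition
and annotation quality the simulation does not model.

## Validation problem sizes

The validation suite runs the full default cohort (2,000 genes × 573
samples) across five seeds for the classifier and calibration checks,
1,000 randomized protein records against a character-tally oracle for the
feature engine, and 200-feature noise matrices for the leakage probe.
These sizes were chosen to exercise the study-scale class imbalance while
keeping a complete run in the minutes range on a single core.

## Known limitations

- The Welch-t DE stage is a deliberate stand-in for a negative-binomial
  Wald test; at very small per-class counts (< ~10) its calibration
  degrades and an external NB implementation should be preferred.
- $EW$/$EH$ absolute values depend on the property-table choice; only
  comparisons are portable.
- The reaction parser handles flat stoichiometry only — no formula
  balancing, charge accounting, or pH-dependent protonation states.
- The package's empirical claims are the property-based ones its tests
  compute on synthetic cohorts; real-cohort performance must be measured
  on real data.
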