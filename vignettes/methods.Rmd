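---
title: "Sequence determinants of protein abundance and expression noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence determinants of protein abundance and expression noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seq2abundance)
```

## The scientific question

Steady-state protein abundance in a bacterium is set jointly by the
transcript level and by mRNA-encoded signals controlling translation
initiation (the Shine-Dalgarno interaction with the 3' tail of 16S rRNA,
start-codon identity, RNA structure around the start) and elongation
(codon and amino-acid usage, codon adaptation, protein length).
`seq2abundance` implements a pipeline that quantifies these determinants:
it extracts a translation initiation region (TIR) and coding sequence
(CDS) per gene, computes a catalogue of 107 sequence features, fits a
partial least squares (PLS) regression of log protein abundance on the
features plus the log mRNA level, prunes the 108 predictors by backward
elimination, decomposes each gene's prediction into mRNA/TIR/CDS group
contributions, and relates those contributions to cell-to-cell expression
noise.

## Region conventions

The TIR is the 55-nt window from position $-25$ to $+30$ around the
start codon, where $+1$ is the first base of the start codon and there is
no position 0. The CDS runs from start to stop codon inclusive. External
coordinates are 1-based inclusive (GenBank/GFF3 dialect); the minus
strand is read on the reverse complement; on circular contigs the
upstream window wraps across the origin. Whether the downstream limit
counts from the first base of the start codon is genuinely ambiguous in
the field's usage; the package fixes $+1..+30$ (so the window always
contains the start codon) and exposes `tir_upstream`/`tir_downstream` for
other conventions. Genes whose TIR cannot be extracted are skipped with a
warning rather than padded: padding would fabricate sequence for exactly
the features (SD scan, folding) that are most sensitive to it.

Gene filters: a gene is aberrant if its CDS length is not a multiple of 3
(frameshift), its start codon is outside `{ATG, GTG, TTG}` (configurable;
the canonical bacterial initiators), or an in-frame stop precedes the
terminal codon. Expression outliers are flagged by regressing
z(log10 protein) on z(log10 mRNA) and removing genes whose absolute
residual exceeds 3 residual standard deviations; log10 space is used
because abundances span orders of magnitude.

## The feature catalogue (107 features)

Sixteen TIR features: PWM score, position and spacing of the best
Shine-Dalgarno match (and the deviation of that spacing from the 7-nt
optimum), the count of above-threshold motif hits, four descriptors of
the minimum-energy hybrid between the TIR and the anti-SD probe
(5'-GAUCACCUCCUUA-3', the 13 3'-terminal nucleotides of *E. coli* 16S
rRNA; configurable), the TIR folding energy, accessibility of the
$-4..+16$ window and unpaired-base count, three start-codon indicators,
and a pass-through column for an external initiation-rate score (0 unless
supplied — the package does not reimplement external initiation-rate
calculators). Ninety-one CDS features: 61 sense-codon frequencies, 20
amino-acid frequencies, CAI, tAI, AT/A/GC/GC3 content, protein length
and three stop-codon indicators. With the log10 mRNA level the design
table has 108 predictors. Sentinel hybridization values (no stable
duplex) are imputed with the column median, which keeps the design
complete without inventing energies.

Note that the catalogue contains exact linear dependencies by
construction — each amino-acid frequency is the sum of its synonymous
codon frequencies, the hybrid's total energy is the sum of its duplex and
exterior terms plus a constant, and CAI is close to a linear functional
of the codon frequencies. This redundancy is intentional (it mirrors how
such catalogues are built in practice) and is the reason the feature
selection step, not the fit itself, decides which representative of a
collinear block survives.

## The RNA energy model

Folding and hybridization use a simplified nearest-neighbor model:
stacking energies over adjacent pairs (Watson-Crick and GU), a
hairpin-loop penalty by loop length, dangling-end terms, a duplex
initiation constant and per-loop penalties in duplexes. Parameters live
in `inst/extdata/energy_model_default.tsv`; an expert can substitute
published parameter sets file-for-file. The minimum-free-energy structure
is computed by dynamic programming over all nested structures
(`min_hairpin = 3`, lonely pairs allowed, no multiloop or interior-loop
penalties); the empty structure is always admissible, so folding energies
are never positive. The bimolecular step finds the minimum-total-energy
antiparallel duplex (bulges/internal loops up to 4 nt per strand) with no
intramolecular pairs; its "exterior loop" energy is defined as the sum of
the dangling-end contributions of the unpaired bases flanking the helix
on both molecules. This definition is an explicit, documented stand-in
for the more elaborate exterior-loop decompositions of full secondary
structure packages; both operations are verified against exhaustive
enumeration under the same tables, so correctness claims are relative to
the model's own definition, not to any external parameterization.

## Codon indices

CAI weights are relative adaptiveness values: within each synonymous
family, codon count over the family maximum (zero counts floored at
0.01); the default table is the classical *E. coli*
highly-expressed-gene set shipped with `seqinr`. CAI is the geometric
mean over the CDS's codons excluding the stop and the single-codon
families (ATG, TGG). tAI weights derive from tRNA gene copy numbers with
the standard wobble penalties (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68),
normalized to a maximum of 1; the bundled copy-number table is an
*E. coli* K-12 consensus. The tAI is the geometric mean over all sense
codons. Specialized decoding (lysidine-modified CAT reading ATA) is not
modeled; affected codons simply fall to the 0.01 floor in the default
table.

## Regression and selection

All predictors and the response are z-scored with the population-sd
convention (divide by $n$); in cross-validation, standardization
parameters always come from the training fold only, so held-out rows
cannot leak into the transform. PLS components are extracted by NIPALS
(single response), and the coefficient vector for every nested component
count is kept so one 10-fold CV pass scores all component counts at once.
The component count is the smallest one whose pooled CV $R^2$ is within
0.002 of the maximum over $1..15$ — parsimony at statistically
indistinguishable accuracy — and is re-chosen after every removal.
Coefficient uncertainty is the delete-a-group jackknife over the CV
folds: $se_j = \sqrt{\frac{k-1}{k}\sum_i (\beta_{ij}-\bar\beta_j)^2}$.

Backward elimination proposes the predictor with the smallest jackknife
$t$-like ratio $|\beta|/se$ (ties: smaller $|\beta|$, then name), accepts
the removal if the CV $R^2$ does not drop by more than `tol = 0.002`,
and otherwise sets the predictor aside for the rest of the pass; it stops
when no predictor can be removed. One predictor is removed per accepted
step for auditability, the fold assignment is fixed by a single seed for
the whole run, and constant columns are removed up front. The mRNA level
is not protected by default, but a `protected` set is supported.

## Contribution decomposition and noise

For a fitted model, the contribution of group $g$ to gene $i$ is
$\sum_{j\in g}\beta_j x^z_{ij}$; contributions plus the intercept equal
the prediction exactly. Variance attribution uses the normalized
covariance decomposition $raw_g = \sum_{j\in g}\beta_j r(x^z_j, y^z)$,
rescaled so the group shares sum exactly to the model $R^2$; under
mutually orthogonal predictors each predictor's raw term reduces to its
squared correlation. This estimator was chosen over sequential-$R^2$
attribution because it is order-invariant within groups; negative raw
terms (suppressor configurations) are flagged in the output rather than
silently clipped. Transcription is the mRNA contribution; translation
efficiency is TIR + CDS.

Noise: CoV is $\sqrt{\sigma^2}/\mu$; the noise differential subtracts the
median CoV of the 51 genes centered at the gene's abundance rank
(truncated at the edges; the window is configurable because the running
median's neighborhood size is a free parameter of this estimator family).
Group comparisons use the Mann-Whitney test with midranks, tie-corrected
normal approximation with continuity correction, and exact enumeration at
pooled sizes up to 12. Partial correlations use the first-order formula
(on midranks for Spearman), returning 0 by convention when the controlled
variable is collinear with an argument, with $t$-based p-values on
$n-3$ degrees of freedom; multiple testing is controlled by
Benjamini-Hochberg.

## The synthetic-data generator

The generator exists so every stage is testable without downloads, and
its defaults are the package's study conditions. Per gene it draws a
latent expression level $e\sim N(0,1)$; amino acids from per-gene tilted
propensities (log-normal tilt, sd 0.35); codons from a mixture
$(1-m)\,\text{uniform} + m\,\text{preferred}$ whose strength
$m = \text{logistic}(e + 0.8u_g + 1.0v_{gf})$ has a shared latent part
(so CAI tracks $e$), a gene part $u_g$ and a per-family part $v_{gf}$ —
codon usage covaries with expression but is not a deterministic function
of amino-acid composition, which keeps individual codon and amino-acid
features statistically distinguishable. TIRs carry an SD hexamer sampled
from the PWM at a 4-12 nt spacing in AT-rich flanks. Genes are laid on
one contig, both strands, with intergenic spacers, and always pass the
aberrant-gene screen. The mRNA level is log-normal and correlated with
$e$ (log10 slope 0.45, noise 0.35).

Protein abundance realizes the regression model literally:
$z(\log_{10} PA) = \sum_i \beta_i x^z_i + \varepsilon$ with
$\varepsilon \sim N(0, 0.55)$, applied to the *realized, z-scored
features of the generated sequences* — so sequence feature extraction is
on the tested path — and mapped to molecules/cell as
$10^{1.7 + 0.8z}$, spanning roughly 1 to $10^4$.

Two shipped ground-truth configurations serve different analyses. The
*recovery* configuration (`default_true_beta()`) has 16 actives: mRNA
0.55, CAI 0.25, the 16S:SD exterior-loop energy 0.12, and 13 codon/amino
acid effects at $|\beta| = 0.12\!-\!0.15$. The set is chosen for
identifiability given the catalogue's exact collinearity: at most one
active codon per synonymous family, and amino-acid actives only from 4-
and 6-codon families without an active codon — an active with an exact
or near-exact alias among the nulls (e.g. an amino acid of a two-codon
family, whose frequency is the exact sum of its two codon columns) can be
replaced by its alias during elimination at zero cost, making "named"
recovery meaningless; effect sizes sit above the detectability floor
implied by the elimination tolerance
($\beta^2(1-R^2_{proxy})/\mathrm{var}(y) > 0.002$). The *dominant-mRNA*
configuration (`dominant_mrna_beta()`: mRNA 0.7, all other actives at
$\pm 0.1$) reproduces the transcript-dominated regime of real expression
data, in which the mRNA group carries the largest variance share; it is
the configuration used for the expression-profile and noise analyses.

Single-cell noise follows $CoV = \sqrt{a/\mu + c_0} + \delta_g$ with
$a = 1$, $c_0 = 0.1$. In the bundle, every gene carries a small
symmetric offset $\delta_g \sim N(0, 0.05)$ — real CoV scatters around
the scaling law everywhere, and a strictly deterministic law would let
running-median edge artifacts at the steep low-abundance end dominate
the noise-differential tails — and the planted noisy subgroup receives
an additional $+0.3$. Planted genes are those with the highest
translation-signal minus mRNA-signal score, emulating the observed
association of excess noise with weak transcription and efficient
translation; for the dominant-mRNA noise analysis the planted fraction
is 0.25, aligned with the quartile split, so the group comparison
contrasts planted against unplanted genes.

What the generator does *not* emulate: operon structure, 5' ramp and
codon-pair effects, mRNA half-life variation, protein degradation,
measurement error models of fluorescence microscopy, and small-RNA
regulation. Passing the recovery tests therefore demonstrates that the
pipeline's statistics do what they claim on data with the assumed
structure — not that the biological conclusions transfer to any real
data set.

## Numerical choices and degenerate inputs

Population-sd z-scores throughout; PLS component extraction stops when
the residual covariance norm falls below $10^{-12}$ (a response
orthogonal to X yields the zero model); constant columns are an error in
`standardize()` but are tolerated (centered, unscaled) inside CV folds
and removed up front by the selection loop; degenerate partial
correlations return 0; the no-duplex hybrid is a sentinel imputed at the
column median; quantile splits use linear interpolation (type 7) with
boundary ties assigned to the middle group; all stochastic steps flow
from explicit integer seeds and the default fold seed is 20140206.

## Problem sizes used by the test suite

Unit tests run on bundles of 12-200 genes; the recovery and qualitative
acceptance checks use the study-scale conditions (800 genes, five seeds;
1000 genes for the noise plant-and-recover), and the folding/duplex
oracles enumerate structures exhaustively at sequence lengths up to 12,
where enumeration is exact and fast.

## Known limitations

The energy model is deliberately simplified (no multiloop/interior
penalties, no temperature dependence, no partition function); tAI ignores
specialized decoding; the GenBank parser covers single-span CDS features
with simple or complement locations only (join/compound locations are
out of scope — use FASTA+GFF3 for such genomes); the backward elimination
explores one greedy path, and within exactly collinear blocks the
surviving representative is decided by the jackknife ordering, not by
biology.
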