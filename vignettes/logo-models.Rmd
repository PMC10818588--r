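---
title: "Logo models: quantified sequence logos for peptide binding prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logo models: quantified sequence logos for peptide binding prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peplogo)
```

## The model

HLA class II proteins bind peptides through a groove that accommodates a
nine-residue core. A logo model condenses a set of aligned binding cores
into a 20 × 9 quantitative matrix (QM): with $X_{i,p}$ the occurrence
frequency of residue $i$ at core position $p$,

$$X^{norm}_{i,p} = \frac{X_{i,p} - \bar{X}_p}{X_{max} - X_{min}},$$

where $\bar{X}_p$ is the mean frequency at position $p$ (exactly $1/20$
when every peptide contributes one residue per position) and $X_{max}$,
$X_{min}$ are the extreme frequencies. Entries lie in $[-1, 1]$ and each
column sums to zero; positive cells are preferred residues, negative cells
non-preferred — the numerical counterpart of a sequence logo's letter
stack.

Classification uses a *pair* of models. A peptide's binding score $BS$ is
the sum of the binder-QM cells selected by its residues; its non-binding
score $NBS$ is the same sum over a QM trained on non-binders. The peptide
is a binder iff $BS > NBS$; a tie is a non-binder. There is no score
ranking and no tunable threshold — the decision boundary is supplied by the
negative model.

### The denominator: global, not per-position

The normalization's natural reading takes $X_{max}$ and $X_{min}$ at the
same position as $X_{i,p}$. The packaged reference matrices are, however,
only reproduced when the extremes are taken over the *whole* matrix:
per-position scaling gives, e.g., 0.750 for Val at p1 of the DQ2.5 binder
model where the published value is 0.391 = (25/125 − 1/20)/(48/125 − 0).
The package therefore implements the global convention throughout
(`normalize_counts()`), with $\bar{X}_p$ still per-position. Under the
global convention with a zero minimum frequency the encoding is invertible,
which is what `decode_counts()` exploits (below).

### Assumptions

- Training peptides are pre-aligned, equal-length cores over the 20
  standard residues; duplicates count with multiplicity (frequencies are
  occurrence frequencies). Non-standard residues (X/B/Z/U, gaps) are
  rejected with an error rather than skipped or imputed, since the model
  defines no value for them.
- No pseudocounts, background-composition correction, or
  information-content weighting: the method is raw frequency normalization,
  and zero-count cells all share the matrix minimum value.
- A matrix in which every frequency is equal has an undefined model
  (zero denominator); `normalize_counts()` raises an error rather than
  returning zeros.

## The combinatorial non-binder pool

No experimentally validated non-binder sets exist for these proteins, so
negatives are constructed: for each core position, a set of experimentally
disfavored ("non-preferred") residues is known, and any peptide drawing a
non-preferred residue at *every* position is taken to be a non-binder. The
pool is the Cartesian product of the nine sets:

```{r pools}
dq81 <- load_packaged_allele("HLA-DQ8.1")
pool_size(dq81$motif)          # 10*4*9*11*3*10*7*3*11

dq25 <- load_packaged_allele("HLA-DQ2.5")
pool_size(dq25$motif)
```

`sample_pool()` draws uniformly from the pool without materializing ~10⁷
sequences: positions are sampled independently and uniformly within their
sets, and duplicates or excluded sequences are rejected against a hash set.
Rejection is cheap because every intended draw (≤ 4339) is at least three
orders of magnitude smaller than the pool. Seeds are mandatory: the
reference publication's own draws are irreproducible (no seed or scheme was
stated), so this implementation insists that yours are not.
`split_train_test_negatives()` performs the published protocol — a negative
training draw, then a disjoint negative test draw excluding it — inside a
single seeded stream.

### The DQ2.5 pool-size inconsistency

The source publication states a DQ2.5 pool of 24,710,400 nonamers, but the
product of its printed set sizes (9·2·6·13·4·10·10·5·8) is 22,464,000. The
ratio is exactly 11/10, pointing at one residue missing from one printed
10-residue list. The package's own decoder locates it: the DQ2.5
*non-binder* matrix decodes Arg at p7 to 18 occurrences, although Arg is
absent from the printed p7 set — an 11-residue p7 set containing Arg
reconciles both the pool size and the matrix. Following the principle of
packaging printed data verbatim, the motif ships with the 10-residue list;
`pool_size()` reports 22,464,000, and `verify_packaged()` flags the Arg/p7
cell as the one (known, documented) motif-consistency violation rather than
silently editing the published lists. HLA-DQ8.1 is fully consistent:
printed pool size, set-size product (27,442,800) and matrix all agree.

## Decoding printed matrices

Published QMs carry three decimals. Because every packaged matrix has at
least one never-observed residue–position cell, the global minimum
frequency is 0 and each printed value is $(c - N/20)/R$ for an integer
count $c$ and the global maximum count $R$. `decode_counts()` searches $R$
in a ±3 window around $r_0 = \mathrm{round}((N/20)/(-\min))$, accepting
candidates whose rounded counts are non-negative with every column summing
to $N$, and keeps the candidate with the smallest rounding residual. The
assumption (global minimum count 0) is a documented limitation: a matrix
from a training set dense enough to populate every cell would not decode.

```{r decode}
cnt <- decode_counts(dq25$pair$binder, 125)
attr(cnt, "scale_R")           # the global maximum count
cnt["Val", "p1"]               # 25 of 125 training cores carry Val at p1
```

The decode → re-normalize roundtrip reproduces all four packaged matrices
cell-for-cell at three decimals, and runs at load time as an integrity
check (`load_packaged_allele(verify = TRUE)`), alongside an md5 manifest
guarding against transcription drift. Comparisons against printed values
round half-away-from-zero with a ±0.001 allowance for half-even ambiguity
in the published rounding.

## Scoring choices

- **Variable-length peptides.** The published validation scored binders "of
  varying lengths" without stating the rule. The package scans every 9-mer
  window and reports the one maximizing $BS - NBS$ (ties to the smallest
  offset) — the standard core-scanning convention for class II 9-mer cores;
  a peptide is a binder if any register of it would be.
- **Ties.** $BS = NBS$ classifies as non-binder, per the method's
  "otherwise" rule.
- **Confidence ratios.** $BS/NBS$ for true binders, $NBS/BS$ for true
  non-binders, winner-over-loser when the truth is unknown. Ratios strictly
  between −1 and +1 are binned `uncertain` (boundary values included in
  `uncertain`, since confident predictions are strictly below −1 or above
  +1); a denominator within $10^{-12}$ of zero makes the ratio `undefined`
  rather than ±∞, avoiding an arbitrary sign at zero.

```{r score}
score_peptides(c(gliadin = "LQLQPFPQPELPYPQPQ"), dq25$pair, label = "unknown")
```

## What the synthetic generator does and does not emulate

`generate_fixture_peptides()` draws each position independently from a
stated per-position distribution — precisely the generative model a
sequence logo depicts. It reproduces positional composition (the tests
verify recovery of the generating frequencies within binomial error at
n = 10,000) but none of the between-position correlation real binding
cores may carry, and no relationship between a peptide and any flanking
sequence. A green test on fixtures therefore establishes the pipeline's
arithmetic (counting, normalization, scoring), not biological validity of
any particular model.

Defaults mirror the published datasets where they exist: training sets of
125 (DQ2.5) and 463 (DQ8.1) nonamers, negative test draws of 4249 and 4339
with the training draw excluded. Where the publication states nothing (the
generating frequencies of synthetic fixtures), tests use either degenerate
distributions with known closed-form results or seeded uniform/random
tables — chosen once, not tuned.

## What the validation does and does not reproduce

Specificity of both packaged model pairs is reproduced exactly: 100% of
seeded negative test draws (4249 and 4339 peptides) are classified
non-binders, matching the published 100%/100%. The published sensitivity
(90%/98%) and accuracy (95%/99%) depend on external LC-MS-derived binder
test sets that are not printed in the source and are therefore out of
numeric scope; in their place the test suite carries property-based checks
(brute-force oracle equivalence of normalization and scoring at $10^{-12}$,
column-sum conservation over 1,000 random count matrices, exhaustive
enumeration equality for small pools, parameter recovery from synthetic
fixtures, and swap-antisymmetry of $BS/NBS$ under matrix exchange).

## Known limitations

- The BS > NBS rule is calibrated by the negative model; with a different
  negative-set construction the operating point moves, and nothing in the
  score is an affinity (no IC50, no percentile rank).
- Deamidation of gluten peptides (Gln→Glu conversion by tissue
  transglutaminase, which strongly affects DQ2.5/DQ8.1 binding) is not
  modeled; queries should be supplied in the relevant modified form.
- `decode_counts()` requires a zero global minimum count, and the motif
  consistency check can only flag — not repair — discrepancies in published
  per-position sets.
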