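# peplogo

Logo models for peptide–protein binding prediction, applied to the two HLA
class II proteins that drive celiac disease, HLA-DQ2.5 and HLA-DQ8.1. These
proteins present gluten-derived peptides to T cells through a nine-residue
binding core; screening novel food proteins for predicted DQ2.5/DQ8.1
binders is part of regulatory safety assessment, which is the use case the
packaged models target. The method itself is generic: any set of
equal-length peptides that bind (or fail to bind) a protein can be turned
into a model.

## The method

A **logo model** is a quantitative matrix (QM) over the 20 amino acids and
the L = 9 core positions. Writing X<sub>i,p</sub> for the frequency of
residue *i* at position *p* in the training peptides, each cell is the
normalized frequency

&nbsp;&nbsp;&nbsp;&nbsp;X<sup>norm</sup><sub>i,p</sub> =
(X<sub>i,p</sub> − X̄<sub>p</sub>) / (X<sub>max</sub> − X<sub>min</sub>)

with X̄<sub>p</sub> the mean frequency at position *p* (1/20) and
X<sub>max</sub>, X<sub>min</sub> the extreme frequencies over the whole
matrix. Entries lie in [−1, 1]: positive cells mark preferred residues,
negative cells non-preferred ones — a sequence logo in numbers.

Two models are paired: one trained on binders, one on **combinatorially
generated non-binders**. Because no validated non-binder sets exist for
these proteins, the negative peptides are drawn from the Cartesian product
of per-position *non-preferred* residue sets (a pool of ~2.2×10⁷ nonamers
for DQ2.5, 27,442,800 for DQ8.1): a peptide carrying a disfavored residue at
every position cannot bind.

A query peptide gets a binding score BS (sum of binder-QM cells for its
residues) and a non-binding score NBS (same over the non-binder QM); it is
classified as a binder iff BS > NBS — no rank normalization, no threshold to
tune. Peptides longer than 9 residues are scanned over all 9-mer windows and
the window maximizing BS − NBS is reported. The ratio of the winning to the
losing score flags confidence: predictions with a ratio strictly between −1
and +1 are `uncertain` (that is where misclassifications concentrate);
ratios below −1 or above +1 are confident.

## Worked example

```r
library(peplogo)

dq25 <- load_packaged_allele("HLA-DQ2.5")
#> <peplogo_allele> HLA-DQ2.5: 125 binder / 125 non-binder training nonamers,
#> pool size 22,464,000

# score a 17-mer gliadin fragment: all nine 9-mer windows are scanned
score_peptides(c(gliadin = "LQLQPFPQPELPYPQPQ"), dq25$pair, label = "unknown")
#>        id           peptide offset      core    bs    nbs predicted      ratio       bin
#> 1 gliadin LQLQPFPQPELPYPQPQ      4 PFPQPELPY 0.538 -0.581    binder -0.9259897 uncertain

# evaluate against 1000 seeded draws from the combinatorial non-binder pool
neg <- sample_pool(dq25$motif, n = 1000, seed = 42)
ev  <- evaluate_model(dq25$pair, positives = "PQPELPYPQ", negatives = neg)
glance(ev)
#>   allele        n    tp    fp    tn    fn sensitivity specificity accuracy
#> 1 HLA-DQ2.5  1001     1     0  1000     0           1           1        1
```

The fragment is called a binder through its best core `PFPQPELPY` (offset 4,
0-based), but the BS/NBS ratio of −0.93 falls in the `uncertain` band, so
the call warrants experimental follow-up. The deamidated core `PQPELPYPQ`
scores BS = 0.807 vs NBS = −0.035 (ratio ≈ −23): a confident binder call.
All 1000 pool draws are correctly rejected — specificity 1.0, matching the
published validation.

Other entry points: `build_logo_model()` trains a QM from your own peptide
set; `decode_counts()` recovers the integer training counts behind a printed
matrix (an integrity check shipped for all four packaged matrices —
`verify_packaged("HLA-DQ2.5")`); `autoplot()` draws QM heatmaps and
confidence-bin breakdowns; `read_peptides()`/`write_peptides()` handle FASTA
and line-per-peptide files. A command-line wrapper with `build`, `poolsize`,
`sample-pool`, `score`, `evaluate`, `decode` and `verify-packaged`
subcommands is installed at
`system.file("cli", "peplogo.R", package = "peplogo")`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference quantities from
scratch against the installed package: the DQ8.1 combinatorial pool size;
the specificity of both packaged model pairs on seeded, training-excluded
negative test draws of the published sizes (4249 and 4339); and the
decode-and-rebuild roundtrip values of the packaged matrices (matrix maxima
and the Leu/p2 cell of the DQ2.5 non-binder model). Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

- The published DQ2.5 non-preferred list gives a product of 22,464,000,
  not the published pool size 24,710,400; the decoded non-binder matrix
  shows the resolution (an 11th p7 residue, Arg). See the methods vignette
  (`vignettes/logo-models.Rmd`) — the package keeps the published lists
  verbatim and reports the inconsistency rather than silently fixing it.
- Sensitivity/accuracy of the published external validation cannot be
  reproduced here: the positive test sets come from LC-MS elution data not
  printed in the source. Specificity can be, and is, reproduced exactly.
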