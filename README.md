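# sigoverlap

Rank-based gene-signature overlap statistics with signed similarity
indices, for asking how strongly the expression changes in a
differential-expression dataset resemble a reference expression signature
— and in which direction.

The motivating use case is panels of disease-model hippocampus datasets
(e.g. Alzheimer's-model mice) compared against three reference signatures:
hippocampal **maturity** (infant vs adult), brain **pH**-associated genes,
and neural **hyperexcitation** (seizure-induced) genes. The package is for
computational biologists who have per-dataset DEG tables (gene, signed fold
change, p-value) and want comparable, signed overlap summaries across
heterogeneous datasets, plus a pathway-level meta-analysis of the shared
genes.

## The statistic

Each signature is a gene list ranked by absolute score with a sign per
gene. Comparing a query dataset against a reference runs five running
hypergeometric scans over the query ranking: at every rank cutoff *k*
(placed at tie-group boundaries only),

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>k</sub> = P(X ≥ x<sub>k</sub>),&nbsp; X ~ Hypergeom(N, K, k),

with N the gene universe, K the reference set size and x<sub>k</sub> the
top-*k* overlap; the minimum p over cutoffs is Bonferroni-corrected by the
number of cutoffs. Four scans are directional (up/up, down/down — concordant;
up/down, down/up — discordant) and one is unsigned, giving the overall
overlap p. The **similarity index** is

&nbsp;&nbsp;&nbsp;&nbsp;index = ± (−log₁₀ p<sub>overall</sub>),

signed by whether concordant or discordant evidence dominates: a negative
maturity index means the dataset's changes run *opposite* to maturation
(an immature-looking profile). Indices are correlated across datasets
(Pearson, OLS line), and per-dataset overlap gene sets are meta-analyzed
against a GMT collection by summing −log₁₀ enrichment p per term.

A fully seeded synthetic-data module generates reference signatures,
expression matrices with planted concordant/discordant overlaps, and GMT
collections with a planted enriched term, with complete truth bookkeeping —
so the whole pipeline is exercisable and testable without any downloads.

## Worked example

Simulate one dataset planted to be discordant with the maturity signature,
call DEGs with the |FC| > 1.2 & p < 0.05 criterion, and test the overlap:

```r
library(sigoverlap)
cfg  <- synthetic_config(seed = 11)
refs <- generate_references(cfg)
uni  <- synthetic_universe(cfg)
d    <- generate_dataset(cfg, refs, "model_A",
                         planted = list(maturity = c(0.05, 0.35)), seed = 101)
degs <- call_degs(d$matrix, name = "model_A")
ov   <- signature_overlap(degs, refs$maturity, uni)
ov
#> Signature overlap: model_A vs maturity (universe 5000 )
#>   shared genes: 300  overall p: 4.24e-158  dominant: negative
#>   up_up     n=  20  p_corrected=1
#>   down_down n=  25  p_corrected=1
#>   up_down   n= 131  p_corrected=3.7e-94
#>   down_up   n= 124  p_corrected=9.14e-89
similarity_index(ov)
#> Similarity index (maturity) = -157.4  [p = 4.24e-158 , negative ]
```

Reading: of the 300 genes the dataset shares with the maturity signature,
the discordant cells (131 + 124 genes, both with vanishing p) dominate the
concordant ones (20 + 25, p = 1), so the dataset anti-tracks maturation and
the index is negative; its magnitude is −log₁₀ of the overall overlap p.
The planted fractions (5% concordant, 35% discordant of an 800-gene
reference) are what the test recovered.

The full pipeline — simulate a 20-dataset cohort, DEG-call, overlap against
all three (disjointified) references, build the index table, correlate the
three index pairs, and meta-rank pathway enrichment — is one call:

```r
res <- run_pipeline("out/", seed = 11, n_datasets = 20)
res$correlations
#>                       pair  n          r            p      slope intercept
#> 1              maturity_ph 20  0.9261487 4.736861e-09  0.3338132  1.193040
#> 2 maturity_hyperexcitation 20 -0.9765341 1.881963e-13 -1.7346322  1.128967
#> 3       ph_hyperexcitation 20 -0.9155245 1.526388e-08 -4.5119801 11.848947
```

The default cohort plants maturity/pH discordance and hyperexcitation
concordance along a common severity ramp, and the recovered sign pattern
(maturity–pH positive, both hyperexcitation pairs negative) reflects that
construction. All outputs (overlap JSONs, index table, correlations,
meta-enrichment tables, manifest) are written under `out/`.

See `vignettes/signature-overlap-methods.Rmd` for the model, the
aggregation choices, the synthetic study design and its limitations.

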