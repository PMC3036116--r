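# penetrance

Maximum-likelihood estimation of the penetrance rate of a rare autosomal
dominant allele from pedigree phenotype data, with an exact Bayesian
credible interval, for genetic counselors and gene mappers.

Many dominant Mendelian disorders are incompletely penetrant: a carrier of
the pathogenic genotype expresses the phenotype only with probability

    K = P(affected | Aa),

and accurate estimates of K are needed for recurrence-risk counseling and
for penetrance-aware linkage analysis.  Because the allele is rare,
affected individuals can be taken to be Aa heterozygotes and married-in
spouses to be aa; a pedigree's phenotypes then depend on K only through a
small set of structures, and the likelihood (up to a constant) is

    L(K) = K^A (1-K)^B ((2-K)/2)^C × Π_t f_t(K) × Π_c w_c(K)^{n_c}

where A counts affected (penetrant) carriers, B obligate non-penetrant
carriers, C childless normal offspring of obligate carriers, f_t are the
probabilities of the trees of normal descendants (computed by the recursion
f = 1/2 + (1-K)/2 · Π f(child), with f = (2-K)/2 at childless nodes), and
w_c are same-sex twin-pair class probabilities mixed over zygosity.  The
package:

* reads pedigrees in 6-column LINKAGE/PED format (plus a YAML sidecar for
  twin pairs and the designated carrier founder) and a compact
  structure-counts text format;
* filters a pedigree into the structures above, inferring obligate
  carriers;
* detects consanguineous marriage loops, splits them into transmission
  configurations, and combines the per-configuration estimates by
  inverse-variance weighting;
* maximizes L(K) and computes the exact (quadrature-based, not
  normal-approximation) 95% credible interval under a uniform prior,
  equal-tailed by default, HPD optionally;
* computes per-individual heterozygosity probabilities and offspring risks;
* includes a gene-drop simulator for parameter-recovery studies;
* ships a command-line interface (`exec/penetrance`) with subcommands
  `estimate`, `risks`, `simulate`, `fixtures`.

See the methods vignette (`vignettes/penetrance-methods.Rmd`) for the model,
assumptions, numerical choices and limitations.

## Worked example

The bundled four-generation example family has three affected individuals,
four obligate non-penetrant carriers, two childless normal offspring of
carriers and two 2-generation trees of normal individuals:

```r
library(penetrance)
ped <- make_fixture("fig1")
extract_structures(ped)
#> Structure counts: A = 3 affected, B = 4 obligate non-penetrant, C = 2 childless normal
#> Normal trees: 2  3

fit <- estimate_penetrance(ped)
report_text(fit)
#> Penetrance estimation results
#>   estimate of K            : 0.334106
#>   exact 95% credibility interval: [0.119722, 0.694037]
#>   variance                 : 0.022698781
#>   likelihood function: L(K) = K^3 * (1-K)^4 * ((2-K)/2)^2 * [1/2 + (1-K)/2*((2-K)/2)^2] * [1/2 + (1-K)/2*((2-K)/2)^3]
```

About a third of this family's carriers express the condition; the wide
interval reflects how little a single small family constrains K.  Risk
columns for counseling, at the estimated K:

```r
head(risk_table(ped, k = fit$k_hat), 3)
#>     id classification heterozygosity offspring_risk
#> 1  I-1       obligate      1.0000000     0.16705294
#> 2 II-1       obligate      1.0000000     0.16705294
#> 3 II-2           tree      0.3160045     0.05278948
```

The same estimate from the shell, via the counts route:

```sh
exec/penetrance estimate --counts fig1_counts.txt
```

where `fig1_counts.txt` holds the filtered decomposition
(`3,4,2` / `2,2,3` / `0` / `0` / `0` / `0,0,0` / `0`).  A consanguineous
family (`make_fixture("fig5")`) is automatically split into its two
transmission configurations, estimated per configuration, and combined by
inverse-variance weighting.

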