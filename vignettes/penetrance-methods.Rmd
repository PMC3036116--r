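---
title: "Penetrance estimation from pedigrees: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penetrance estimation from pedigrees: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penetrance)
```

## The genetic model

We consider a single autosomal locus with a rare dominant pathogenic allele
A and normal allele a.  Because A is rare, AA homozygotes are ignored:
affected individuals are taken to be Aa heterozygotes, and every normal
individual is either aa or a non-penetrant Aa carrier.  Married-in spouses
of family members are assumed aa with probability one, and exactly one
founder lineage introduces the allele (single origin, no phenocopies, no
de novo mutation).  The one free parameter is the penetrance rate

$$K = \Pr(\text{affected} \mid Aa), \qquad K \in [0, 1].$$

Under these assumptions the phenotypes of a whole pedigree depend on K only
through a small set of structures, and the likelihood factorizes over them.

## Filtering a pedigree into structures

`identify_obligate_carriers()` finds every individual that must carry A:
all affected individuals, plus every individual lying on *all* transmission
paths from the allele's origin to some affected descendant.  The origin is
the designated carrier founder when the sidecar annotation provides one;
otherwise it is the unique topmost affected individual that is an ancestor
of every other affected individual.  When neither exists (e.g. affected
siblings under normal founder parents), either member of the founder couple
could have transmitted, and the package refuses to guess: the user must
designate the carrier founder.  This is a deliberate design choice — a
silent arbitrary pick would change B by one and bias the estimate.

`extract_structures()` then classifies each informative individual exactly
once:

* **A** — affected (penetrant) carriers, contributing a factor $K$;
* **B** — obligate non-penetrant carriers, contributing $1 - K$;
* **C** — childless normal offspring of an obligate carrier, contributing
  $(2-K)/2 = \tfrac12 \cdot 1 + \tfrac12 (1 - K)$, the probability that a
  child of an $Aa \times aa$ mating is unaffected;
* **trees of normal individuals** — a normal child of an obligate carrier
  together with its all-normal descendants, contributing $f(\text{root})$
  from the recursion
  $$f(x) = \begin{cases} (2-K)/2 & x \text{ childless} \\
  \tfrac12 + \tfrac{1-K}{2} \prod_{c \in \text{children}(x)} f(c) &
  \text{otherwise;} \end{cases}$$
* **same-sex twin pairs** — see below.

Married-in spouses carry no information and are excluded.  Individuals with
unknown phenotype are excluded from the likelihood with a warning, together
with their descendants when those are only reachable through them; an
unknown-phenotype individual that demonstrably transmitted the allele is
still treated as transmitting but contributes no phenotype factor.  We
exclude rather than integrate over unknown phenotypes because the structure
taxonomy is defined for observed normal/affected states; integrating would
require an assumption about why the phenotype is missing.

The constant factors of the likelihood — the $\tfrac12$ transmission
probabilities of obligate carriers and founder priors — are dropped
throughout, so $L(K)$ is defined up to proportionality; neither the MLE nor
the normalized posterior is affected.

The correctness of the decomposition is pinned in the test suite by an
exhaustive oracle: for small simulated pedigrees the log-likelihood-ratio
between any two values of K computed from the filtered structures agrees
with a brute-force sum over all carrier-state assignments of every blood
member of the full pedigree, to ~1e-14.

## Twin pairs

A same-sex twin pair born (childless) to an obligate carrier falls into one
of three classes — both normal, discordant, both affected.  Each class
probability is a mixture over zygosity with mixing weight
`mz_prob` $= m = \Pr(\text{MZ} \mid \text{same-sex pair})$:
monozygotic twins share one genotype (Aa with probability $\tfrac12$) and
are assumed to express the phenotype independently given that genotype (no
shared-environment concordance parameter); dizygotic twins have independent
genotypes like ordinary siblings.  The default $m = 0.5$ is a neutral
choice, adjustable per dataset; `weinberg_mz_prob()` estimates $m$ from
same-sex and opposite-sex pair counts by Weinberg's differential rule.
Opposite-sex pairs are necessarily dizygotic and are treated as two
ordinary siblings.  Twin pairs with their own offspring are not supported
(error), and a twin pair not born to an obligate carrier is an error since
all three class terms condition on a carrier parent.

## Consanguineous loops

When the two members of a couple are both blood descendants of the carrier
lineage, an affected descendant of that couple may have received the allele
through either line, and intermediate ancestors are no longer obligate.
`detect_consanguineous_loops()` finds such loops by enumerating transmission
paths; the supported taxonomy is the classical pattern of two candidate
transmitting lines converging on one descendant line.  Branch members that
are obligate regardless of the loop (affected, designated, or with affected
descendants outside the loop) are trimmed off the ambiguity.  Anything more
tangled — three or more routes, loops sharing members, routes that split
again below their reconvergence — raises an "unsupported loop" error rather
than producing silent nonsense; full Elston–Stewart peeling of arbitrary
loop topologies is a non-goal.

`split_configurations()` fixes the transmission route through each candidate
transmitter in turn by severing the join child's link to the other mate and
re-running the standard classification: the chosen line becomes obligate,
while the other line's members fall back to childless normals or normal
trees (their offspring through the couple being explained by the carrier
partner).  The likelihood of the family is then the common (non-inbred)
part times one term per loop configuration.  `combine_configurations()`
enumerates the Cartesian product of configurations across loops, estimates
$K_{ij}$ with variance $\mathrm{var}(K_{ij})$ for each combination, and
combines them with weights $w_{ij} = 1/\mathrm{var}(K_{ij})$:
$$\hat K = \frac{\sum w_{ij} K_{ij}}{\sum w_{ij}},$$
the interval limits being the same weighted means of the per-combination
limits.  The package supports any number of loops (warning above 64
combinations).  A consistency check verifies that the classification of
individuals *outside* the loops does not depend on the assumed route; if it
does, the pattern is outside the supported taxonomy and an error is raised.

## Estimation

**MLE.** $\log L$ is maximized over $[0,1]$ by a grid pre-scan (step
$10^{-3}$) followed by `stats::optimize()` refinement (tolerance $10^{-10}$)
in the bracketing interval, guarding against the mild multimodality that
mixed tree/twin terms can in principle produce.  Boundary maxima (0 or 1)
are admissible and reported with a warning; the credible interval remains
interior by construction.

**Exact credible interval.** "Exact" means computed from the likelihood
itself, not from a normal approximation: the likelihood is normalized over
$[0,1]$ under a uniform prior by adaptive quadrature
(`stats::integrate()`, split at the posterior mode, relative tolerance
$10^{-12}$), and the default equal-tailed interval takes the
$(1-\ell)/2$ and $1-(1-\ell)/2$ posterior quantiles by root-finding on the
posterior CDF (`uniroot`, tolerance $10^{-9}$ in K).  The equal-tailed
convention was chosen as the default because it is the standard reporting
convention for credible intervals and is invariant to monotone
reparameterization of the CDF; the highest-posterior-density (shortest)
interval is available with `interval = "hpd"`.

**Variance.** The default `variance = "posterior"` is the variance of K
under the normalized posterior, computed from the first two moments by the
same quadrature — consistent with the credibility framework and the
inverse-variance weights used for consanguineous combinations.  The
observed-information variance $1/(-\partial^2 \log L/\partial K^2)$ at the
MLE is available as `variance = "information"` (undefined at boundary
MLEs).  Where conventions were genuinely open, both are exposed and the
defaults documented here.

Whenever the decomposition is purely binomial ($L \propto K^a (1-K)^b$) the
posterior is Beta$(a+1, b+1)$, and the test suite requires agreement of the
MLE, interval and variance with the conjugate closed forms to $10^{-6}$
over $a, b \in \{0, \ldots, 6\}$.

## Heterozygosity probabilities and offspring risks

At a penetrance value $K$ (by default the MLE; any posterior summary can be
passed instead — which summary the counselor plugs in is a reporting
choice, not a modeling one):

* affected individuals and obligate carriers have carrier probability 1;
* a married-in non-descendant has probability 0;
* a childless normal child of an obligate carrier has
  $\tfrac{(1-K)}{(2-K)}$;
* a member $x$ of a normal tree has
  $\Pr(\text{parent of } x \text{ carries}) \cdot
  \tfrac12 (1-K) \prod_{c} f(c) / f(x)$, applied top-down from the root
  (whose parent is an obligate carrier); each individual's posterior uses
  its own structure only, which is exact because structures are independent
  given the obligate-carrier skeleton;
* normal twin members use the zygosity-mixture posterior (the normal
  co-twin of an affected monozygote is itself an obligate carrier).

The offspring risk is $\Pr(\text{carrier}) \times \tfrac{K}{2}$, the
probability that a future child with a non-carrier mate is affected.  The
tree formulas are pinned against a brute-force conditional-probability
oracle (enumeration of all carrier states) to $10^{-12}$.

## The gene-drop simulator and the recovery study

`random_topology()` builds a loop-free skeleton: a founder couple whose
first member is the designated carrier, every blood member of the
non-terminal generations marrying in a new spouse, with sibship sizes
$1 + \text{Poisson}(\bar s - 1)$; the defaults (4 generations, mean sibship
3) describe a modest clinical family.  `gene_drop()` implements the genetic
model generatively: the designated founder is Aa, each child of a carrier
receives the allele with probability $\tfrac12$, carriers are affected with
probability $K_{\text{true}}$.  The simulator emulates phenotype
segregation only: it does not model ascertainment (families are not
selected for coming to clinical attention), allele frequency, mutation,
phenocopies, or genotyping data — so passing recovery tests demonstrates
internal consistency of the estimator under its own model, not robustness
to those real-data features.

The parameter-recovery study in the test suite runs 500 gene-drop
replicates at $K_{\text{true}} = 0.7$ on one fixed large multiplex family
(4 generations, mean sibship 5, 158 individuals, drawn once from the
generator under a fixed seed) and requires the mean $\hat K$ within 0.05 of
the truth and 95%-interval coverage between 93% and 97%.  The topology is
deliberately an information-rich multiplex family — the setting penetrance
studies are actually conducted in — because the calibration being checked
is a likelihood property: in very small families the uniform prior
contributes a non-negligible share of the posterior, intervals widen, and
coverage at a fixed true value rises above the nominal level (we observe
98–99% on a 22-member family).  Replicates without a single affected
individual carry no information about K and are skipped; in small families
this conditioning also biases the mean of $\hat K$ upward, a form of
ascertainment effect that the method, by design, does not correct.

## Numerical and input conventions

* Phenotype coding in PED files: 1 = normal, 2 = affected, 0 = unknown;
  0 = missing parent; extra columns ignored with a warning.
* Twin pairs and the designated carrier founder are not expressible in
  standard PED and live in a sidecar YAML file, keeping the PED file
  interoperable with LINKAGE-family tools.
* The structure-counts text format stores trees of 2–5 generations; the
  nested-parenthesis serialization for trees deeper than two generations
  and the per-configuration blocks are this package's own documented
  extension (flagged in the emitted file header).  Deeper trees are
  supported in memory and from PED input, just not in this file format.
* Degenerate inputs: an empty decomposition has a constant likelihood and
  K is reported as non-identifiable; $K = 0$ with $A > 0$ (or $K = 1$ with
  $B > 0$) is a valid $-\infty$ log-likelihood, not an exception.

## Known limitations

* No ascertainment correction: estimates from families collected because
  they contain affected individuals are biased upward, most visibly in
  small families.
* Obligate-carrier logic assumes the single-origin, rare-allele model; AA
  homozygotes, phenocopies and de novo cases are out of scope.
* Only the two-route consanguinity pattern is supported; X-linked and
  recessive models are not.
* Risks are not defined for pedigrees with unresolved loops.
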