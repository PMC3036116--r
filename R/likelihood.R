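#' Log-likelihood of the penetrance rate
#'
#' The model: a single rare autosomal dominant locus (A, a).  Affected
#' individuals are taken to be Aa heterozygotes; normal individuals are
#' either aa homozygotes or non-penetrant Aa heterozygotes; married-in
#' spouses are aa with probability one.  The penetrance rate
#' K = P(affected | Aa) is the single free parameter.  Given the filtered
#' decomposition of a pedigree into structure counts, the likelihood (up to a
#' K-independent constant: the 1/2 transmission factors of obligate carriers
#' and founder priors are dropped) is
#' \deqn{L(K) = K^A (1-K)^B \left(\frac{2-K}{2}\right)^C
#'   \prod_t f_t(K) \prod_c w_c(K)^{n_c}}
#' where A, B, C count affected penetrant carriers, obligate non-penetrant
#' carriers and childless normal offspring of carriers, \eqn{f_t} are the
#' normal-tree probabilities of [tree_term()] and \eqn{w_c} the twin-class
#' probabilities of [twin_term()].
#'
#' The childless-normal factor \eqn{(2-K)/2} is the probability that a child
#' of an Aa x aa mating is unaffected: \eqn{1/2 + (1-K)/2}.
#'
#' @param counts a \code{pen_counts} decomposition.  Consanguineous trees
#'   must have been resolved upstream (see [combine_configurations()]); their
#'   presence is an error here.
#' @param k penetrance value(s) in [0, 1]; vectorized.
#' @param mz_prob probability that a same-sex twin pair is monozygotic
#'   (default 0.5); see [twin_term()].
#' @return numeric vector of log-likelihood values (up to an additive
#'   constant).  \code{K = 0} with \code{A > 0}, or \code{K = 1} with
#'   \code{B > 0}, gives \code{-Inf}, a valid log-likelihood value.
#' @seealso [estimate_penetrance()], [likelihood_formula()]
#' @export
#' @examples
#' cnt <- structure_counts(3, 4, 2, trees = list(two_gen_tree(2), two_gen_tree(3)))
#' log_likelihood(cnt, c(0.3, 0.5, 0.7))
log_likelihood <- function(counts, k, mz_prob = 0.5) {
  stopifnot(inherits(counts, "pen_counts"), all(k >= 0 & k <= 1),
            mz_prob >= 0, mz_prob <= 1)
  if (length(counts$consanguineous) > 0L) {
    stop("log_likelihood is defined for a single configuration; resolve ",
         "consanguineous trees with combine_configurations()/",
         "estimate_penetrance() first")
  }
  ll <- rep(0, length(k))
  if (counts$n_affected > 0L) ll <- ll + counts$n_affected * log(k)
  if (counts$n_obligate > 0L) ll <- ll + counts$n_obligate * log(1 - k)
  if (counts$n_childless > 0L) ll <- ll + counts$n_childless * log((2 - k) / 2)
  for (tr in counts$trees) ll <- ll + log(tree_term(tr, k))
  for (cls in names(counts$twins)) {
    n <- counts$twins[[cls]]
    if (n > 0L) ll <- ll + n * log(twin_term(cls, k, mz_prob))
  }
  ll
}

#' Probability that a normal tree is observed all-normal
#'
#' For a node x whose parent is an obligate carrier of the dominant allele,
#' \code{tree_term} returns f(x), the probability that x and its entire
#' subtree of descendants are phenotypically normal.  The recursion: for a
#' childless node \eqn{f = (2-K)/2}; for a node with children
#' \eqn{c_1 \ldots c_m},
#' \deqn{f = \frac12 + \frac{1-K}{2} \prod_i f(c_i),}
#' since with probability 1/2 the node is aa (its whole line then normal with
#' probability one, spouses being non-carriers) and with probability 1/2 it
#' is Aa, unaffected with probability 1-K, each child subtree then being
#' independently normal with probability \eqn{f(c_i)}.  Any depth is
#' supported.
#'
#' @param tree a [normal_tree()].
#' @param k penetrance value(s) in [0, 1]; vectorized.
#' @return probability vector, same length as \code{k}.
#' @export
#' @examples
#' tree_term(two_gen_tree(2), 0.5)  # 1/2 * (1 + 0.5 * 0.75^2)
tree_term <- function(tree, k) {
  stopifnot(inherits(tree, "normal_tree"), all(k >= 0 & k <= 1))
  rec <- function(node) {
    if (length(node$children) == 0L) return((2 - k) / 2)
    prod_f <- Reduce(`*`, lapply(node$children, rec))
    0.5 + 0.5 * (1 - k) * prod_f
  }
  rec(tree)
}

#' Twin-pair class probabilities
#'
#' Probability of observing a same-sex twin-pair phenotype class among the
#' childless twin offspring of an obligate carrier, as a mixture over
#' zygosity.  Monozygotic twins share one genotype (Aa with probability 1/2)
#' and express the phenotype independently given that genotype; dizygotic
#' twins have independent genotypes, like ordinary siblings.
#'
#' \tabular{lll}{
#'   class \tab MZ \tab DZ \cr
#'   both_normal \tab \eqn{1/2 + (1-K)^2/2} \tab \eqn{((2-K)/2)^2} \cr
#'   discordant \tab \eqn{K(1-K)} \tab \eqn{K(2-K)/2} \cr
#'   both_affected \tab \eqn{K^2/2} \tab \eqn{K^2/4}
#' }
#'
#' The returned value is \code{mz_prob * MZ + (1 - mz_prob) * DZ}.  For every
#' K and \code{mz_prob} the three class probabilities sum to one.
#'
#' @param class one of \code{"both_normal"}, \code{"discordant"},
#'   \code{"both_affected"}.
#' @param k penetrance value(s) in [0, 1]; vectorized.
#' @param mz_prob probability the pair is monozygotic.
#' @return probability vector, same length as \code{k}.
#' @export
twin_term <- function(class, k, mz_prob = 0.5) {
  stopifnot(all(k >= 0 & k <= 1), mz_prob >= 0, mz_prob <= 1)
  class <- match.arg(class, c("both_normal", "discordant", "both_affected"))
  mz <- switch(class,
    both_normal = 0.5 + 0.5 * (1 - k)^2,
    discordant = k * (1 - k),
    both_affected = 0.5 * k^2
  )
  dz <- switch(class,
    both_normal = ((2 - k) / 2)^2,
    discordant = k * (2 - k) / 2,
    both_affected = k^2 / 4
  )
  mz_prob * mz + (1 - mz_prob) * dz
}

#' Estimate the monozygotic proportion by Weinberg's differential rule
#'
#' Among twin pairs, opposite-sex pairs are necessarily dizygotic and
#' same-sex dizygotic pairs occur at (approximately) the same rate, so the
#' monozygotic fraction among same-sex pairs is estimated as
#' \code{(n_same_sex - n_opposite_sex) / n_same_sex}.
#'
#' @param n_same_sex number of same-sex pairs.
#' @param n_opposite_sex number of opposite-sex pairs.
#' @return estimated P(MZ | same-sex pair), clamped to [0, 1].
#' @export
weinberg_mz_prob <- function(n_same_sex, n_opposite_sex) {
  stopifnot(n_same_sex > 0, n_opposite_sex >= 0)
  max(0, min(1, (n_same_sex - n_opposite_sex) / n_same_sex))
}

#' Render the likelihood formula as text
#'
#' Plain-text display of L(K) for a structure-count decomposition, e.g.
#' \code{"K^3 * (1-K)^4 * ((2-K)/2)^2 * [1/2 + (1-K)/2*((2-K)/2)^2]"},
#' mirroring the results screen of the original penetrance calculators.
#'
#' @param counts a \code{pen_counts} decomposition (consanguineous trees not
#'   supported here; the combined report lists one formula per
#'   configuration).
#' @param mz_prob twin monozygosity probability, shown symbolically as
#'   \code{m} only when twins are present.
#' @return a single string.
#' @export
likelihood_formula <- function(counts, mz_prob = 0.5) {
  stopifnot(inherits(counts, "pen_counts"))
  if (length(counts$consanguineous) > 0L) {
    stop("likelihood_formula applies to a single configuration")
  }
  pow <- function(base, n) {
    if (n == 0L) return(character(0))
    if (n == 1L) base else paste0(base, "^", n)
  }
  factors <- c(
    pow("K", counts$n_affected),
    pow("(1-K)", counts$n_obligate),
    pow("((2-K)/2)", counts$n_childless)
  )
  tree_strs <- vapply(counts$trees, tree_factor_string, character(1))
  if (length(tree_strs) > 0L) {
    tab <- table(tree_strs)
    factors <- c(factors, unlist(Map(pow, names(tab), as.integer(tab)),
                                 use.names = FALSE))
  }
  twin_str <- c(
    both_normal = paste0("[m*(1/2+(1-K)^2/2) + (1-m)*((2-K)/2)^2]"),
    discordant = paste0("[m*K*(1-K) + (1-m)*K*(2-K)/2]"),
    both_affected = paste0("[m*K^2/2 + (1-m)*K^2/4]")
  )
  for (cls in names(counts$twins)) {
    factors <- c(factors, pow(twin_str[[cls]], counts$twins[[cls]]))
  }
  if (length(factors) == 0L) return("1")
  paste(factors, collapse = " * ")
}

tree_factor_string <- function(tree) {
  if (length(tree$children) == 0L) return("((2-K)/2)")
  child_strs <- vapply(tree$children, tree_factor_string, character(1))
  tab <- table(child_strs)
  prods <- mapply(function(b, n) if (n == 1L) b else paste0(b, "^", n),
                  names(tab), as.integer(tab))
  paste0("[1/2 + (1-K)/2*", paste(prods, collapse = "*"), "]")
}
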