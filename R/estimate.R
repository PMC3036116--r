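#' Maximum-likelihood estimate of the penetrance rate
#'
#' Maximizes the log-likelihood over K in [0, 1] by a grid pre-scan (step
#' 1e-3) followed by bounded scalar refinement around the best grid point;
#' the grid guards against the mild multimodality that mixed tree/twin terms
#' can in principle produce.  Boundary maxima (0 or 1) are admissible and
#' reported as-is with a warning.
#'
#' @param counts a \code{pen_counts} decomposition without consanguineous
#'   trees.
#' @param mz_prob twin monozygosity probability.
#' @return the MLE of K.
#' @export
#' @examples
#' penetrance_mle(structure_counts(3, 4, 0))  # 3/7, the binomial MLE
penetrance_mle <- function(counts, mz_prob = 0.5) {
  if (counts_empty(counts)) {
    stop("penetrance K is not identifiable: the structure counts carry no ",
         "information (constant likelihood)")
  }
  f <- function(k) log_likelihood(counts, k, mz_prob)
  grid <- seq(0, 1, by = 1e-3)
  lg <- f(grid)
  ib <- which.max(lg)
  lo <- max(0, grid[ib] - 2e-3)
  hi <- min(1, grid[ib] + 2e-3)
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  cand_k <- c(opt$maximum, 0, 1)
  cand_v <- c(opt$objective, f(0), f(1))
  k_hat <- cand_k[which.max(cand_v)]
  if (k_hat < 1e-9) k_hat <- 0
  if (k_hat > 1 - 1e-9) k_hat <- 1
  if (k_hat %in% c(0, 1)) {
    warning("maximum-likelihood estimate lies on the boundary (K = ", k_hat,
            "); the credible interval remains interior")
  }
  k_hat
}

# Normalized posterior machinery: uniform prior on [0,1], density
# proportional to exp(logL).  Integrals are split at the mode for stable
# adaptive quadrature on sharply peaked likelihoods.
posterior_setup <- function(counts, mz_prob = 0.5, allow_flat = FALSE) {
  flat <- counts_empty(counts)
  if (flat && !allow_flat) {
    stop("penetrance K is not identifiable: the structure counts carry no ",
         "information (constant likelihood)")
  }
  f <- function(k) log_likelihood(counts, k, mz_prob)
  grid <- seq(0, 1, by = 1e-3)
  lg <- f(grid)
  M <- max(lg)
  mode <- grid[which.max(lg)]
  dens_raw <- function(k) exp(f(k) - M)
  piecewise <- function(g, lower, upper) {
    cuts <- sort(unique(c(lower, upper, mode[mode > lower & mode < upper])))
    tot <- 0
    for (i in seq_len(length(cuts) - 1L)) {
      tot <- tot + stats::integrate(g, cuts[i], cuts[i + 1L],
                                    rel.tol = 1e-12, abs.tol = 1e-12,
                                    subdivisions = 500L)$value
    }
    tot
  }
  Z <- piecewise(dens_raw, 0, 1)
  dens <- function(k) dens_raw(k) / Z
  list(
    density = dens,
    cdf = function(q) {
      if (q <= 0) return(0)
      if (q >= 1) return(1)
      piecewise(dens, 0, q)
    },
    moment = function(p) piecewise(function(k) k^p * dens(k), 0, 1),
    mode = mode
  )
}

posterior_quantile <- function(post, alpha) {
  if (alpha <= 0) return(0)
  if (alpha >= 1) return(1)
  stats::uniroot(function(q) post$cdf(q) - alpha, interval = c(0, 1),
                 tol = 1e-9)$root
}

#' Exact credible interval for the penetrance rate
#'
#' Normalizes the likelihood over [0, 1] under a uniform prior by adaptive
#' quadrature and returns a posterior interval at the requested level.  The
#' default is the equal-tailed interval, whose limits are the (1-level)/2 and
#' 1-(1-level)/2 posterior quantiles found by root-finding on the posterior
#' CDF; \code{type = "hpd"} gives the highest-posterior-density (shortest)
#' interval instead.  "Exact" means computed from the normalized likelihood,
#' not from a normal approximation.
#'
#' @param counts a \code{pen_counts} decomposition without consanguineous
#'   trees.
#' @param level credibility level in (0, 1), default 0.95.
#' @param mz_prob twin monozygosity probability.
#' @param type \code{"equal_tailed"} (default) or \code{"hpd"}.
#' @param allow_flat if \code{TRUE}, an empty decomposition is treated as a
#'   uniform posterior instead of an error.
#' @return numeric vector \code{c(lower, upper)}.
#' @export
#' @examples
#' credibility_interval(structure_counts(3, 4, 0))  # Beta(4, 5) quantiles
credibility_interval <- function(counts, level = 0.95, mz_prob = 0.5,
                                 type = c("equal_tailed", "hpd"),
                                 allow_flat = FALSE) {
  stopifnot(level > 0, level < 1)
  type <- match.arg(type)
  post <- posterior_setup(counts, mz_prob, allow_flat = allow_flat)
  alpha <- (1 - level) / 2
  if (type == "equal_tailed") {
    return(c(posterior_quantile(post, alpha),
             posterior_quantile(post, 1 - alpha)))
  }
  upper_of <- function(l) posterior_quantile(post, post$cdf(l) + level)
  l_max <- posterior_quantile(post, 1 - level)
  opt <- stats::optimize(function(l) upper_of(l) - l,
                         interval = c(0, l_max), tol = 1e-7)
  c(opt$minimum, upper_of(opt$minimum))
}

#' Posterior variance of the penetrance rate
#'
#' Variance of K under the normalized posterior (uniform prior), computed by
#' quadrature of the first two moments; this is the variance used to weight
#' consanguineous configuration estimates.  With
#' \code{convention = "information"} the observed-information variance
#' \eqn{1/(-d^2 \log L / dK^2)} at the MLE is returned instead.
#'
#' @param counts a \code{pen_counts} decomposition without consanguineous
#'   trees.
#' @param mz_prob twin monozygosity probability.
#' @param convention \code{"posterior"} (default) or \code{"information"}.
#' @param allow_flat treat an empty decomposition as a uniform posterior
#'   (variance 1/12) instead of an error.
#' @return the variance, a positive scalar.
#' @export
posterior_variance <- function(counts, mz_prob = 0.5,
                               convention = c("posterior", "information"),
                               allow_flat = FALSE) {
  convention <- match.arg(convention)
  if (convention == "posterior") {
    post <- posterior_setup(counts, mz_prob, allow_flat = allow_flat)
    m1 <- post$moment(1)
    m2 <- post$moment(2)
    return(m2 - m1^2)
  }
  k_hat <- suppressWarnings(penetrance_mle(counts, mz_prob))
  h <- min(1e-5, k_hat / 2, (1 - k_hat) / 2)
  if (h <= 0) {
    stop("observed-information variance is undefined at a boundary MLE; ",
         "use convention = 'posterior'")
  }
  f <- function(k) log_likelihood(counts, k, mz_prob)
  d2 <- (f(k_hat + h) - 2 * f(k_hat) + f(k_hat - h)) / h^2
  if (d2 >= 0) stop("likelihood is not locally concave at the MLE")
  -1 / d2
}

# point estimate + interval + variance for one configuration
fit_one <- function(counts, level, mz_prob, interval_type, variance_type) {
  k_hat <- suppressWarnings(penetrance_mle(counts, mz_prob))
  ci <- credibility_interval(counts, level, mz_prob, type = interval_type)
  v <- posterior_variance(counts, mz_prob, convention = variance_type)
  list(k_hat = k_hat, ci = ci, variance = v)
}

new_pen_fit <- function(k_hat, ci, level, variance, formula,
                        per_configuration = NULL, counts = NULL,
                        options = list()) {
  structure(
    list(k_hat = k_hat, ci_lower = ci[1], ci_upper = ci[2], level = level,
         variance = variance, formula = formula,
         per_configuration = per_configuration, counts = counts,
         options = options),
    class = "pen_fit"
  )
}

#' Estimate penetrance from a pedigree or a structure-count decomposition
#'
#' The main entry point.  For a pedigree, the filtered decomposition is
#' computed with [extract_structures()]; consanguineous loops are detected,
#' split into transmission configurations and combined by inverse-variance
#' weighting ([combine_configurations()]).  For a \code{pen_counts} object
#' (e.g. read with [read_structure_counts()]) the same estimation runs on the
#' pre-tabulated counts.
#'
#' @param x a \code{pen_pedigree} or \code{pen_counts} object.
#' @param level credibility level, default 0.95.
#' @param mz_prob twin monozygosity probability, default 0.5 (see
#'   [weinberg_mz_prob()]).
#' @param interval interval convention, \code{"equal_tailed"} or
#'   \code{"hpd"}.
#' @param variance variance convention, \code{"posterior"} or
#'   \code{"information"}.
#' @param ... passed between methods.
#' @return a \code{pen_fit} object with components \code{k_hat},
#'   \code{ci_lower}, \code{ci_upper}, \code{level}, \code{variance},
#'   \code{formula} (likelihood display string) and, for consanguineous
#'   pedigrees, \code{per_configuration} (one row per configuration
#'   combination with its estimate, variance, interval and weight).
#' @export
#' @examples
#' fit <- estimate_penetrance(make_fixture("fig1"))
#' fit
estimate_penetrance <- function(x, ...) UseMethod("estimate_penetrance")

#' @rdname estimate_penetrance
#' @export
estimate_penetrance.pen_counts <- function(x, level = 0.95, mz_prob = 0.5,
                                           interval = c("equal_tailed", "hpd"),
                                           variance = c("posterior",
                                                        "information"), ...) {
  interval <- match.arg(interval)
  variance <- match.arg(variance)
  opts <- list(level = level, mz_prob = mz_prob, interval = interval,
               variance = variance)
  if (length(x$consanguineous) > 0L) {
    common <- structure_counts(x$n_affected, x$n_obligate, x$n_childless,
                               trees = x$trees, twins = x$twins)
    return(combine_configurations(common, x$consanguineous, level = level,
                                  mz_prob = mz_prob, interval = interval,
                                  variance = variance))
  }
  est <- fit_one(x, level, mz_prob, interval, variance)
  new_pen_fit(est$k_hat, est$ci, level, est$variance,
              likelihood_formula(x, mz_prob), counts = x, options = opts)
}

#' @rdname estimate_penetrance
#' @export
estimate_penetrance.pen_pedigree <- function(x, level = 0.95, mz_prob = 0.5,
                                             interval = c("equal_tailed",
                                                          "hpd"),
                                             variance = c("posterior",
                                                          "information"),
                                             ...) {
  dec <- decompose_pedigree(x)
  counts <- dec$common
  if (length(dec$loops) > 0L) counts$consanguineous <- dec$loops
  estimate_penetrance(counts, level = level, mz_prob = mz_prob,
                      interval = interval, variance = variance)
}

#' @export
print.pen_fit <- function(x, digits = 4, ...) {
  cat("Penetrance estimate\n")
  cat("  K-hat = ", format(round(x$k_hat, digits)), "\n", sep = "")
  cat("  ", format(100 * x$level), "% credible interval: [",
      format(round(x$ci_lower, digits)), ", ",
      format(round(x$ci_upper, digits)), "]\n", sep = "")
  cat("  posterior variance = ", format(signif(x$variance, digits)), "\n",
      sep = "")
  if (!is.null(x$per_configuration)) {
    cat("  combined over", nrow(x$per_configuration),
        "configuration combination(s) by inverse-variance weighting:\n")
    pc <- x$per_configuration
    num <- vapply(pc, is.numeric, logical(1))
    pc[num] <- lapply(pc[num], round, digits = digits)
    print(pc, row.names = FALSE)
  }
  if (!is.null(x$formula)) cat("  L(K) =", x$formula, "\n")
  invisible(x)
}
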