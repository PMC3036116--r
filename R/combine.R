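#' Combine consanguineous-configuration estimates
#'
#' A pedigree with consanguineous loops has a likelihood made of a common
#' (non-inbred) part multiplied by one configuration term per loop, where the
#' configuration fixes through which candidate ancestor the allele reached
#' the loop's affected descendants.  This function enumerates the Cartesian
#' product of configurations across loops (two loops with two configurations
#' each give exactly four combinations), estimates K for every combination
#' from the merged counts, and combines the estimates by inverse-variance
#' weighting: \eqn{\hat K = \sum w_{ij} K_{ij} / \sum w_{ij}} with
#' \eqn{w_{ij} = 1/\mathrm{var}(K_{ij})}.  The combined interval limits are
#' the same weighted means of the per-combination lower and upper limits.
#'
#' @param common \code{pen_counts} for the non-inbred part (may be empty).
#' @param trees list of consanguineous trees, each with a
#'   \code{configurations} list of \code{pen_counts} (see
#'   [split_configurations()] and [read_structure_counts()]).
#' @param level credibility level.
#' @param mz_prob twin monozygosity probability.
#' @param interval interval convention.
#' @param variance variance convention for both the reported variances and
#'   the weights.
#' @return a \code{pen_fit} whose \code{per_configuration} component has one
#'   row per combination: label, k_hat, variance, ci_lower, ci_upper, weight.
#' @export
combine_configurations <- function(common, trees, level = 0.95,
                                   mz_prob = 0.5,
                                   interval = c("equal_tailed", "hpd"),
                                   variance = c("posterior", "information")) {
  interval <- match.arg(interval)
  variance <- match.arg(variance)
  stopifnot(inherits(common, "pen_counts"), length(common$consanguineous) == 0L)
  if (length(trees) == 0L) stop("no consanguineous trees to combine")
  n_cfg <- vapply(trees, function(ct) length(ct$configurations), integer(1))
  if (any(n_cfg == 0L)) {
    stop("every consanguineous tree needs at least one surviving configuration")
  }
  n_comb <- prod(n_cfg)
  if (n_comb > 64L) {
    warning("configuration product is ", n_comb,
            " combinations; expect a combinatorial slowdown")
  }
  idx <- expand.grid(lapply(n_cfg, seq_len))
  rows <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    chosen <- lapply(seq_along(trees), function(t) {
      trees[[t]]$configurations[[idx[r, t]]]
    })
    total <- Reduce(merge_counts, chosen, common)
    est <- fit_one(total, level, mz_prob, interval, variance)
    labels <- vapply(seq_along(trees), function(t) {
      cfg <- trees[[t]]$configurations[[idx[r, t]]]
      lab <- attr(cfg, "transmitter")
      if (is.null(lab)) as.character(idx[r, t]) else lab
    }, character(1))
    rows[[r]] <- data.frame(
      label = paste0("K", paste(idx[r, ], collapse = "")),
      configuration = paste(labels, collapse = " x "),
      k_hat = est$k_hat, variance = est$variance,
      ci_lower = est$ci[1], ci_upper = est$ci[2],
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, rows)
  w <- 1 / per$variance
  per$weight <- w / sum(w)
  k_hat <- sum(per$weight * per$k_hat)
  ci <- c(sum(per$weight * per$ci_lower), sum(per$weight * per$ci_upper))
  # combined uncertainty of the inverse-variance weighted mean
  var_comb <- 1 / sum(w)
  new_pen_fit(k_hat, ci, level, var_comb,
              formula = if (counts_empty(common)) NULL
                        else likelihood_formula(common, mz_prob),
              per_configuration = per, counts = common,
              options = list(level = level, mz_prob = mz_prob,
                             interval = interval, variance = variance))
}
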