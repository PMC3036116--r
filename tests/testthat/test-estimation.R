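test_that("binomial-only decompositions recover Beta conjugate closed forms", {
  for (a in 0:6) {
    for (b in 0:6) {
      cnt <- structure_counts(a, b, 0)
      if (a + b > 0) {
        expect_equal(suppressWarnings(penetrance_mle(cnt)), a / (a + b),
                     tolerance = 1e-6)
        ci <- credibility_interval(cnt, 0.95)
        v <- posterior_variance(cnt)
      } else {
        ci <- credibility_interval(cnt, 0.95, allow_flat = TRUE)
        v <- posterior_variance(cnt, allow_flat = TRUE)
      }
      expect_equal(ci, stats::qbeta(c(0.025, 0.975), a + 1, b + 1),
                   tolerance = 1e-6)
      beta_var <- (a + 1) * (b + 1) / ((a + b + 2)^2 * (a + b + 3))
      expect_equal(v, beta_var, tolerance = 1e-6)
    }
  }
})

test_that("closed-form interval cases invert exactly", {
  # posterior ~ K, CDF = K^2
  expect_equal(credibility_interval(structure_counts(1, 0, 0)),
               c(sqrt(0.025), sqrt(0.975)), tolerance = 1e-6)
  # uniform posterior
  expect_equal(credibility_interval(structure_counts(0, 0, 0),
                                    allow_flat = TRUE),
               c(0.025, 0.975), tolerance = 1e-9)
  expect_equal(posterior_variance(structure_counts(0, 0, 0),
                                  allow_flat = TRUE), 1 / 12,
               tolerance = 1e-9)
})

test_that("MLE handles boundaries and degenerate input", {
  expect_equal(penetrance_mle(structure_counts(3, 4, 0)), 3 / 7,
               tolerance = 1e-6)
  expect_warning(k0 <- penetrance_mle(structure_counts(0, 5, 2)),
                 "boundary")
  expect_equal(k0, 0)
  expect_warning(k1 <- penetrance_mle(structure_counts(4, 0, 0)), "boundary")
  expect_equal(k1, 1)
  expect_error(penetrance_mle(structure_counts(0, 0, 0)), "identifiable")
})

test_that("a near point-mass posterior has vanishing variance", {
  v <- posterior_variance(structure_counts(1e4, 1e4, 0))
  expect_lt(v, 1e-4)
  expect_gt(v, 0)
})

test_that("intervals contain the posterior median and tighten with information", {
  models <- list(
    structure_counts(3, 4, 2, trees = list(two_gen_tree(2))),
    structure_counts(2, 1, 0, twins = c(1, 1, 0)),
    structure_counts(5, 1, 3)
  )
  for (cnt in models) {
    post <- penetrance:::posterior_setup(cnt)
    med <- penetrance:::posterior_quantile(post, 0.5)
    ci <- credibility_interval(cnt)
    expect_true(ci[1] <= med && med <= ci[2])
  }
  # width non-increasing when counts scale up proportionally
  widths <- vapply(c(1L, 2L, 4L), function(s) {
    cnt <- structure_counts(3L * s, 4L * s, 2L * s,
                           trees = rep(list(two_gen_tree(2)), s))
    diff(credibility_interval(cnt))
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("the HPD interval is the shortest interval at its level", {
  cnt <- structure_counts(2, 7, 1)
  et <- credibility_interval(cnt, type = "equal_tailed")
  hpd <- credibility_interval(cnt, type = "hpd")
  expect_lte(diff(hpd), diff(et) + 1e-6)
  post <- penetrance:::posterior_setup(cnt)
  expect_equal(post$cdf(hpd[2]) - post$cdf(hpd[1]), 0.95, tolerance = 1e-4)
  # density equal at both ends for an interior-mode posterior
  expect_equal(post$density(hpd[1]), post$density(hpd[2]), tolerance = 1e-2)
})

test_that("observed-information variance approaches the posterior variance", {
  cnt <- structure_counts(120, 80, 0)
  v_post <- posterior_variance(cnt, convention = "posterior")
  v_info <- posterior_variance(cnt, convention = "information")
  expect_equal(v_info, v_post, tolerance = 0.1)
})

test_that("configuration combination reduces, weighs and commutes correctly", {
  common <- structure_counts(1, 1, 0)
  cfg <- function(a, b) structure_counts(a, b, 0)
  # one tree, one configuration: identical to plain estimation on the merge
  one <- list(list(configurations = list(cfg(2, 3))))
  fit1 <- combine_configurations(common, one)
  merged <- penetrance:::merge_counts(common, cfg(2, 3))
  plain <- estimate_penetrance(merged)
  expect_equal(fit1$k_hat, plain$k_hat, tolerance = 1e-9)
  expect_equal(c(fit1$ci_lower, fit1$ci_upper),
               c(plain$ci_lower, plain$ci_upper), tolerance = 1e-9)

  # two symmetric configurations with equal variances average their K's
  sym <- list(list(configurations = list(cfg(3, 1), cfg(1, 3))))
  fit2 <- combine_configurations(structure_counts(0, 0, 0), sym)
  pc <- fit2$per_configuration
  expect_equal(pc$variance[1], pc$variance[2], tolerance = 1e-9)
  expect_equal(fit2$k_hat, mean(pc$k_hat), tolerance = 1e-9)

  # the combined estimate is the inverse-variance weighted mean
  w <- 1 / pc$variance
  expect_equal(fit2$k_hat, sum(w * pc$k_hat) / sum(w), tolerance = 1e-12)
  expect_equal(fit2$ci_lower, sum(w * pc$ci_lower) / sum(w),
               tolerance = 1e-12)

  # invariance to the ordering of trees and of configurations
  two <- list(list(configurations = list(cfg(2, 3), cfg(3, 2))),
              list(configurations = list(cfg(1, 2), cfg(0, 4))))
  fit_a <- combine_configurations(common, two)
  fit_b <- combine_configurations(common, rev(two))
  flipped <- lapply(two, function(t) list(configurations = rev(t$configurations)))
  fit_c <- combine_configurations(common, flipped)
  for (f in list(fit_b, fit_c)) {
    expect_equal(fit_a$k_hat, f$k_hat, tolerance = 1e-9)
    expect_equal(c(fit_a$ci_lower, fit_a$ci_upper),
                 c(f$ci_lower, f$ci_upper), tolerance = 1e-9)
  }
  expect_equal(nrow(fit_a$per_configuration), 4L)
})

test_that("estimating from counts with configuration blocks matches direct combination", {
  f <- withr::local_tempfile()
  writeLines(c("1,2,0", "1,2", "0", "0", "0", "0,0,0", "1",
               "2", "1,2,1;1;0,0,0", "1,3,2;;0,0,0"), f)
  cnt <- read_structure_counts(f)
  fit <- estimate_penetrance(cnt)
  expect_equal(nrow(fit$per_configuration), 2L)
  common <- structure_counts(1, 2, 0, trees = list(two_gen_tree(2)))
  direct <- combine_configurations(common, cnt$consanguineous)
  expect_equal(fit$k_hat, direct$k_hat, tolerance = 1e-12)
})
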