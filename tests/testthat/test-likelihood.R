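test_that("the childless-normal factor enumerates correctly", {
  c1 <- structure_counts(0, 0, 1)
  expect_equal(log_likelihood(c1, 0), 0)            # allele never expressed
  expect_equal(log_likelihood(c1, 1), log(1 / 2))   # only the aa half remains
  expect_equal(log_likelihood(c1, 0.6), log(0.7))   # 1/2 + (1 - 0.6)/2
})

test_that("boundary penetrance gives -Inf log-likelihood, not an error", {
  expect_identical(log_likelihood(structure_counts(2, 0, 0), 0), -Inf)
  expect_identical(log_likelihood(structure_counts(0, 3, 0), 1), -Inf)
  expect_identical(log_likelihood(structure_counts(0, 0, 0), c(0, .5, 1)),
                   c(0, 0, 0))
})

test_that("tree recursion matches its closed form and its extremes", {
  ks <- seq(0, 1, by = 0.05)
  for (n in 1:5) {
    closed <- 0.5 * (1 + (1 - ks) * ((2 - ks) / 2)^n)
    expect_equal(tree_term(two_gen_tree(n), ks), closed, tolerance = 1e-14)
  }
  for (tr in tree_catalogue()) {
    expect_equal(tree_term(tr, 0), 1)     # allele never expressed
    expect_equal(tree_term(tr, 1), 0.5)   # root must be a non-carrier
  }
  expect_equal(tree_term(two_gen_tree(2), 0.5), 0.640625)
})

test_that("every tree term matches brute-force genotype enumeration", {
  ks <- seq(0, 1, by = 0.1)
  for (tr in tree_catalogue()) {
    got <- tree_term(tr, ks)
    want <- vapply(ks, function(k) oracle_tree_prob(tr, k), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("twin-class terms match enumeration and conserve probability", {
  classes <- c("both_normal", "discordant", "both_affected")
  for (m in c(0, 0.5, 1)) {
    for (k in seq(0, 1, by = 0.1)) {
      want <- oracle_twin_probs(k, m)
      got <- vapply(classes, twin_term, numeric(1), k = k, mz_prob = m)
      expect_equal(unname(got), unname(want[classes]), tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-12)
    }
  }
  expect_equal(twin_term("both_normal", 0, 0.3), 1)
  expect_equal(twin_term("both_affected", 1, 0.5), 0.375)
})

test_that("the example pedigree log-likelihood assembles from its parts", {
  cnt <- extract_structures(make_fixture("fig1"))
  t2 <- 0.5 * (1 + 0.5 * 0.75^2)   # 0.640625
  t3 <- 0.5 * (1 + 0.5 * 0.75^3)   # 0.60546875
  want <- 3 * log(0.5) + 4 * log(0.5) + 2 * log(0.75) + log(t2) + log(t3)
  expect_equal(log_likelihood(cnt, 0.5), want, tolerance = 1e-14)
})

test_that("with no affected individuals the likelihood decreases in K", {
  cnt <- structure_counts(0, 2, 3, trees = list(two_gen_tree(2)),
                          twins = c(1, 0, 0))
  ks <- seq(0, 1, by = 0.01)
  ll <- log_likelihood(cnt, ks)
  expect_true(all(diff(ll) <= 1e-12))
})

test_that("the likelihood formula renders the classical display", {
  cnt <- extract_structures(make_fixture("fig1"))
  expect_equal(
    likelihood_formula(cnt),
    paste("K^3 * (1-K)^4 * ((2-K)/2)^2 *",
          "[1/2 + (1-K)/2*((2-K)/2)^2] * [1/2 + (1-K)/2*((2-K)/2)^3]")
  )
  expect_equal(likelihood_formula(structure_counts(0, 0, 0)), "1")
})

test_that("the filtered likelihood equals the full-pedigree likelihood", {
  # ratio test: decomposition and exhaustive genotype enumeration may differ
  # only by a K-independent constant
  set.seed(42)
  tested <- 0
  while (tested < 8) {
    topo <- random_topology(generations = 3, sibship_mean = 2)
    if (nrow(topo$individuals) > 15) next
    ped <- gene_drop(topo, 0.6, n = 1)[[1]]
    if (!any(ped$individuals$phenotype == "affected")) next
    cnt <- extract_structures(ped)
    for (pair in list(c(0.3, 0.7), c(0.2, 0.9), c(0.55, 0.8))) {
      d_pkg <- log_likelihood(cnt, pair[1]) - log_likelihood(cnt, pair[2])
      d_ora <- oracle_pedigree_ll(ped, pair[1]) -
        oracle_pedigree_ll(ped, pair[2])
      expect_equal(d_pkg, d_ora, tolerance = 1e-10)
    }
    tested <- tested + 1
  }
})

test_that("weinberg rule estimates the monozygotic fraction", {
  expect_equal(weinberg_mz_prob(30, 10), 2 / 3)
  expect_equal(weinberg_mz_prob(10, 15), 0)  # clamped
})
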