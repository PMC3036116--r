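test_that("the example pedigree filters into its published decomposition", {
  ped <- make_fixture("fig1")
  obl <- identify_obligate_carriers(ped)
  phe <- ped$individuals$phenotype[match(obl, ped$individuals$id)]
  expect_setequal(obl[phe == "normal"], c("I-1", "II-1", "II-3", "III-1"))
  expect_setequal(obl[phe == "affected"], c("II-4", "III-4", "IV-1"))

  cnt <- extract_structures(ped)
  expect_equal(cnt$n_affected, 3L)
  expect_equal(cnt$n_obligate, 4L)
  expect_equal(cnt$n_childless, 2L)
  expect_setequal(vapply(cnt$trees, penetrance:::tree_to_string,
                         character(1)), c("2", "3"))
  expect_equal(sum(cnt$twins), 0L)
  cl <- attr(cnt, "classification")
  expect_setequal(cl$id[cl$class == "childless"], c("II-5", "II-6"))
  # married-in spouses are absent from the filtered pedigree
  expect_false(any(c("I-2", "II-7", "II-8", "II-9", "III-6", "III-7") %in%
                     cl$id))
})

test_that("obligate-carrier inference covers the degenerate cases", {
  # single affected founder, nothing else affected
  ped <- quick_ped(
    list("F", NA, NA, "male", "affected"),
    list("M", NA, NA, "female", "normal"),
    list("C", "F", "M", "male", "normal")
  )
  expect_setequal(c(identify_obligate_carriers(ped)), "F")

  # affected grandparent, normal middle parent, affected grandchild
  ped <- quick_ped(
    list("GP", NA, NA, "male", "affected"),
    list("GM", NA, NA, "female", "normal"),
    list("P", "GP", "GM", "female", "normal"),
    list("S", NA, NA, "male", "normal"),
    list("GC", "S", "P", "male", "affected")
  )
  obl <- identify_obligate_carriers(ped)
  expect_true("P" %in% obl)
  cnt <- extract_structures(ped)
  expect_equal(cnt$n_obligate, 1L)
  expect_equal(cnt$n_affected, 2L)

  # no affected individuals: nothing to estimate
  ped <- quick_ped(list("F", NA, NA, "male", "normal"),
                   list("M", NA, NA, "female", "normal"))
  expect_error(identify_obligate_carriers(ped), "nothing to estimate")

  # affected siblings under normal undesignated founders: must designate
  ped <- quick_ped(
    list("F", NA, NA, "male", "normal"),
    list("M", NA, NA, "female", "normal"),
    list("C1", "F", "M", "male", "affected"),
    list("C2", "F", "M", "female", "affected")
  )
  expect_error(identify_obligate_carriers(ped), "[Dd]esignate")
})

test_that("a chain of normals under a carrier builds one nested tree", {
  ped <- quick_ped(
    list("F", NA, NA, "male", "affected"),
    list("M", NA, NA, "female", "normal"),
    list("N1", "F", "M", "female", "normal"),
    list("S1", NA, NA, "male", "normal"),
    list("N2", "S1", "N1", "female", "normal"),
    list("S2", NA, NA, "male", "normal"),
    list("N3", "S2", "N2", "male", "normal")
  )
  cnt <- extract_structures(ped)
  expect_length(cnt$trees, 1L)
  expect_equal(tree_depth(cnt$trees[[1]]), 3L)
  expect_equal(penetrance:::tree_to_string(cnt$trees[[1]]), "(1)")
  expect_equal(penetrance:::tree_member_ids(cnt$trees[[1]]),
               c("N1", "N2", "N3"))
})

test_that("filtering partitions the informative individuals exactly once", {
  set.seed(31)
  topos <- replicate(40, random_topology(generations = 3, sibship_mean = 2),
                     simplify = FALSE)
  for (topo in topos) {
    ped <- gene_drop(topo, k_true = 0.5, n = 1)[[1]]
    if (!any(ped$individuals$phenotype == "affected")) next
    cnt <- extract_structures(ped)
    cl <- attr(cnt, "classification")
    # every id classified exactly once
    expect_false(anyDuplicated(cl$id) > 0)
    n_struct <- cnt$n_affected + cnt$n_obligate + cnt$n_childless +
      sum(vapply(cnt$trees, tree_size, integer(1))) + 2L * sum(cnt$twins)
    expect_equal(n_struct, nrow(cl))
    # affected individuals are never classified as anything but penetrant
    aff <- ped$individuals$id[ped$individuals$phenotype == "affected"]
    expect_true(all(cl$class[cl$id %in% aff] %in%
                      c("affected", "twin_discordant", "twin_both_affected")))
  }
})

test_that("filtering is invariant under relabeling of individual ids", {
  ped <- make_fixture("fig1")
  df <- ped$individuals
  set.seed(5)
  relabel <- stats::setNames(paste0("x", sample(nrow(df))), df$id)
  df$id <- unname(relabel[df$id])
  df$father <- ifelse(is.na(df$father), NA, unname(relabel[df$father]))
  df$mother <- ifelse(is.na(df$mother), NA, unname(relabel[df$mother]))
  ped2 <- pedigree(df[sample(nrow(df)), ], family_id = "RELAB")
  expect_identical(counts_sig(extract_structures(ped2)),
                   counts_sig(extract_structures(ped)))
})

test_that("unknown phenotypes are excluded with a warning", {
  ped <- quick_ped(
    list("F", NA, NA, "male", "affected"),
    list("M", NA, NA, "female", "normal"),
    list("C1", "F", "M", "male", "unknown"),
    list("C2", "F", "M", "female", "normal")
  )
  expect_warning(cnt <- extract_structures(ped), "unknown")
  expect_equal(cnt$n_childless, 1L)
  expect_false("C1" %in% attr(cnt, "classification")$id)
})

test_that("twin pairs classify into the three classes and enforce their preconditions", {
  twin_ped <- function(ph1, ph2, sex2 = "male") {
    quick_ped(
      list("F", NA, NA, "male", "affected"),
      list("M", NA, NA, "female", "normal"),
      list("T1", "F", "M", "male", ph1, "tw"),
      list("T2", "F", "M", sex2, ph2, "tw")
    )
  }
  expect_equal(extract_structures(twin_ped("normal", "normal"))$twins[["both_normal"]], 1L)
  expect_equal(extract_structures(twin_ped("normal", "affected"))$twins[["discordant"]], 1L)
  expect_equal(extract_structures(twin_ped("affected", "affected"))$twins[["both_affected"]], 1L)
  # the affected member of a discordant pair is counted in the twin class, not in A
  cnt <- extract_structures(twin_ped("normal", "affected"))
  expect_equal(cnt$n_affected, 1L)  # only the founder

  # opposite-sex twins are necessarily dizygotic: ordinary siblings
  cnt <- extract_structures(twin_ped("normal", "normal", sex2 = "female"))
  expect_equal(sum(cnt$twins), 0L)
  expect_equal(cnt$n_childless, 2L)

  # twins not born to an obligate carrier
  ped <- quick_ped(
    list("F", NA, NA, "male", "affected"),
    list("M", NA, NA, "female", "normal"),
    list("U1", NA, NA, "male", "normal"),
    list("U2", NA, NA, "female", "normal"),
    list("T1", "U1", "U2", "male", "normal", "tw"),
    list("T2", "U1", "U2", "male", "normal", "tw")
  )
  expect_error(extract_structures(ped), "obligate carrier")

  # twins with their own offspring are unsupported
  ped <- quick_ped(
    list("F", NA, NA, "male", "affected"),
    list("M", NA, NA, "female", "normal"),
    list("T1", "F", "M", "male", "normal", "tw"),
    list("T2", "F", "M", "male", "normal", "tw"),
    list("S", NA, NA, "female", "normal"),
    list("K", "T1", "S", "male", "normal")
  )
  expect_error(extract_structures(ped), "offspring")
})

test_that("loop detection finds the cousin-marriage loop and nothing else", {
  expect_length(detect_consanguineous_loops(make_fixture("fig1")), 0L)

  loops <- detect_consanguineous_loops(make_fixture("fig5"))
  expect_length(loops, 1L)
  expect_setequal(loops[[1]]$transmitters, c("I-1", "II-2"))
  expect_setequal(loops[[1]]$members,
                  c("I-1", "II-1", "II-2", "III-1", "IV-1", "IV-2"))
  expect_equal(loops[[1]]$join, "III-1")

  # a plain 4-generation descent chain has no loops
  ped <- quick_ped(
    list("F", NA, NA, "male", "affected"),
    list("M", NA, NA, "female", "normal"),
    list("A", "F", "M", "male", "normal"),
    list("AS", NA, NA, "female", "normal"),
    list("B", "A", "AS", "male", "normal"),
    list("BS", NA, NA, "female", "normal"),
    list("C", "B", "BS", "male", "affected")
  )
  expect_length(detect_consanguineous_loops(ped), 0L)
})

test_that("the cousin loop splits into the two published configurations", {
  ped <- make_fixture("fig5")
  loop <- detect_consanguineous_loops(ped)[[1]]
  cfgs <- split_configurations(loop, ped)
  expect_length(cfgs, 2L)
  via <- vapply(cfgs, attr, character(1), "transmitter")
  c1 <- cfgs[[match("II-2", via)]]  # transmission through the married-in line
  c2 <- cfgs[[match("I-1", via)]]
  expect_equal(c(c1$n_affected, c1$n_obligate, c1$n_childless), c(1L, 2L, 1L))
  expect_length(c1$trees, 1L)
  expect_equal(penetrance:::tree_to_string(c1$trees[[1]]), "1")
  expect_setequal(penetrance:::tree_member_ids(c1$trees[[1]]),
                  c("I-1", "II-1"))
  expect_equal(c(c2$n_affected, c2$n_obligate, c2$n_childless), c(1L, 3L, 2L))
  expect_length(c2$trees, 0L)
  # both configurations cover the same member multiset
  m1 <- sort(attr(c1, "classification")$id)
  m2 <- sort(attr(c2, "classification")$id)
  expect_identical(m1, m2)
  expect_identical(m1, loop$members)
})

test_that("a loop whose route is already forced reduces to plain filtering", {
  # both sibling mates have their own affected child, so both lines carry
  # regardless of the loop: nothing to split
  ped <- quick_ped(
    list("O1", NA, NA, "male", "normal", NA, TRUE),
    list("O2", NA, NA, "female", "normal"),
    list("U", "O1", "O2", "male", "normal"),
    list("V", "O1", "O2", "female", "normal"),
    list("US", NA, NA, "female", "normal"),
    list("VS", NA, NA, "male", "normal"),
    list("AU", "U", "US", "male", "affected"),
    list("AV", "VS", "V", "male", "affected"),
    list("J", "U", "V", "male", "normal"),
    list("JS", NA, NA, "female", "normal"),
    list("X", "J", "JS", "male", "affected")
  )
  expect_length(detect_consanguineous_loops(ped), 0L)
  cnt <- extract_structures(ped)
  expect_equal(cnt$n_affected, 3L)
  expect_setequal(attr(cnt, "classification")$id[
    attr(cnt, "classification")$class == "obligate"],
    c("O1", "U", "V", "J"))
})

test_that("extraction on a pedigree with an open loop points to the loop API", {
  expect_error(extract_structures(make_fixture("fig5")), "consanguineous")
})
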