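test_that("support collapsing contracts exactly the weak edges", {
  tr <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)100:1);")
  expect_identical(ape::write.tree(collapse_low_support(tr, 70)),
                   ape::write.tree(tr))

  tr59 <- ape::read.tree(text = "((A:1,B:1)59:1,(C:1,D:1)95:1);")
  col <- collapse_low_support(tr59, 70)
  expect_equal(col$Nnode, 2L)                     # one polytomy created
  expect_setequal(col$tip.label, tr59$tip.label)
  expect_true(mono_oracle(col, c("C", "D")))

  tr0 <- ape::read.tree(text = "(((A,B)0,C)0,(D,E)0);")
  star <- collapse_low_support(tr0, 70)
  expect_equal(star$Nnode, 1L)                    # full collapse to a star
  expect_length(star$tip.label, 5L)
})

test_that("monophyly matches worked examples", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(monophyly_class(tr, c("A", "B"))$classification, "monophyletic")

  tr2 <- ape::read.tree(text = "((A,C),(B,D));")
  r <- monophyly_class(tr2, c("A", "B"),
                       groups = c(A = "Hal", B = "Hal", C = "Bac", D = "Eur"))
  expect_equal(r$classification, "polyphyletic")
  expect_true(all(r$interrupting_labels %in% c("C", "D")))
  expect_length(r$interrupting_labels, 1L)

  expect_error(monophyly_class(tr, c("A", "Z")), "not in tree")
  deg <- monophyly_class(tr, c("A", "B", "C", "D"))
  expect_true(deg$degenerate)
  expect_equal(deg$classification, "monophyletic")
})

test_that("interrupting taxa are the minimal entangled non-focal leaves", {
  tr <- ape::read.tree(text = "((A,(B,C)),(D,E));")
  r <- monophyly_class(tr, c("A", "B"))
  expect_equal(r$interrupting_labels, "C")
})

test_that("monophyly agrees with exhaustive bipartition enumeration", {
  set.seed(101)
  for (i in 1:500) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    k <- sample(2:(n - 1), 1)
    focal <- sample(tr$tip.label, k)
    got <- monophyly_class(tr, focal)$classification == "monophyletic"
    expect_identical(got, mono_oracle(tr, focal),
                     info = paste(ape::write.tree(tr), paste(focal, collapse = ",")))
  }
})

test_that("polytomies are treated permissively", {
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  expect_equal(monophyly_class(star, c("A", "B"))$classification,
               "monophyletic")
  part <- ape::read.tree(text = "((A,B,C),(D,E));")
  expect_equal(monophyly_class(part, c("A", "B"))$classification,
               "monophyletic")
})

test_that("Fitch counts match worked examples and brute force", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_events(tr, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_equal(fitch_events(tr, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_equal(fitch_events(tr, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  expect_error(fitch_events(tr, c(A = 1)), "fewer than 2")
  expect_error(fitch_events(tr, c(A = 1, B = 2, C = 0, D = 0)), "0 or 1")

  set.seed(55)
  for (i in 1:150) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    chr <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    expect_equal(fitch_events(tr, chr), fitch_brute(tr, chr))
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(56)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    tr <- ape::rtree(n)
    chr <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    dat <- phangorn::phyDat(matrix(chr, ncol = 1,
                                   dimnames = list(names(chr), NULL)),
                            type = "USER", levels = c(0, 1))
    expect_equal(fitch_events(tr, chr),
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("Fitch and monophyly are invariant under rerooting", {
  set.seed(57)
  for (i in 1:40) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    chr <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    focal <- sample(tr$tip.label, sample(2:(n - 1), 1))
    out <- sample(tr$tip.label, 1)
    rr <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    expect_equal(fitch_events(tr, chr), fitch_events(rr, chr))
    expect_equal(monophyly_class(tr, focal)$classification,
                 monophyly_class(rr, focal)$classification)
    # and under leaf-order permutation of the focal vector
    expect_equal(monophyly_class(tr, sample(focal))$classification,
                 monophyly_class(tr, focal)$classification)
  }
})

test_that("missing leaves are pruned before parsimony counting", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  chr <- c(A = 1, B = NA, C = 0, D = 1, E = NA)
  expect_equal(fitch_events(tr, chr), fitch_events(ape::keep.tip(
    tr, c("A", "C", "D")), c(A = 1, C = 0, D = 1)))
})

test_that("collapsing weak support preserves leaves and drops only weak splits", {
  set.seed(58)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n)
    tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
    col <- collapse_low_support(tr, 70)
    expect_setequal(col$tip.label, tr$tip.label)
    # exactly the weakly supported internal edges disappear
    weak <- sum(as.numeric(tr$node.label[-1]) < 70)
    expect_equal(col$Nnode, tr$Nnode - weak)
    # every retained split keeps its support label
    if (!is.null(col$node.label))
      expect_true(all(col$node.label[col$node.label != ""] %in%
                        tr$node.label))
    # a focal set that was monophyletic stays monophyletic after collapsing
    # (polytomies are read permissively)
    clade <- ape::extract.clade(tr, n + 2)$tip.label
    if (length(clade) >= 2 && length(clade) < n)
      expect_equal(monophyly_class(col, clade)$classification,
                   monophyly_class(tr, clade)$classification)
  }
})

test_that("vertical compatibility separates clonal from transferred alleles", {
  # two presences on opposite sides of the root of a balanced 16-leaf tree
  tr <- ape::stree(16, type = "balanced")
  tr$tip.label <- paste0("g", 1:16)
  st <- matrix("ABSENT", 16, 1, dimnames = list(tr$tip.label, "al1"))
  st["g1", 1] <- "LARGE"
  st["g16", 1] <- "MINI"
  vc <- vertical_compatibility(tr, allele_profile(st))
  expect_equal(unname(vc$events), 2L)
  expect_false(vc$compatible[["al1"]])

  # an allele confined to one clade is compatible
  st2 <- st
  st2[, 1] <- c(rep("LARGE", 8), rep("ABSENT", 8))
  vc2 <- vertical_compatibility(tr, allele_profile(st2))
  expect_true(vc2$compatible[["al1"]])
})

test_that("shared allele counts follow strict and lenient semantics", {
  prof <- profile_from_sets(list(g1 = c("a1", "a2", "a3"),
                                 g2 = c("a2", "a3", "a4"),
                                 g3 = "a3"),
                            paste0("a", 1:5))
  expect_equal(shared_alleles(prof, c("g1", "g2", "g3")), 1L)
  expect_equal(shared_alleles(prof, c("g1", "g2")), 2L)

  ident <- profile_from_sets(list(g1 = paste0("a", 1:5),
                                  g2 = paste0("a", 1:5)), paste0("a", 1:5))
  expect_equal(shared_alleles(ident, c("g1", "g2")), 5L)

  disj <- profile_from_sets(list(g1 = c("a1", "a2"), g2 = c("a3", "a4")),
                            paste0("a", 1:4))
  expect_equal(shared_alleles(disj, c("g1", "g2")), 0L)

  # MISSING disqualifies in strict mode but not in lenient mode
  st <- matrix(c("LARGE", "MISSING"), 2, 1,
               dimnames = list(c("g1", "g2"), "a1"))
  p <- allele_profile(st)
  expect_equal(shared_alleles(p, c("g1", "g2"), strict = TRUE), 0L)
  expect_equal(shared_alleles(p, c("g1", "g2"), strict = FALSE), 1L)
  expect_error(shared_alleles(p, "g1"), "two members")
  expect_error(shared_alleles(p, c("g1", "zz")), "unknown")
})
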