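# Enumeration, canonical form, newick serialization, random generators.

test_that("enumeration counts match the Wedderburn-Etherington recurrence", {
  we <- o_we(17)
  for (l in c(1:12, 17))
    expect_identical(nShapes(c_space(l)), as.integer(we[l]),
                     info = paste("l =", l))
  # spot values: 11 shapes on 7 leaves, 46 on 9, 24631 on 17
  expect_identical(nShapes(c_space(7)), 11L)
  expect_identical(nShapes(c_space(9)), 46L)
  expect_identical(nShapes(c_space(17)), 24631L)
  # package's own recurrence agrees with the independent convolution
  expect_equal(wedderburnEtherington(20), o_we(20))
})

test_that("shape counts grow like b^l with b near 2.48", {
  w <- o_we(21)
  # n ~ b^l l^(-3/2)  =>  b ~ (n_{l+1}/n_l) ((l+1)/l)^(3/2)
  for (l in 15:20) {
    b <- w[l + 1] / w[l] * ((l + 1) / l)^1.5
    expect_gt(b, 2.3)
    expect_lt(b, 2.6)
  }
})

test_that("the two shapes on 4 leaves are the caterpillar and the balanced", {
  ks <- shapeKeys(c_space(4))
  expect_setequal(ks, c(canonicalKey(caterpillarShape(4)),
                        canonicalKey(balancedShape(4))))
  expect_identical(nShapes(c_space(1)), 1L)
  expect_identical(shapeKeys(c_space(1)), ";")
})

test_that("enumerateShapes rejects bad leaf counts", {
  expect_error(enumerateShapes(0), "positive integer")
  expect_error(enumerateShapes(2.5), "positive integer")
  expect_error(enumerateShapes(-3), "positive integer")
})

test_that("canonical form is invariant under child reordering", {
  set.seed(42)
  for (l in c(6, 7)) {
    for (shape in o_enumerate(l)[c(1, 3)]) {
      ref <- treeShape(o_newick(shape))
      for (rep in 1:20) {
        scrambled <- o_newick(shape, scramble = TRUE)
        expect_identical(canonicalKey(treeShape(scrambled)),
                         canonicalKey(ref))
      }
    }
  }
  # mirror image of the caterpillar
  expect_identical(canonicalKey(treeShape("(((((( ,),),),),),);")),
                   canonicalKey(caterpillarShape(7)))
  expect_false(canonicalKey(caterpillarShape(7)) ==
                 canonicalKey(balancedShape(7)))
})

test_that("canonical form is idempotent and matches enumeration", {
  ks <- shapeKeys(c_space(7))
  expect_identical(canonicalKey(ks), ks)
})

test_that("labels, branch lengths and whitespace are discarded on parse", {
  expect_identical(canonicalKey(treeShape("((A:1,B:2),(C,D));")),
                   canonicalKey(balancedShape(4)))
  expect_identical(canonicalKey(treeShape("(,( ,(,)));")),
                   canonicalKey(caterpillarShape(4)))
  expect_identical(canonicalKey(treeShape("(a_1:0.5,(b:1e-3,c):2);")),
                   canonicalKey(caterpillarShape(3)))
})

test_that("malformed newick fails with a position", {
  expect_error(treeShape("(a,b,c);"), "multifurcating")
  expect_error(treeShape("((,);"), "position")
  expect_error(treeShape("(,))"), "position")
  err <- tryCatch(treeShape("(a,(b,c,d));"), error = conditionMessage)
  expect_match(err, "position [0-9]+")
})

test_that("phylo round trip preserves the isomorphism class", {
  sp <- c_space(6)
  for (i in seq_len(nShapes(sp))) {
    phy <- shapePhylo(sp[[i]])
    expect_s3_class(phy, "phylo")
    expect_identical(ape::Ntip(phy), 6L)
    expect_identical(canonicalKey(treeShape(phy)), shapeKeys(sp)[i])
  }
})

test_that("newick write/parse round-trips all 46 shapes on 9 leaves", {
  ks <- shapeKeys(c_space(9))
  round <- vapply(ks, function(k) canonicalKey(treeShape(k)), "",
                  USE.NAMES = FALSE)
  expect_identical(round, ks)
  # via file export/import too
  f <- withr::local_tempfile()
  exportShapes(c_space(9), f)
  back <- readShapeFile(f)
  expect_identical(vapply(back, canonicalKey, ""), ks)
})

test_that("Yule shape frequencies at l = 4 match exact probabilities", {
  # P(balanced) = 1/3: the third split hits the cherry-member lineage pair
  # with probability 1/3 after symmetry reduction
  set.seed(101)
  n <- 1e5
  ks <- randomShapeKeys(4, n, "yule")
  p_bal <- mean(ks == canonicalKey(balancedShape(4)))
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(p_bal - 1 / 3), 3 * se)
  expect_setequal(unique(ks), shapeKeys(c_space(4)))
})

test_that("PDA shape frequencies are proportional to labeled topologies", {
  # 15 labeled rooted topologies on 4 tips: 12 caterpillars, 3 balanced
  set.seed(202)
  n <- 1e5
  ks <- randomShapeKeys(4, n, "pda")
  p_bal <- mean(ks == canonicalKey(balancedShape(4)))
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p_bal - 0.2), 3 * se)
})

test_that("random shapes are canonical members of the enumerated space", {
  set.seed(7)
  keys9 <- shapeKeys(c_space(9))
  for (model in c("yule", "pda")) {
    draws <- randomShapeKeys(9, 200, model)
    expect_true(all(draws %in% keys9))
    expect_identical(canonicalKey(draws), draws)
  }
  expect_identical(randomShapeKeys(2, 3, "yule"), rep("(,);", 3))
  expect_identical(canonicalKey(randomShape(2, "pda")), "(,);")
  expect_error(randomShapeKeys(5, 1, "other"), "should be one of")
})

test_that("random draws are reproducible under set.seed", {
  set.seed(33)
  a <- randomShapeKeys(10, 50, "yule")
  set.seed(33)
  b <- randomShapeKeys(10, 50, "yule")
  expect_identical(a, b)
})
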