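# The seven statistics: hand-derived values, an independent recursive
# oracle, and the centered-normalized statistic vectors.

test_that("hand-derived values on reference shapes are reproduced", {
  cat7 <- caterpillarShape(7)
  bal8 <- balancedShape(8)
  cherry <- treeShape("(,);")

  # caterpillar(7): leaf depths 1..6,6; splits (1,6)..(1,2),(1,1)
  expect_equal(collessIndex(cat7), 1)                       # 15 * 2/30
  expect_equal(sackinIndex(cat7), 27 / 7)
  expect_equal(depthVariance(cat7), 127 / 7 - (27 / 7)^2)
  expect_equal(i2Index(cat7), 1)                            # five unit terms
  expect_equal(b1Index(cat7), 1 / 5 + 1 / 4 + 1 / 3 + 1 / 2 + 1)  # 137/60
  expect_equal(b2Index(cat7),
               1 / 2 + 2 / 4 + 3 / 8 + 4 / 16 + 5 / 32 + 6 / 64 + 6 / 64)
  expect_identical(nCherries(cat7), 1L)

  # balanced(8) is the perfect binary tree of depth 3
  expect_equal(collessIndex(bal8), 0)
  expect_equal(sackinIndex(bal8), 3)
  expect_equal(depthVariance(bal8), 0)
  expect_equal(i2Index(bal8), 0)
  expect_equal(b1Index(bal8), 2 * (1 / 2) + 4 * 1)
  expect_equal(b2Index(bal8), 8 * 3 / 2^3)
  expect_identical(nCherries(bal8), 4L)

  expect_equal(sackinIndex(cherry), 1)
  expect_equal(depthVariance(cherry), 0)
  expect_equal(b1Index(cherry), 0)      # no non-root internal node
  expect_equal(b2Index(cherry), 1)

  # 4-leaf shapes: depths of the caterpillar are 1,2,3,3
  expect_equal(collessIndex(caterpillarShape(4)), 1)
  expect_equal(collessIndex(balancedShape(4)), 0)
  expect_equal(b2Index(caterpillarShape(4)), 1 / 2 + 2 / 4 + 2 * (3 / 8))
  # both the (1,3) root and the (1,2) node qualify for I2
  expect_equal(i2Index(caterpillarShape(4)), 1)

  expect_identical(nCherries(treeShape("((,),((,),(,)));")), 3L)
})

test_that("statistics need enough leaves for their normalizers", {
  expect_error(collessIndex(treeShape("(,);")), "at least 3")
  expect_error(i2Index(treeShape("(,);")), "at least 3")
  expect_equal(sackinIndex(treeShape(";")), 0)
})

test_that("all statistics match an independent recursive oracle", {
  for (l in 7:8) {
    sp <- c_space(l)
    got <- shapeStatistics(sp)
    for (i in seq_len(nShapes(sp))) {
      want <- o_stats(o_parse(shapeKeys(sp)[i]))
      expect_equal(unlist(got[i, names(want)]), want,
                   tolerance = 1e-12, ignore_attr = TRUE,
                   info = paste("l =", l, "shape", i))
    }
  }
})

test_that("aggregate scale is the unnormalized printed scale", {
  sp <- c_space(8)
  pr <- shapeStatistics(sp, "printed")
  ag <- shapeStatistics(sp, "aggregate")
  expect_equal(ag$colless, pr$colless * (7 * 6) / 2)
  expect_equal(ag$sackin, pr$sackin * 8)
  expect_equal(ag$sigma2, pr$sigma2 * 8)
  expect_equal(ag$i2, pr$i2 * 6)
  expect_equal(ag$b1, pr$b1)
  expect_equal(ag$b2, pr$b2)
})

test_that("statistic vectors are centered, unit-norm and affine-invariant", {
  sp <- c_space(9)
  for (st in c("colless", "sackin", "b2")) {
    sv <- statisticVector(sp, st)
    expect_equal(sum(sv@centered), 0, tolerance = 1e-12)
    expect_equal(sum(sv@centered^2), 1, tolerance = 1e-12)
    # y -> a*y + c leaves x unchanged (a > 0); a < 0 flips the sign
    expect_equal(centerUnit(3 * sv@values + 5), sv@centered)
    expect_equal(centerUnit(-2 * sv@values + 1), -sv@centered)
  }
})

test_that("a constant statistic is rejected as degenerate", {
  sp1 <- enumerateShapes(3)   # a single shape: everything is constant
  expect_error(statisticVector(sp1, "sackin"), "constant over the shape space")
  expect_error(centerUnit(rep(2, 10)), "constant")
})

test_that("colless and i2 are extremal where they should be", {
  # colless: max at the caterpillar, min at the maximally balanced shape.
  # i2: max at the caterpillar (all qualifying terms equal 1); its minimum
  # is NOT in general the balanced shape -- at l = 5 the shape
  # (leaf, balanced(4)) scores 1/3 against the balanced shape's 4/9.
  for (l in 5:10) {
    sp <- c_space(l)
    ks <- shapeKeys(sp)
    i_cat <- match(canonicalKey(caterpillarShape(l)), ks)
    i_bal <- match(canonicalKey(balancedShape(l)), ks)
    for (st in c("colless", "i2"))
      expect_identical(which.max(statisticVector(sp, st)@values), i_cat,
                       info = paste(st, l))
    expect_identical(which.min(statisticVector(sp, "colless")@values), i_bal,
                     info = paste("colless", l))
  }
  y5 <- statisticVector(c_space(5), "i2")@values
  i_lb4 <- match(canonicalKey(treeShape("(,((,),(,)));")), shapeKeys(c_space(5)))
  expect_identical(which.min(y5), i_lb4)
  expect_equal(min(y5), 1 / 3)
})

test_that("colless attains 1 once per space and 0 only at powers of two", {
  # colless = 0 needs every split exactly even, which forces l = 2^k;
  # at l = 7 the minimum is positive and unique (the balanced shape)
  y7 <- statisticVector(c_space(7), "colless")@values
  expect_identical(sum(y7 == 1), 1L)
  expect_identical(sum(y7 == 0), 0L)
  expect_identical(sum(y7 == min(y7)), 1L)
  y8 <- statisticVector(c_space(8), "colless")@values
  expect_identical(sum(y8 == 0), 1L)
  expect_identical(sum(y8 == 1), 1L)
})

test_that("the Saless index combines Sackin and Colless linearly", {
  expect_equal(salessIndex(caterpillarShape(7), 1), 27 / 7 + 1)
  expect_equal(salessIndex(balancedShape(8), 2), 6)
  sp <- c_space(7)
  expect_equal(salessIndex(sp, 0), statisticVector(sp, "colless")@values)
  expect_equal(salessIndex(sp, 1.5, scale = "aggregate"),
               1.5 * statisticVector(sp, "sackin", "aggregate")@values +
                 statisticVector(sp, "colless", "aggregate")@values)
  expect_error(salessIndex(treeShape("(,);"), 1), "at least 3")
  expect_error(salessIndex(caterpillarShape(5), Inf), "finite")
})
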