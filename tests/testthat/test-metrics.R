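test_that("hand-evaluated index values are reproduced", {
  expect_equal(sorensen2(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_equal(sorensen2(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(sorensen2(c(1, 1, 0), c(0, 0, 1)), 0)
  # counts binarize first: (0,1,7) acts as (0,1,1)
  expect_equal(sorensen2(c(0, 1, 7), c(5, 1, 0)), 0.5)

  expect_equal(sorensen3(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)), 0.75)
  expect_equal(sorensen3(c(1, 1), c(1, 1), c(1, 1)), 1)
  expect_equal(sorensen3(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 0)

  expect_equal(czekanowski2(c(2, 0, 1), c(1, 1, 0)), 0.4)
  expect_equal(czekanowski2(c(2, 5), c(2, 5)), 1)

  expect_equal(czekanowski3(c(2, 0, 1), c(1, 1, 0), c(0, 2, 1)), 0.5625)
  expect_equal(czekanowski3(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)), 0.75)
  expect_equal(czekanowski3(c(3, 1), c(3, 1), c(3, 1)), 1)
})

test_that("length mismatches and negative entries are rejected", {
  expect_error(sorensen2(c(1, 0), c(1, 0, 1)), "mismatch")
  expect_error(sorensen3(c(1, 0), c(1, 0), c(1, 0, 1)), "mismatch")
  expect_error(czekanowski2(c(1, -1), c(1, 0)), "non-negative")
})

test_that("empty profiles give similarity 0, not NaN", {
  z <- c(0, 0, 0)
  expect_identical(sorensen2(z, z), 0)
  expect_identical(sorensen3(z, z, z), 0)
  expect_identical(czekanowski2(z, z), 0)
  expect_identical(czekanowski3(z, z, z), 0)
})

test_that("all indices stay in [0, 1] and triplet forms are permutation-invariant", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      x <- sample(0:5, 6, replace = TRUE)
      y <- sample(0:5, 6, replace = TRUE)
      z <- sample(0:5, 6, replace = TRUE)
      vals <- c(sorensen2(x, y), czekanowski2(x, y),
                sorensen3(x, y, z), czekanowski3(x, y, z))
      expect_true(all(vals >= 0 & vals <= 1))
      perms <- list(list(x, y, z), list(x, z, y), list(y, x, z),
                    list(y, z, x), list(z, x, y), list(z, y, x))
      s3 <- vapply(perms, function(p) do.call(sorensen3, p), numeric(1))
      c3 <- vapply(perms, function(p) do.call(czekanowski3, p), numeric(1))
      expect_equal(max(s3) - min(s3), 0)
      expect_equal(max(c3) - min(c3), 0)
      expect_equal(sorensen2(x, y), sorensen2(y, x))
    }
  })
})

test_that("on binary inputs the Czekanowski indices reduce to Sorensen", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      x <- sample(0:1, 10, replace = TRUE)
      y <- sample(0:1, 10, replace = TRUE)
      z <- sample(0:1, 10, replace = TRUE)
      expect_lt(abs(czekanowski2(x, y) - sorensen2(x, y)), 1e-12)
      expect_lt(abs(czekanowski3(x, y, z) - sorensen3(x, y, z)), 1e-12)
    }
  })
})

test_that("triplets with empty three-way intersection never exceed 3/4", {
  # Sorensen: exhaustive over all binary triples on a 4-family universe
  subsets <- as.matrix(expand.grid(rep(list(0:1), 4)))
  vals <- c()
  for (i in seq_len(nrow(subsets))) {
    for (j in seq_len(nrow(subsets))) {
      for (k in seq_len(nrow(subsets))) {
        if (sum(subsets[i, ] & subsets[j, ] & subsets[k, ]) == 0) {
          vals <- c(vals, sorensen3(subsets[i, ], subsets[j, ], subsets[k, ]))
        }
      }
    }
  }
  expect_equal(max(vals), 0.75)
  # Czekanowski: randomized with the triple minimum forced to zero
  withr::with_seed(21, {
    for (rep in 1:500) {
      x <- sample(0:5, 6, replace = TRUE)
      y <- sample(0:5, 6, replace = TRUE)
      z <- sample(0:5, 6, replace = TRUE)
      kill <- sample(1:3, 6, replace = TRUE)
      x[kill == 1] <- 0; y[kill == 2] <- 0; z[kill == 3] <- 0
      expect_lte(czekanowski3(x, y, z), 0.75)
    }
  })
})

test_that("the pairwise-minima bound behind the Czekanowski theorem holds", {
  withr::with_seed(5, {
    a <- sample(0:20, 2000, replace = TRUE)
    b <- sample(0:20, 2000, replace = TRUE)
    c_ <- sample(0:20, 2000, replace = TRUE)
    lhs <- pmin(a, b) + pmin(a, c_) - pmin(a, pmin(b, c_))
    expect_true(all(lhs <= a))
  })
})

test_that("a family shared by all three species never lowers the triplet index", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      x <- sample(0:3, 5, replace = TRUE)
      y <- sample(0:3, 5, replace = TRUE)
      z <- sample(0:3, 5, replace = TRUE)
      expect_gte(sorensen3(c(x, 1), c(y, 1), c(z, 1)), sorensen3(x, y, z))
    }
  })
})

test_that("reciprocal E-value scores follow the configured convention", {
  expect_equal(tribemcl_pair_score(1e-5, 1e-5), 5)
  expect_equal(tribemcl_pair_score(1, 1), 0)
  expect_equal(tribemcl_pair_score(1e-3, 1e-7),
               tribemcl_pair_score(1e-7, 1e-3))
  # underflowed E-values clamp at the ceiling instead of overflowing
  expect_equal(tribemcl_pair_score(0, 0), 200)
  expect_equal(tribemcl_pair_score(0, 0, ceiling = 50), 50)
  expect_lte(tribemcl_pair_score(1e-300, 0), 200)
  expect_equal(tribemcl_pair_score(0.25, 0.25, convention = "log2_mean"), -2)
  expect_error(tribemcl_pair_score(-1e-5, 1e-5), "non-negative")
})
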