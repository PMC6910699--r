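# numeric rank decisions, Jacobians, clustering

test_that("jacobian_at differentiates exactly", {
  id5 <- coefficient_map(paste0("p", 1:5), paste0("p", 1:5), "id5")
  set.seed(3)
  z <- rand_complex(5)
  expect_equal(jacobian_at(id5, z), diag(5) + 0i)

  prod2 <- coefficient_map("p1*p2", c("p1", "p2"), "prod")
  expect_equal(jacobian_at(prod2, c(2 + 0i, 3 + 0i)),
               matrix(c(3 + 0i, 2 + 0i), 1, 2))

  ex3 <- coefficient_fixture("linear3_c")
  J <- jacobian_at(ex3, rand_complex(7))
  expect_equal(dim(J), c(5L, 7L))
})

test_that("numeric_corank thresholds singular values correctly", {
  expect_equal(numeric_corank(matrix(0 + 0i, 3, 4), 0L)$corank, 4L)

  # full-rank matrix built from random unitary factors with unit singular values
  set.seed(9)
  q1 <- qr.Q(qr(matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5)))
  q2 <- qr.Q(qr(matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5)))
  M <- q1 %*% Conj(t(q2))
  expect_equal(numeric_corank(M, 0L)$corank, 0L)
  # scaling by a nonzero constant leaves the rank unchanged
  expect_equal(numeric_corank(M * (1e-7 + 3i), 0L)$rank,
               numeric_corank(M, 0L)$rank)

  # published coranks of the order-zero all-leak compartment jet system
  set.seed(10)
  js <- truncate_model(fixture("linear3"), 0)
  pt <- seed_point(js)
  J <- identikit:::jet_jacobian(js, pt$assignment)[, c(js$p_cols, js$x_cols)]
  expect_equal(numeric_corank(J, 0L)$corank, 9L)
  expect_equal(numeric_corank(J, 7L)$corank, 2L)
})

test_that("column-offset coranks respect column-count bookkeeping", {
  set.seed(21)
  for (rep in 1:5) {
    M <- matrix(rand_complex(6 * 8), 6, 8)
    M[, 1] <- M[, 2]  # introduce collinearity
    c0 <- numeric_corank(M, 0L)$corank
    for (j in c(1L, 3L, 5L)) {
      cj <- numeric_corank(M, j)$corank
      expect_gte(c0, cj - j)
    }
  }
})

test_that("corank of jet systems is stable across generic points", {
  set.seed(31)
  for (name in c("linear3", "hiv")) {
    js <- truncate_model(fixture(name), 6)
    cols <- c(js$p_cols, js$x_cols)
    coranks <- replicate(5, {
      pt <- seed_point(js)
      J <- identikit:::jet_jacobian(js, pt$assignment)[, cols]
      numeric_corank(J, 0L, equilibrate = TRUE, method = "gap")$corank
    })
    expect_length(unique(coranks), 1L)
  }
})

test_that("cluster_points groups by relative distance", {
  p <- list(c(1 + 1i, 2), c(1 + 1i, 2), c(5, 5))
  g <- cluster_points(p, 1e-6)
  expect_length(g, 2L)
  expect_equal(g[[1]], c(1L, 2L))

  expect_length(cluster_points(list(0 + 0i, 1 + 0i), 1e-6), 2L)

  # the twelve published parameter vectors group into 3 clusters of 4 by
  # their extended output coordinate
  y8 <- list(0.1706 + 0i, 0.1706 + 0i, 0.1706 + 0i, 0.1706 + 0i,
             0.1107 - 0.404i, 0.1107 + 0.404i, 0.1107 + 0.404i,
             0.1107 - 0.404i, 0.1107 + 0.404i, 0.1107 - 0.404i,
             0.1107 - 0.404i, 0.1107 + 0.404i)
  g <- cluster_points(y8, 1e-6)
  expect_length(g, 3L)
  expect_equal(sort(unname(vapply(g, length, integer(1)))), c(4L, 4L, 4L))
})
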