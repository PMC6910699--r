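# identifiability degree straight from jet systems

test_that("one-state models have the expected jet-side degree", {
  one <- load_model(list(name = "one", states = "x", params = "p",
                         outputs = "y", odes = list(x = "-p*x"),
                         output_exprs = list(y = "x")))
  set.seed(71)
  r1 <- jet_degree(one, 1)
  expect_equal(unname(r1$k), 1L)

  two <- load_model(list(name = "two", states = "x", params = "p",
                         outputs = "y", odes = list(x = "-p^2*x"),
                         output_exprs = list(y = "x")))
  set.seed(72)
  r2 <- jet_degree(two, 1)
  expect_equal(unname(r2$k), 2L)
  expect_equal(r2$n_solutions, 2L)
  # oracle: p^2 = -y1/y0, the two square roots
  p1 <- r2$params[[1]][1]; p2 <- r2$params[[2]][1]
  expect_lt(abs(p1 + p2), 1e-8)
})

test_that("jet-side solutions in one cluster share all output jets", {
  set.seed(73)
  two <- load_model(list(name = "two", states = "x", params = "p",
                         outputs = "y", odes = list(x = "-p^2*x"),
                         output_exprs = list(y = "x")))
  r <- jet_degree(two, 2)
  # both solutions yield the same input-output, so one cluster of two
  expect_equal(unname(r$k), 2L)
  y <- r$y_next
  expect_lt(max(abs(y[[1]] - y[[2]])), 1e-8)
})
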