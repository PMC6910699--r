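# model loading, fixtures, jet systems and seed points

test_that("load_model validates declarations and counts", {
  m <- fixture("linear3")
  expect_s3_class(m, "ik_model")
  expect_length(m$states, 3L)
  expect_length(m$params, 7L)
  expect_length(m$inputs, 1L)
  expect_length(m$outputs, 1L)

  one <- load_model(list(name = "one", states = "x", params = "p",
                         outputs = "y", odes = list(x = "-p*x"),
                         output_exprs = list(y = "x")))
  expect_length(one$states, 1L)
  # both power spellings parse
  two <- load_model(list(name = "two", states = "x", params = "p",
                         outputs = "y", odes = list(x = "-p**2*x"),
                         output_exprs = list(y = "x^1")))
  expect_equal(pl_degree(two$rhs[[1]]$num), 3L)

  expect_error(load_model(list(name = "bad", states = "x", params = "p",
                               outputs = "y", odes = list(x = "-q*x"),
                               output_exprs = list(y = "x"))),
               "q")
  expect_error(fixture("nosuchmodel"), "linear3")
})

test_that("fixtures match the published models", {
  hiv <- fixture("hiv")
  expect_length(hiv$states, 3L)
  expect_length(hiv$params, 5L)
  expect_length(hiv$inputs, 0L)
  # y = x3
  g <- hiv$output_exprs[[1]]$num
  expect_equal(nrow(g$E), 1L)
  expect_equal(which(g$E[1, ] > 0L), 3L)

  fc <- fixture("fourcomp")
  expect_equal(fc$params,
               c("a11", "a12", "a21", "a22", "a23", "a33", "a34", "a42",
                 "a43", "a44"))
  g <- fc$output_exprs[[1]]$num
  expect_equal(which(g$E[1, ] > 0L), 1L)  # y = x1

  mm <- fixture("mapk_mixed")
  expect_length(mm$params, 32L)
  expect_length(mm$states, 12L)
  expect_length(mm$outputs, 4L)
  expect_length(fixture("mapk_6out")$outputs, 6L)
})

test_that("mass-action MAPK equations conserve substrate, kinase and phosphatase", {
  m <- fixture("mapk_6out")
  js <- truncate_model(m, 0)
  set.seed(11)
  pt <- seed_point(js)
  z <- pt$assignment
  # x1 coordinates of the derivative jets
  x1 <- z[js$m1 + js$ns + seq_len(js$ns)]
  names(x1) <- m$states
  # total kinase K + KS00 + KS01 + KS10 is conserved
  expect_lt(abs(x1["K"] + x1["KS00"] + x1["KS01"] + x1["KS10"]), 1e-10)
  # total phosphatase F + FS01 + FS10 + FS11
  expect_lt(abs(x1["F"] + x1["FS01"] + x1["FS10"] + x1["FS11"]), 1e-10)
  # total substrate (all 12 species except free K and F)
  expect_lt(abs(sum(x1) - x1["K"] - x1["F"]), 1e-9)
})

test_that("truncation produces the published block structure", {
  m <- fixture("linear3")
  for (r in c(0L, 3L)) {
    js <- truncate_model(m, r)
    expect_length(js$polys, 4L * (r + 1L))
  }
  expect_equal(truncate_model(m, 8)$N_r, 37L)
  expect_error(truncate_model(m, -1), "r must be")

  one <- load_model(list(name = "one", states = "x", params = "p",
                         outputs = "y", odes = list(x = "p*x"),
                         output_exprs = list(y = "x")))
  js0 <- truncate_model(one, 0)
  # {p*x0 - x1, y0 - x0}
  z <- c(2 + 0i, 3 + 0i, 6 + 0i, 3 + 0i)  # p, x0, x1, y0
  expect_equal(sys_eval(js0, z), c(0 + 0i, 0 + 0i))
  expect_equal(sys_eval(js0, c(2 + 0i, 3 + 0i, 5 + 0i, 4 + 0i)),
               c(1 + 0i, 1 + 0i))
})

test_that("jet systems have the prefix property", {
  for (name in c("linear3", "hiv")) {
    m <- fixture(name)
    a <- truncate_model(m, 2)
    b <- truncate_model(m, 3)
    nv <- a$n
    # map the order-2 variables into the order-3 variable set by name
    map <- match(a$vars, b$vars)
    expect_false(anyNA(map))
    for (i in seq_along(a$polys)) {
      pa <- pl_remap(a$polys[[i]], b$n, map)
      pb <- b$polys[[i]]
      set.seed(5)
      z <- rand_complex(b$n)
      expect_lt(abs(pl_eval(pa, z) - pl_eval(pb, z)), 1e-10)
    }
  }
})

test_that("seed points satisfy the jet equations and honor constraints", {
  set.seed(42)
  for (name in c("linear3", "threecomp", "hiv", "fourcomp")) {
    js <- truncate_model(fixture(name), 7)
    pt <- seed_point(js)
    expect_lt(pt$residual, 1e-10)
  }
  # determinism under a fixed seed
  js <- truncate_model(fixture("linear3"), 5)
  set.seed(7); p1 <- seed_point(js)$assignment
  set.seed(7); p2 <- seed_point(js)$assignment
  expect_identical(p1, p2)
  # constrained third state starts at exactly zero
  mc <- threecomp_constrained()
  jsc <- truncate_model(mc, 3)
  set.seed(8)
  ptc <- seed_point(jsc)
  expect_equal(unname(ptc$assignment[jsc$m1 + 3L]), 0 + 0i)
  expect_lt(ptc$residual, 1e-10)
})

test_that("the all-leak compartment jet Jacobian has full row rank 4(r+1)", {
  m <- fixture("linear3")
  set.seed(12)
  for (r in c(0L, 4L, 8L)) {
    js <- truncate_model(m, r)
    pt <- seed_point(js)
    J <- identikit:::jet_jacobian(js, pt$assignment)
    rk <- numeric_corank(t(J), 0L, equilibrate = TRUE, method = "gap")$rank
    expect_equal(rk, 4L * (r + 1L))
  }
})
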