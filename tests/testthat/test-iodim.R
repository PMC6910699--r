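# coefficient maps and the two dimension methods

test_that("elementary symmetric polynomials match direct enumeration", {
  expect_equal(elementary_symmetric(1, c(1, 2, 3)), 6)
  # E_2(1,2,3) = 1*2 + 1*3 + 2*3
  pairs <- combn(c(1, 2, 3), 2)
  expect_equal(elementary_symmetric(2, c(1, 2, 3)),
               sum(apply(pairs, 2, prod)))
  expect_equal(elementary_symmetric(3, c(1, 2, 3)), 6)
  expect_equal(elementary_symmetric(0, c(4, 5)), 1)
  expect_error(elementary_symmetric(4, c(1, 2, 3)), "out of range")
})

test_that("coefficient fixtures reproduce the published values", {
  cm <- coefficient_fixture("linear3_noleak13_c")
  expect_equal(cmap_eval(cm, c(-1, -2, 5, -1, -3)),
               as.complex(c(-2, -31, 5, -1, -30)))

  fc <- coefficient_fixture("fourcomp_c")
  expect_equal(fc$m1, 10L)
  expect_equal(fc$m2, 7L)

  # first coefficient of the all-leak map is E_1 of the negated column sums
  l3 <- coefficient_fixture("linear3_c")
  p <- rand_complex(7)
  names(p) <- l3$params
  e1 <- elementary_symmetric(1, c(-(p["k01"] + p["k21"]),
                                  -(p["k02"] + p["k12"] + p["k32"]),
                                  -(p["k03"] + p["k13"])))
  expect_lt(abs(cmap_eval(l3, p)[1] - e1), 1e-12)
  expect_error(coefficient_fixture("nope"), "linear3_c")
})

test_that("method 1 computes the fiber dimension from the Jacobian corank", {
  set.seed(41)
  expect_equal(method1_dimension(coefficient_fixture("linear3_c"))$l, 2L)
  expect_equal(method1_dimension(coefficient_fixture("linear3_noleak13_c"))$l, 0L)
  id4 <- coefficient_map(paste0("p", 1:4), paste0("p", 1:4), "id4")
  expect_equal(method1_dimension(id4)$l, 0L)
})

test_that("method 2 reproduces the published dimension tables", {
  set.seed(42)
  t1 <- method2_dimension(fixture("linear3"))
  expect_equal(t1$d_r[1:9], c(7, 7, 7, 6, 5, 4, 3, 2, 2))
  expect_equal(attr(t1, "final_dimension"), 2L)
  expect_equal(t1$N_r, 13L + 3L * t1$r)
  expect_equal(t1$corank0[1:9], c(9, 8, 7, 6, 5, 4, 3, 2, 2))
  expect_equal(t1$corank_m1[1:9], c(2, 1, 0, 0, 0, 0, 0, 0, 0))

  t2 <- method2_dimension(fixture("threecomp"))
  expect_equal(attr(t2, "final_dimension"), 0L)
  expect_equal(t2$d_r[1:6], c(3, 3, 3, 2, 1, 0))

  t3 <- method2_dimension(threecomp_constrained())
  expect_equal(attr(t3, "final_dimension"), 1L)
  expect_equal(t3$d_r[1:5], c(3, 3, 2, 1, 1))
  expect_equal(t3$corank0[1:5], c(4, 3, 2, 1, 1))

  t4 <- method2_dimension(fixture("hiv"))
  expect_equal(attr(t4, "final_dimension"), 0L)
  expect_equal(t4$d_r[1:8], c(5, 5, 5, 4, 3, 2, 1, 0))
})

test_that("d_r is monotone nonincreasing for every fixture", {
  set.seed(43)
  for (name in c("linear3", "threecomp", "hiv")) {
    tab <- method2_dimension(fixture(name))
    expect_true(all(diff(tab$d_r) <= 0))
  }
})

test_that("methods 1 and 2 agree where a published coefficient map exists", {
  set.seed(44)
  expect_equal(method1_dimension(coefficient_fixture("linear3_c"))$l,
               attr(method2_dimension(fixture("linear3")), "final_dimension"))
  expect_equal(method1_dimension(coefficient_fixture("linear3_noleak13_c"))$l,
               attr(method2_dimension(fixture("linear3_noleak13")),
                    "final_dimension"))
})
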