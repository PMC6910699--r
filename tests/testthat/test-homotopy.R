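# path tracking, total-degree start systems, slices and slice moves

test_that("track follows simple homotopies", {
  # H(z, t) = z - (1 - t) * a : endpoint a
  a <- 2.5 - 1.25i
  n <- 1L
  hp <- pl_add(pl_var(2L, 1L),
               pl_add(pl_const(2L, -a),
                      pl_scale(pl_var(2L, 2L), a)))
  hsys <- ik_system(list(hp), c("z", ".s"))
  r <- track(hsys, list(0 + 0i), "linear")[[1]]
  expect_equal(r$status, "converged")
  expect_lt(abs(r$endpoint - a), 1e-10)

  # H(z, t) = z^2 - (t + 4(1 - t)) from z = 1: continuity picks +2
  hp2 <- pl_sum(list(pl_var(2L, 1L, 2L), pl_const(2L, -4),
                     pl_scale(pl_var(2L, 2L), 3)))
  r2 <- track(ik_system(list(hp2), c("z", ".s")), list(1 + 0i), "linear")[[1]]
  expect_lt(abs(r2$endpoint - 2), 1e-10)
})

test_that("total-degree homotopies find complete solution sets", {
  # {z^2 - 1}
  sys <- ik_system(list(parse_rational("z^2 - 1", "z")$num), "z")
  set.seed(51)
  r <- total_degree_solve(sys)
  expect_equal(r$n_paths, 2L)
  expect_true(sets_match(r$solutions, list(1 + 0i, -1 + 0i), 1e-8))

  # {z1 - 3, z2^2 - 4}
  sys2 <- ik_system(list(parse_rational("z1 - 3", c("z1", "z2"))$num,
                         parse_rational("z2^2 - 4", c("z1", "z2"))$num),
                    c("z1", "z2"))
  r2 <- total_degree_solve(sys2)
  expect_length(r2$solutions, 2L)

  # oracle: products of univariate factors, roots from polyroot
  set.seed(52)
  co1 <- rand_complex(4)  # cubic in z1
  co2 <- rand_complex(3)  # quadratic in z2
  mk_poly <- function(co, var, nv, k) {
    acc <- pl_zero(nv)
    for (d in seq_along(co)) {
      E <- matrix(0L, 1L, nv); E[1L, k] <- d - 1L
      acc <- pl_add(acc, structure(list(E = E, c = co[d]), class = "ikpoly"))
    }
    acc
  }
  sys3 <- ik_system(list(mk_poly(co1, "z1", 2L, 1L),
                         mk_poly(co2, "z2", 2L, 2L)), c("z1", "z2"))
  r3 <- total_degree_solve(sys3)
  roots1 <- polyroot(co1); roots2 <- polyroot(co2)
  expected <- list()
  for (a in roots1) for (b in roots2)
    expected[[length(expected) + 1L]] <- c(a, b)
  expect_true(sets_match(r3$solutions, expected, 1e-6))
})

test_that("converged endpoints satisfy their systems to 1e-10", {
  set.seed(53)
  cm <- coefficient_fixture("linear3_noleak13_c")
  alpha <- rand_complex(5)
  val <- cmap_eval(cm, alpha)
  rows <- identikit:::cmap_fiber_polys(cm, val)
  sol <- total_degree_solve(ik_system(rows, cm$params))
  for (z in sol$solutions)
    expect_lt(max(abs(cmap_eval(cm, z) - val)) / max(1, max(abs(z))), 1e-10)
})

test_that("random slices pass through their point", {
  set.seed(54)
  p <- rand_complex(6)
  sl <- random_slice_through(p, 3L)
  expect_lt(identikit:::slice_residual(sl, p), 1e-12)
  full <- random_slice_through(p, 6L)
  expect_equal(full$codimension, 6L)
  sl2 <- random_slice_through(p, 3L)
  expect_false(isTRUE(all.equal(sl$A, sl2$A)))
})

test_that("slice moves reproduce the published endpoint and are reversible", {
  set.seed(55)
  cm <- coefficient_fixture("linear3_c")
  p <- as.complex(1:7)
  val <- cmap_eval(cm, p)
  cons <- ik_system(identikit:::cmap_fiber_polys(cm, val), cm$params)

  # trivial move: identical slices return the start point
  sl <- random_slice_through(p, 2L)
  r0 <- move_slice(cons, p, sl, sl)
  expect_lt(max(abs(r0$endpoint - p)), 1e-8)

  # published slices give the published endpoint to four decimals
  r <- move_slice(cons, p, slice_Lp(), slice_L())
  expect_equal(r$status, "converged")
  expect_lt(max(abs(r$endpoint - eq12_endpoint())), 1e-4)

  # reversibility
  back <- move_slice(cons, r$endpoint, slice_L(), slice_Lp())
  expect_lt(max(abs(back$endpoint - p)), 1e-8)
})

test_that("the jet-side slice move reaches the same parameter endpoint", {
  set.seed(56)
  m <- fixture("linear3")
  js <- truncate_model(m, 7)
  # trajectory through p = (1, ..., 7) with random input and initial state
  p <- as.complex(1:7)
  r <- js$order; ns <- js$ns
  x0 <- rand_complex(ns); U <- rand_complex(r + 1L)
  X <- matrix(complex(ns * (r + 2L)), ns, r + 2L); X[, 1] <- x0
  for (j in 0:r) {
    vals <- c(lapply(seq_len(ns), function(s) X[s, 1:(j + 1L)]),
              lapply(seq_len(7L), function(k) c(p[k], complex(j))),
              list(U[1:(j + 1L)]))
    for (s in seq_len(ns))
      X[s, j + 2L] <- identikit:::nser_poly(m$rhs[[s]]$num, vals, j + 1L)[j + 1L]
  }
  Y <- X[1, 1:(r + 1L)]  # output y = x1
  basesys <- identikit:::jet_io_system(js, U, Y)
  z0 <- c(p, as.vector(X))
  # slices act on the parameter coordinates only
  cols <- seq_len(7L)
  rmv <- move_slice(basesys, z0, slice_Lp(), slice_L(), cols = cols)
  expect_equal(rmv$status, "converged")
  expect_lt(max(abs(rmv$endpoint[1:7] - eq12_endpoint())), 1e-4)
})
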