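# identifiable functions: sampling, interpolation, integer recovery,
# global classification

test_that("monomial bases enumerate the expected terms", {
  b1 <- monomial_basis(paste0("k", 1:7), 1)
  expect_equal(nrow(b1$E), 7L)
  b2 <- monomial_basis(c("p1", "p2"), 2)
  expect_equal(nrow(b2$E), 5L)
  b3 <- monomial_basis(paste0("a", 1:10), 2)
  expect_equal(nrow(b3$E), choose(12, 2) - 1L)  # 65 by direct count
})

test_that("fiber samples stay on the fiber and move every coordinate", {
  set.seed(81)
  cm <- coefficient_fixture("linear3_c")
  p <- as.complex(1:7)
  fs <- sample_fiber(cm, p, n = 4, d = 2)
  val <- cmap_eval(cm, p)
  for (q in fs$component_points) {
    expect_lt(max(abs(cmap_eval(cm, q) - val)), 1e-8)
    # every single parameter moves: each one is unidentifiable
    expect_gt(min(abs(q - p)), 1e-4)
  }
})

test_that("the identifiable linear subspace has dimension three", {
  set.seed(82)
  cm <- coefficient_fixture("linear3_c")
  fs <- sample_fiber(cm, as.complex(1:7), n = 5, d = 2)
  bas <- monomial_basis(cm$params, 1)
  sub <- identifiable_subspace(bas, fs)
  expect_equal(sub$dimension, 3L)
  # the first pairs each cut the dimension; later ones become redundant
  expect_true(all(diff(sub$dims_path) <= 0))
  expect_equal(sub$dims_path[length(sub$dims_path)],
               sub$dims_path[length(sub$dims_path) - 1L])
})

test_that("integer recovery finds the published linear combinations", {
  set.seed(83)
  cm <- coefficient_fixture("linear3_c")
  fs <- sample_fiber(cm, as.complex(1:7), n = 3, d = 2)
  bas <- monomial_basis(cm$params, 1)
  rec <- integer_recovery(fs, bas)
  want <- c("k01+k21", "k03+k13", "k02+k12+k32")
  canon <- function(s) paste(sort(strsplit(gsub("[ ]", "", s), "\\+")[[1]]),
                             collapse = "+")
  expect_setequal(unname(vapply(rec$labels, canon, character(1))),
                  unname(vapply(want, canon, character(1))))
  # recovered vectors verify on a fresh sample
  fs2 <- sample_fiber(cm, rand_complex(7), n = 2, d = 2)
  M2 <- identikit:::constraint_rows(bas, fs2)
  for (i in seq_len(nrow(rec$vectors)))
    expect_lt(max(abs(M2 %*% rec$vectors[i, ])), 1e-6)
})

test_that("exact integer constraint rows are recovered exactly", {
  bas <- list(E = diag(3L), labels = c("x", "y", "z"), params = c("x", "y", "z"))
  class(bas) <- "ik_basis"
  # a row that is already integer: x + 2y - z = 0 direction
  M <- matrix(c(1, 2, 5), 1, 3) + 0i   # relations: (2,-1,0) and (5,0,-1)
  rel <- identikit:::lll_relations(identikit:::stack_reim(M))
  expect_true(length(rel) >= 2L)
  for (a in rel) expect_lt(max(abs(M %*% a)), 1e-8)
})

test_that("recovered functions are constant on fresh fiber samples", {
  set.seed(84)
  cm <- coefficient_fixture("linear3_c")
  iset <- staged_identifiable_functions(cm, max_degree = 1)
  expect_equal(iset$independence, 3L)
  p <- rand_complex(7)
  fs <- sample_fiber(cm, p, n = 5, d = 2)
  for (fp in iset$fpolys) {
    v0 <- pl_eval(fp, p)
    for (q in fs$component_points)
      expect_lt(abs(pl_eval(fp, q) - v0) / max(1, abs(v0)), 1e-6)
  }
})

test_that("independence counts equal Jacobian ranks", {
  # {p1, p1^2} -> 1
  f1 <- structure(list(E = matrix(c(1L, 0L), 1), c = 1 + 0i), class = "ikpoly")
  f2 <- structure(list(E = matrix(c(2L, 0L), 1), c = 1 + 0i), class = "ikpoly")
  set.seed(85)
  expect_equal(independence_count(list(f1, f2), 2L), 1L)
  # the three recovered linear combinations have rank 3 (explicit matrix)
  V <- rbind(c(1, 0, 0, 0, 0, 1, 0),
             c(0, 0, 1, 0, 1, 0, 0),
             c(0, 1, 0, 1, 0, 0, 1))
  expect_equal(qr(V)$rank, 3L)
  bas <- monomial_basis(paste0("k", 1:7), 1)
  # same count through the package's Jacobian route
  ord <- match(c("k1", "k2", "k3", "k4", "k5", "k6", "k7"), bas$labels)
  fp <- lapply(1:3, function(i) {
    a <- integer(7); a[ord] <- V[i, ]
    identikit:::function_poly(a, bas)
  })
  expect_equal(independence_count(fp, 7L), 3L)
})

test_that("global classification matches the published jet-side cluster", {
  # the real 4-point cluster of the HIV jet computation
  cl4 <- list(c(0.1253, -2.4825, 4.4249, -0.9210, -0.2137) + 0i,
              c(-0.1253, -2.4825, 4.4249, -0.9210, -0.2137) + 0i,
              c(0.2602, -2.4825, 4.4249, -0.2137, -0.9210) + 0i,
              c(-0.2602, -2.4825, 4.4249, -0.2137, -0.9210) + 0i)
  bas <- monomial_basis(paste0("p", 1:5), 1)
  pick <- function(nm) {
    a <- integer(nrow(bas$E)); a[match(nm, bas$labels)] <- 1L
    identikit:::function_poly(a, bas)
  }
  fns <- list(pick("p2"), pick("p3"),
              identikit:::function_poly(
                {a <- integer(nrow(bas$E))
                 a[match(c("p4", "p5"), bas$labels)] <- 1L; a}, bas),
              pick("p4"), pick("p5"))
  set.seed(86)
  cl <- classify_global(fns, cl4, tol = 1e-3)
  expect_equal(cl$labels,
               c("globally identifiable", "globally identifiable",
                 "globally identifiable", "locally identifiable",
                 "locally identifiable"))
})
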