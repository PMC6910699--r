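# Identifiable parameters of the mixed-output MAPK model.
#
# The fiber of the mixed-output model is one-dimensional (see the dimension
# table tests).  A parameter is identifiable exactly when it is constant on
# the fiber components, which at a generic point means the fiber tangent
# direction has a zero in that coordinate.  The sixteen rate parameters
# below are identifiable; the six binding rates and ten mixing parameters
# are not.

test_that("sixteen MAPK parameters are identifiable from the mixed outputs", {
  set.seed(301)
  m <- fixture("mapk_mixed")
  js <- truncate_model(m, 11)
  idn <- c("b00", "b01", "b10", "c0001", "c0010", "c0011", "c0111", "c1011",
           "beta01", "beta10", "beta11", "gamma0100", "gamma1000",
           "gamma1100", "gamma1101", "gamma1110")
  pidx <- match(idn, m$params)
  unid <- setdiff(seq_len(32L), pidx)
  keep <- c(js$p_cols, js$x_cols)

  tangent_param_part <- function() {
    pt <- seed_point(js)
    J <- identikit:::jet_jacobian(js, pt$assignment)[, keep]
    rs <- apply(abs(J), 1L, max); J2 <- J / rs
    cs <- apply(abs(J2), 2L, max); cs[cs == 0] <- 1
    x <- svd(sweep(J2, 2L, cs, "/"))$v[, length(keep)]
    v <- (x / cs)[seq_len(32L)]
    v / max(abs(v))
  }
  dirs <- lapply(1:3, function(i) tangent_param_part())
  for (v in dirs) {
    # the tangent of the one-dimensional fiber annihilates every
    # identifiable coordinate and moves every unidentifiable one
    expect_lt(max(abs(v[pidx])), 1e-8)
    expect_gt(min(abs(v[unid])), 1e-3)
  }
  # the unidentifiable directions differ between fibers: no single linear
  # combination of the sixteen unidentifiable parameters is constant across
  # the sampled generic fibers
  D <- do.call(rbind, lapply(dirs, function(v) v[unid]))
  expect_equal(numeric_corank(D, 0L)$rank, 3L)
})
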