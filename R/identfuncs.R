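# Identifiable functions of the parameters: fiber sampling, interpolation
# over monomial bases, integer-coefficient recovery, and global-vs-local
# classification.

## ---- fiber sampling ---------------------------------------------------------

# square constraint system for the fiber of cmap through p0: (m1 - d) random
# combinations of the cleared fiber equations (all of them when m2 = m1 - d)
fiber_constraints <- function(cmap, p0, d) {
  val <- cmap_eval(cmap, p0)
  rows <- cmap_fiber_polys(cmap, val)
  need <- cmap$m1 - d
  if (cmap$m2 > need) {
    A <- matrix(rand_complex(need * cmap$m2), need, cmap$m2)
    rows <- lapply(seq_len(need), function(i) {
      acc <- pl_zero(cmap$m1)
      for (j in seq_len(cmap$m2)) acc <- pl_add(acc, pl_scale(rows[[j]], A[i, j]))
      acc
    })
  } else if (cmap$m2 < need) {
    stop("coefficient map has too few coordinates for the claimed fiber dimension")
  }
  ik_system(rows, cmap$params)
}

#' Sample points on the fiber component through a parameter point
#'
#' Builds a random linear slice of codimension d (the dimension of
#' unidentifiability) through `p`, then repeatedly moves it to fresh random
#' slices by the slice-moving homotopy; every endpoint lies on the
#' irreducible fiber component through `p` and satisfies `c(q) = c(p)`.
#'
#' @param cmap an `ik_cmap`.
#' @param p base parameter point.
#' @param n number of samples.
#' @param d fiber dimension (computed by [method1_dimension()] if omitted).
#' @param settings a [path_settings()].
#' @return an `ik_fiber_sample`: list with `base_point`,
#'   `component_points`, `cmap`.
#' @export
sample_fiber <- function(cmap, p, n = 5L, d = NULL,
                         settings = path_settings()) {
  p <- as.complex(p)
  if (is.null(d)) d <- method1_dimension(cmap)$l
  if (d < 1L) stop("fiber is finite (d = 0); use all_components instead")
  cons <- fiber_constraints(cmap, p, d)
  val <- cmap_eval(cmap, p)
  slice_from <- random_slice_through(p, d)
  pts <- list()
  tries <- 0L
  while (length(pts) < n && tries < 4L * n) {
    tries <- tries + 1L
    slice_to <- random_slice_through(rand_complex(cmap$m1), d)
    r <- move_slice(cons, p, slice_from, slice_to, settings = settings)
    if (r$status != "converged") next
    q <- r$endpoint
    if (max(abs(cmap_eval(cmap, q) - val)) / max(1, max(abs(q))) < 1e-8)
      pts[[length(pts) + 1L]] <- q
  }
  if (length(pts) < n)
    stop("fiber sampling failed: too many path failures")
  structure(list(base_point = p, component_points = pts, cmap = cmap, d = d),
            class = "ik_fiber_sample")
}

#' Restrict a coefficient map through an affine parameter map
#'
#' Composes a polynomial coefficient map with `p = B %*% p_hat + d0`,
#' producing a map on fewer free parameters.
#'
#' @param cmap a polynomial `ik_cmap` on m1 parameters.
#' @param B complex m1 x mh matrix.
#' @param d0 complex m1 offset.
#' @param param_names names of the reduced parameters.
#' @return an `ik_cmap` on mh parameters.
#' @export
cmap_restrict <- function(cmap, B, d0, param_names = NULL) {
  if (!cmap$polynomial) stop("affine restriction needs a polynomial map")
  mh <- ncol(B)
  if (is.null(param_names)) param_names <- paste0("ph", seq_len(mh))
  subs <- lapply(seq_len(cmap$m1), function(j) {
    acc <- pl_const(mh, d0[j])
    for (i in which(B[j, ] != 0 + 0i))
      acc <- pl_add(acc, pl_scale(pl_var(mh, i), B[j, i]))
    acc
  })
  polys <- lapply(cmap$sys$polys, pl_compose, subs = subs, new_n = mh)
  new <- coefficient_map(rep("0", 0), character(0), name = paste0(cmap$name, "_restricted"))
  new$params <- param_names; new$m1 <- mh; new$m2 <- cmap$m2
  new$polynomial <- TRUE
  new$sys <- ik_system(polys, param_names)
  new$exprs <- lapply(polys, function(p) rp_make(p, pl_const(mh, 1)))
  new$restriction <- list(B = B, d0 = d0, parent = cmap$name)
  new
}

# all solutions of c_rc(q_hat) = c_rc(p_hat): the fiber over c(p_hat) is
# contained in the witness set of a random slice through that value, which
# is grown by monodromy loops (a loop through the base point itself would
# only ride the tautological branch q_hat(t) = p_hat(t)).  n_target, when
# known (e.g. k * deg X certified by method4 on the restricted map), stops
# the growth early.
restricted_fiber_points <- function(rc, p_hat, n_target = NA_integer_,
                                    max_useless = 10L,
                                    settings = path_settings()) {
  mh <- rc$m1; m2 <- rc$m2
  p_hat <- as.complex(p_hat)
  val <- cmap_eval(rc, p_hat)
  A <- matrix(rand_complex(mh * m2), mh, m2)
  slice <- structure(list(A = A, b = as.complex(A %*% val),
                          codimension = mh), class = "ik_slice")
  w <- structure(list(cmap = rc, slice = slice, points = list(p_hat),
                      certified = FALSE), class = "ik_witness")
  useless <- 0L
  while (useless < max_useless &&
         (is.na(n_target) || length(w$points) < n_target)) {
    step <- monodromy_loop(w, settings = settings)
    if (length(step$new_points) > 0L) {
      w$points <- c(w$points, step$new_points)
      useless <- 0L
    } else useless <- useless + 1L
  }
  # certify the witness set with the bilinear trace test and absorb any
  # points its family discovers that the loops missed
  tt <- trace_test(w, settings)
  if (isTRUE(tt$pass) && length(tt$missing_points) > 0L)
    w$points <- c(w$points, tt$missing_points)
  vscale <- max(1, abs(val))
  pts <- Filter(function(z)
    max(abs(cmap_eval(rc, z) - val)) / vscale < 1e-7, w$points)
  attr(pts, "certified") <- isTRUE(tt$pass)
  pts
}

# continue fiber points along a path of base points: tracks solutions of
# c(q) = c(p(s)) with p(s) = to + s*(from - to) along a random complex arc
fiber_continue <- function(rc, pts, from, to, settings = path_settings()) {
  mh <- rc$m1; m2 <- rc$m2
  subs <- lapply(seq_len(mh), function(i) {
    pl_add(pl_const(mh + 1L, to[i]),
           pl_scale(pl_var(mh + 1L, mh + 1L), from[i] - to[i]))
  })
  gs <- lapply(rc$sys$polys, pl_compose, subs = subs, new_n = mh + 1L)
  A <- if (m2 > mh) matrix(rand_complex(mh * m2), mh, m2) else diag(mh) + 0i
  hpolys <- lapply(seq_len(mh), function(i) {
    acc <- pl_zero(mh + 1L)
    for (j in seq_len(m2)) {
      acc <- pl_add(acc, pl_scale(
        pl_remap(rc$sys$polys[[j]], mh + 1L, seq_len(mh)), A[i, j]))
      acc <- pl_add(acc, pl_scale(gs[[j]], -A[i, j]))
    }
    acc
  })
  hsys <- ik_system(hpolys, c(rc$params, ".s"))
  res <- track_retry(hsys, pts, "gamma", settings = settings)
  ok <- vapply(res, function(r) r$status == "converged", logical(1))
  out <- dedup_points(lapply(res[ok], `[[`, "endpoint"), 1e-6)
  attr(out, "complete") <- all(ok) && length(out) == length(pts)
  out
}

# move a certified generic witness set to the (possibly non-generic) slice
# through the value val: a complete witness set stays complete under slice
# continuation, so the endpoints with c = val are the complete fiber
witness_transfer <- function(rc, witness, val, settings = path_settings()) {
  mh <- rc$m1; m2 <- rc$m2
  Av <- matrix(rand_complex(mh * m2), mh, m2)
  rows_from <- cmap_slice_polys(rc, witness$slice$A, witness$slice$b)
  rows_to <- cmap_slice_polys(rc, Av, as.complex(Av %*% val))
  ext <- function(p) pl_remap(p, mh + 1L, seq_len(mh))
  hpolys <- lapply(seq_len(mh), function(i) {
    toi <- ext(rows_to[[i]])
    pl_add(toi, pl_mul(pl_var(mh + 1L, mh + 1L),
                       pl_sub(ext(rows_from[[i]]), toi)))
  })
  hsys <- ik_system(hpolys, c(rc$params, ".s"))
  res <- track_retry(hsys, witness$points, "gamma", settings = settings)
  ok <- vapply(res, function(r) r$status == "converged", logical(1))
  ends <- dedup_points(lapply(res[ok], `[[`, "endpoint"), 1e-6)
  vscale <- max(1, abs(val))
  pts <- Filter(function(z)
    max(abs(cmap_eval(rc, z) - val)) / vscale < 1e-7, ends)
  attr(pts, "complete") <- all(ok) && length(ends) == length(witness$points)
  pts
}

#' Points on every irreducible component of a fiber
#'
#' Restricts the parameters through a general affine map `b` so that the
#' restricted map is identifiable, finds all solutions of
#' `c(b(q_hat)) = c(b(p_hat))` (monodromy, with the count certified on the
#' restricted map by [method4_degree()]), and maps them back through `b`.
#' The images seed every irreducible component of the fiber over
#' `p = b(p_hat)`.
#'
#' @param cmap a polynomial `ik_cmap`.
#' @param B,d0 optional explicit affine restriction (random if omitted).
#' @param p_hat reduced parameter point (random if omitted).
#' @param d fiber dimension (computed if omitted).
#' @param settings a [path_settings()].
#' @return list with `points` (fiber points, one per component at least),
#'   `k_restricted`, `certified`, `p` (the base point `b(p_hat)`),
#'   `restricted` (the restricted `ik_cmap`).
#' @export
all_components <- function(cmap, B = NULL, d0 = NULL, p_hat = NULL, d = NULL,
                           settings = path_settings()) {
  if (is.null(d)) d <- method1_dimension(cmap)$l
  if (d == 0L) {
    p0 <- rand_complex(cmap$m1)
    return(list(points = list(p0), k_restricted = 1L, certified = TRUE,
                p = p0, restricted = cmap))
  }
  mh <- cmap$m1 - d
  if (is.null(B)) {
    B <- matrix(rand_complex(cmap$m1 * mh), cmap$m1, mh)
    d0 <- rand_complex(cmap$m1)
  }
  if (is.null(d0)) d0 <- complex(cmap$m1)
  rc <- cmap_restrict(cmap, B, d0)
  if (method1_dimension(rc)$l > 0L)
    stop("restricted map is still rank-deficient; try a new random restriction")
  if (is.null(p_hat)) p_hat <- rand_complex(mh)
  p_hat <- as.complex(p_hat)
  val <- cmap_eval(rc, p_hat)
  vscale <- max(1, abs(val))
  # degree-sorted Bezout count of the triangular-squared fiber system
  degs <- sort(vapply(rc$sys$polys, pl_degree, integer(1)))
  bez <- prod(as.numeric(degs[seq_len(mh)]))
  generic_fiber <- function(base_pt) {
    valb <- cmap_eval(rc, base_pt)
    rows <- cmap_fiber_polys(rc, valb)
    if (rc$m2 > mh) rows <- triangular_square(rows, mh)
    sol <- total_degree_solve(ik_system(rows, rc$params), settings)
    Filter(function(z)
      max(abs(cmap_eval(rc, z) - valb)) / max(1, abs(valb)) < 1e-7,
      sol$solutions)
  }
  if (bez <= 600) {
    # solve the fiber over two fully generic base points (every Bezout path
    # is tracked, so the enumeration is complete when the counts agree),
    # then continue the fiber to the requested base point
    p2 <- rand_complex(mh) * (1 + max(abs(p_hat)))
    gen <- generic_fiber(p2)
    gen_check <- generic_fiber(rand_complex(mh) * (1 + max(abs(p_hat))))
    k_restricted <- length(gen)
    pts_hat <- fiber_continue(rc, gen, p2, p_hat, settings)
    complete <- length(gen) == length(gen_check) &&
      isTRUE(attr(pts_hat, "complete"))
    pts_hat <- Filter(function(z)
      max(abs(cmap_eval(rc, z) - val)) / vscale < 1e-7, pts_hat)
  } else {
    deg <- method4_degree(rc, settings = settings)
    k_restricted <- deg$k
    pts_hat <- witness_transfer(rc, deg$witness, val, settings = settings)
    complete <- deg$certified && isTRUE(attr(pts_hat, "complete"))
    if (length(pts_hat) < deg$k) {
      # fall back to monodromy at the special fiber for anything the slice
      # continuation lost
      more <- restricted_fiber_points(rc, p_hat, n_target = deg$n_W,
                                      settings = settings)
      pts_hat <- dedup_points(c(pts_hat, more), 1e-6)
      complete <- deg$certified && isTRUE(attr(more, "certified"))
    }
  }
  # the base point itself belongs to the fiber
  if (!any(vapply(pts_hat, function(q)
    max(abs(q - p_hat)) / max(1, max(abs(p_hat))) < 1e-6, logical(1))))
    pts_hat <- c(list(p_hat), pts_hat)
  if (complete && length(pts_hat) != k_restricted)
    warning("found ", length(pts_hat), " restricted fiber points but the ",
            "enumeration gave ", k_restricted)
  pts <- lapply(pts_hat, function(q) as.complex(B %*% q + d0))
  list(points = pts, k_restricted = k_restricted,
       certified = complete && length(pts_hat) == k_restricted,
       p = as.complex(B %*% p_hat + d0), restricted = rc)
}

#' Monodromy connectivity of fiber witness points
#'
#' The fiber points returned by [all_components()] are the witness points of
#' the fiber variety with respect to the affine restriction plane.  Moving
#' that slice around random two-leg loops permutes them; points in a common
#' cycle lie on the same irreducible component.  A single orbit certifies
#' that the generic fiber has one irreducible component.
#'
#' @param cmap the (unrestricted) `ik_cmap`.
#' @param points fiber witness points in the full parameter space.
#' @param d fiber dimension.
#' @param max_loops loop budget.
#' @param settings a [path_settings()].
#' @return list with `n_orbits` (upper bound on the number of components
#'   carrying the points) and `orbits` (index groups).
#' @export
fiber_component_orbits <- function(cmap, points, d, max_loops = 12L,
                                   settings = path_settings()) {
  m1 <- cmap$m1
  np <- length(points)
  if (np <= 1L)
    return(list(n_orbits = np, orbits = if (np) list(1L) else list()))
  val <- cmap_eval(cmap, points[[1L]])
  cons <- triangular_square(cmap_fiber_polys(cmap, val), m1 - d)
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ext <- function(p) pl_remap(p, m1 + 1L, seq_len(m1))
  leg_sys <- function(rows_from, rows_to) {
    hpolys <- c(lapply(cons, ext),
                lapply(seq_along(rows_to), function(i) {
                  toi <- ext(rows_to[[i]])
                  pl_add(toi, pl_mul(pl_var(m1 + 1L, m1 + 1L),
                                     pl_sub(ext(rows_from[[i]]), toi)))
                }))
    ik_system(hpolys, c(cmap$params, ".s"))
  }
  # common start slice: the affine restriction plane containing all points,
  # expressed as d linear conditions vanishing on every point
  P <- do.call(cbind, points)
  dirs <- P[, -1L, drop = FALSE] - P[, 1L]
  base_rows <- nullspace(t(dirs), 1e-8)
  if (ncol(base_rows) < d)
    stop("fiber points do not lie on a common affine plane of codimension d")
  A0 <- t(base_rows[, seq_len(d), drop = FALSE])
  sl0 <- structure(list(A = A0, b = as.complex(A0 %*% points[[1L]]),
                        codimension = d), class = "ik_slice")
  rows0 <- slice_polys(sl0, seq_len(m1), m1)
  cur <- points
  for (loop in seq_len(max_loops)) {
    if (length(unique(vapply(seq_len(np), find, integer(1)))) == 1L) break
    sl1 <- random_slice_through(rand_complex(m1), d)
    rows1 <- slice_polys(sl1, seq_len(m1), m1)
    out <- track_retry(leg_sys(rows0, rows1), cur, "gamma",
                       settings = settings)
    ok1 <- vapply(out, function(r) r$status == "converged", logical(1))
    back <- track_retry(leg_sys(rows1, rows0),
                        lapply(out, `[[`, "endpoint"), "gamma",
                        settings = settings)
    for (i in seq_len(np)) {
      if (!ok1[i] || back[[i]]$status != "converged") next
      e <- back[[i]]$endpoint
      hit <- which(vapply(points, function(q)
        max(abs(q - e)) / max(1, abs(q), abs(e)) < 1e-6, logical(1)))
      if (length(hit) == 1L && hit != i) {
        ri <- find(i); rh <- find(hit)
        if (ri != rh) parent[max(ri, rh)] <- min(ri, rh)
      }
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  orbits <- split(seq_len(np), match(roots, unique(roots)))
  list(n_orbits = length(orbits), orbits = orbits)
}

## ---- function bases and interpolation --------------------------------------

#' Monomial basis of candidate identifiable functions
#'
#' All nonconstant monomials in the parameters of total degree at most
#' `max_degree`.
#'
#' @param params parameter names.
#' @param max_degree total degree bound.
#' @return an `ik_basis`: list with `E` (terms x params exponent matrix),
#'   `labels`, `params`.
#' @export
monomial_basis <- function(params, max_degree) {
  if (max_degree < 1L) stop("max_degree must be >= 1")
  m <- length(params)
  expos <- list(integer(m))
  for (d in seq_len(max_degree)) {
    prev <- expos
    expos <- list(integer(m))
    for (e in prev) for (j in seq_len(m)) {
      if (sum(e) < d) {
        e2 <- e; e2[j] <- e2[j] + 1L
        expos[[length(expos) + 1L]] <- e2
      }
    }
    expos <- unique(expos)
  }
  # regenerate cleanly: all exponent vectors with 1 <= total degree <= bound
  grid <- as.matrix(do.call(expand.grid, rep(list(0:max_degree), m)))
  keep <- rowSums(grid) >= 1L & rowSums(grid) <= max_degree
  E <- grid[keep, , drop = FALSE]
  E <- E[order(rowSums(E), apply(E, 1, paste, collapse = ",")), , drop = FALSE]
  storage.mode(E) <- "integer"
  colnames(E) <- params
  labels <- apply(E, 1L, function(e) {
    parts <- vapply(which(e > 0L), function(j)
      if (e[j] == 1L) params[j] else paste0(params[j], "^", e[j]), character(1))
    paste(parts, collapse = "*")
  })
  structure(list(E = unname(E), labels = unname(labels), params = params),
            class = "ik_basis")
}

# evaluate all basis monomials at a complex point
basis_eval <- function(basis, z) {
  vapply(seq_len(nrow(basis$E)), function(i) {
    e <- basis$E[i, ]
    prod(z[e > 0L]^e[e > 0L])
  }, complex(1))
}

# constraint rows f_j(q) - f_j(p) for a list of samples; complex matrix
constraint_rows <- function(basis, samples) {
  if (inherits(samples, "ik_fiber_sample")) samples <- list(samples)
  rows <- list()
  for (s in samples) {
    fp <- basis_eval(basis, s$base_point)
    for (q in s$component_points)
      rows[[length(rows) + 1L]] <- basis_eval(basis, q) - fp
  }
  do.call(rbind, rows)
}

stack_reim <- function(M) rbind(Re(M), Im(M))

#' Identifiable linear subspace of a function basis
#'
#' Each sample pair (p, q) on one fiber component imposes the linear
#' constraint `sum(a_j (f_j(q) - f_j(p))) = 0` on the coefficient vector a.
#' Pairs are added one at a time until the nullspace dimension is unchanged
#' by two consecutive additions; the nullspace then spans the identifiable
#' functions inside the basis.
#'
#' @param basis an `ik_basis`.
#' @param samples an `ik_fiber_sample` or list of them.
#' @param tol singular-value tolerance of the nullspace.
#' @return list with `dimension`, `nullspace` (columns span the coefficient
#'   vectors), `n_constraints_used`, `dims_path`.
#' @export
identifiable_subspace <- function(basis, samples, tol = 1e-8) {
  rows <- constraint_rows(basis, samples)
  if (is.null(rows) || nrow(rows) == 0L) stop("need at least one sample pair")
  dims <- integer(0)
  stable <- 0L
  used <- 0L
  for (i in seq_len(nrow(rows))) {
    used <- i
    N <- nullspace(rows[seq_len(i), , drop = FALSE], tol)
    dims <- c(dims, ncol(N))
    if (i > 1L && dims[i] == dims[i - 1L]) stable <- stable + 1L else stable <- 0L
    if (stable >= 2L) break
  }
  list(dimension = dims[used], nullspace = N, n_constraints_used = used,
       dims_path = dims)
}

#' Integer-coefficient identifiable functions inside a basis
#'
#' Searches for primitive integer coefficient vectors a such that
#' `sum(a_j f_j)` is constant on the sampled fiber components: sparse
#' supports of size 1-3 are enumerated with rational ratio recovery, and
#' (for bases of at most 60 terms) LLL lattice reduction over the full
#' constraint matrix finds the rest.  Candidates are verified on every
#' sample pair.
#'
#' @param samples an `ik_fiber_sample` or list of them.
#' @param basis an `ik_basis`.
#' @param tol verification tolerance.
#' @param max_support largest enumerated support size.
#' @param use_lll also run the LLL relation search when the basis is small.
#' @return list with `vectors` (rows = integer coefficient vectors),
#'   `labels` (pretty-published functions).
#' @export
integer_recovery <- function(samples, basis, tol = 1e-6, max_support = 3L,
                             use_lll = TRUE) {
  M <- constraint_rows(basis, samples)
  if (is.null(M) || nrow(M) == 0L) stop("need at least one sample pair")
  scale <- max(abs(M), 1)
  nterms <- ncol(M)
  found <- list()
  ok_vec <- function(a) max(abs(M %*% a)) / (scale * max(abs(a))) < tol
  # support 1
  for (j in seq_len(nterms)) {
    a <- integer(nterms); a[j] <- 1L
    if (ok_vec(a)) found[[length(found) + 1L]] <- a
  }
  # support 2: alpha * f_i + f_j with alpha from the first pair, verified on all
  nz <- which(apply(abs(M), 2L, min) > tol * scale)
  if (max_support >= 2L) {
    for (ii in seq_along(nz)) for (jj in seq_along(nz)) {
      if (ii >= jj) next
      i <- nz[ii]; j <- nz[jj]
      alpha <- -M[1L, j] / M[1L, i]
      if (max(abs(M[, i] * alpha + M[, j])) / scale > tol * 10) next
      rat <- rationalize(Re(alpha))
      if (is.null(rat) || abs(Im(alpha)) > 1e-6 * max(1, abs(alpha))) next
      a <- integer(nterms); a[i] <- rat[1L]; a[j] <- rat[2L]
      if (max(abs(a)) > 0 && ok_vec(a)) found[[length(found) + 1L]] <- primitive_int(a)
    }
  }
  # support 3: solve for two ratios by least squares over all pairs
  if (max_support >= 3L && length(nz) <= 40L && nrow(M) >= 2L) {
    cmb <- utils::combn(nz, 3L)
    for (cix in seq_len(ncol(cmb))) {
      ij <- cmb[, cix]
      A2 <- M[, ij[1:2], drop = FALSE]
      rhs <- -M[, ij[3L]]
      ab <- tryCatch(qr.solve(A2, rhs), error = function(e) NULL)
      if (is.null(ab)) next
      if (max(abs(A2 %*% ab - rhs)) / scale > tol * 10) next
      r1 <- rationalize(Re(ab[1L])); r2 <- rationalize(Re(ab[2L]))
      if (is.null(r1) || is.null(r2) ||
          max(abs(Im(ab))) > 1e-6 * max(1, max(abs(ab)))) next
      den <- r1[2L] * r2[2L]
      a <- integer(nterms)
      a[ij[1L]] <- r1[1L] * r2[2L]; a[ij[2L]] <- r2[1L] * r1[2L]; a[ij[3L]] <- den
      if (ok_vec(a)) found[[length(found) + 1L]] <- primitive_int(a)
    }
  }
  if (use_lll && nterms <= 60L) {
    found <- c(found, lll_relations(stack_reim(M), tol = tol))
  }
  found <- unique(found)
  if (length(found) == 0L)
    return(list(vectors = matrix(integer(0), 0L, nterms),
                labels = character(0),
                diagnostic = "no integer relation below the height bound"))
  V <- do.call(rbind, found)
  list(vectors = V, labels = apply(V, 1L, pretty_function, basis = basis))
}

pretty_function <- function(a, basis) {
  idx <- which(a != 0)
  parts <- vapply(idx, function(j) {
    co <- a[j]
    lab <- basis$labels[j]
    if (co == 1) paste0(" + ", lab)
    else if (co == -1) paste0(" - ", lab)
    else if (co > 0) paste0(" + ", co, "*", lab)
    else paste0(" - ", abs(co), "*", lab)
  }, character(1))
  out <- paste(parts, collapse = "")
  sub("^ \\+ ", "", sub("^ - ", "-", out))
}

# ikpoly over the parameters from a basis coefficient vector
function_poly <- function(a, basis) {
  idx <- which(a != 0)
  structure(list(E = basis$E[idx, , drop = FALSE], c = as.complex(a[idx])),
            class = "ikpoly")
}

function_gradient <- function(fpoly, z) {
  vapply(seq_along(z), function(k) pl_eval(pl_deriv(fpoly, k), z), complex(1))
}

#' Number of algebraically independent functions
#'
#' The rank of the Jacobian of the function list at a random complex
#' parameter point equals the number of algebraically independent functions
#' in the list.
#'
#' @param functions list of `ikpoly` functions (or an `ik_identset`).
#' @param nparams number of parameters (taken from the functions if omitted).
#' @export
independence_count <- function(functions, nparams = NULL) {
  if (inherits(functions, "ik_identset")) functions <- functions$fpolys
  if (length(functions) == 0L) return(0L)
  if (is.null(nparams)) nparams <- ncol(functions[[1L]]$E)
  z <- rand_complex(nparams)
  J <- t(vapply(functions, function_gradient, complex(nparams), z = z))
  numeric_corank(J, 0L)$rank
}

#' Staged search for algebraically independent identifiable functions
#'
#' Recovers integer-coefficient identifiable functions degree by degree:
#' candidates from [integer_recovery()] are ordered by degree, support size
#' and height, and accepted greedily when they increase the Jacobian rank of
#' the accepted set, until rank `m1 - l` (the rank of the coefficient map)
#' is reached or the degree bound is exhausted.
#'
#' @param cmap an `ik_cmap` with positive-dimensional fibers.
#' @param max_degree monomial degree bound.
#' @param n_samples sample pairs per base point.
#' @param settings a [path_settings()].
#' @return an `ik_identset`: list with `vectors`, `labels`, `fpolys`,
#'   `independence`, `rank_target`, `basis`.
#' @export
staged_identifiable_functions <- function(cmap, max_degree = 3L,
                                          n_samples = 5L,
                                          settings = path_settings()) {
  l <- method1_dimension(cmap)$l
  if (l == 0L) stop("map is identifiable; every function of the parameters is identifiable")
  rank_target <- cmap$m1 - l
  p <- rand_complex(cmap$m1)
  samples <- sample_fiber(cmap, p, n = n_samples, d = l, settings = settings)
  basis <- monomial_basis(cmap$params, max_degree)
  rec <- integer_recovery(samples, basis,
                          use_lll = nrow(basis$E) <= 60L)
  if (nrow(rec$vectors) == 0L)
    return(structure(list(vectors = rec$vectors, labels = character(0),
                          fpolys = list(), independence = 0L,
                          rank_target = rank_target, basis = basis,
                          samples = samples), class = "ik_identset"))
  deg <- apply(rec$vectors, 1L, function(a) max(rowSums(basis$E[a != 0, , drop = FALSE])))
  supp <- rowSums(rec$vectors != 0L)
  hgt <- apply(abs(rec$vectors), 1L, max)
  ord <- order(deg, supp, hgt)
  accepted <- list(); vecs <- list()
  z <- rand_complex(cmap$m1)
  grads <- NULL
  for (i in ord) {
    fp <- function_poly(rec$vectors[i, ], basis)
    g <- function_gradient(fp, z)
    cand <- rbind(grads, g)
    if (numeric_corank(cand, 0L)$rank > length(accepted)) {
      accepted[[length(accepted) + 1L]] <- fp
      vecs[[length(vecs) + 1L]] <- rec$vectors[i, ]
      grads <- cand
    }
    if (length(accepted) >= rank_target) break
  }
  V <- do.call(rbind, vecs)
  structure(list(vectors = V,
                 labels = apply(V, 1L, pretty_function, basis = basis),
                 fpolys = accepted,
                 independence = independence_count(accepted, cmap$m1),
                 rank_target = rank_target, basis = basis, samples = samples),
            class = "ik_identset")
}

#' @export
print.ik_identset <- function(x, ...) {
  cat(sprintf("<ik_identset: %d identifiable functions, %d algebraically independent (target %d)>\n",
              length(x$fpolys), x$independence, x$rank_target))
  for (i in seq_along(x$labels)) {
    lab <- if (!is.null(x$global_labels)) paste0("  [", x$global_labels[i], "]") else ""
    cat("  f", i, " = ", x$labels[i], lab, "\n", sep = "")
  }
  invisible(x)
}

#' Classify identifiable functions as globally or locally identifiable
#'
#' A function is globally identifiable when it takes the same value on
#' every irreducible component of a generic fiber.  Given points on all
#' components (from [all_components()]), each function is evaluated at every
#' point; beyond the per-function labels, integer combinations of the
#' locally-identifiable functions that become constant across components
#' (hence globally identifiable) are searched for with the same
#' integer-relation machinery.
#'
#' @param functions list of `ikpoly` functions or an `ik_identset`.
#' @param component_points list of fiber points covering all components.
#' @param tol relative agreement tolerance.
#' @param labels optional pretty labels.
#' @return list with `labels` (`"globally identifiable"` /
#'   `"locally identifiable"`), `values` (components x functions),
#'   `global_combinations` (integer vectors over the function list).
#' @export
classify_global <- function(functions, component_points, tol = 1e-6,
                            labels = NULL) {
  iset <- NULL
  if (inherits(functions, "ik_identset")) {
    iset <- functions
    labels <- functions$labels
    functions <- functions$fpolys
  }
  V <- vapply(functions, function(fp)
    vapply(component_points, function(q) pl_eval(fp, q), complex(1)),
    complex(length(component_points)))
  V <- matrix(V, nrow = length(component_points))
  spread <- apply(V, 2L, function(col)
    max(abs(col - col[1L])) / max(1, max(abs(col))))
  lab <- ifelse(spread < tol, "globally identifiable", "locally identifiable")
  combos <- list(); combo_labels <- character(0)
  loc <- which(lab == "locally identifiable")
  if (length(loc) >= 2L && nrow(V) >= 2L) {
    D <- V[-1L, loc, drop = FALSE] - matrix(V[1L, loc], nrow(V) - 1L,
                                            length(loc), byrow = TRUE)
    fake_basis <- list(E = diag(length(loc)),
                       labels = if (is.null(labels)) paste0("f", loc)
                                else paste0("(", labels[loc], ")"))
    # integer nullspace of the cross-component value differences
    cand <- lll_relations(stack_reim(D), tol = tol)
    for (a in cand) {
      full <- integer(length(functions)); full[loc] <- a
      combos[[length(combos) + 1L]] <- full
      combo_labels <- c(combo_labels, pretty_function(a, fake_basis))
    }
  }
  out <- list(labels = lab, values = V, global_combinations = combos,
              combination_labels = combo_labels)
  if (!is.null(iset)) {
    iset$global_labels <- lab
    out$identset <- iset
  }
  out
}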