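# Identifiability degree: direct total-degree solving, monodromy on
# pseudowitness sets with trace-test stopping, and the jet-side variant
# that needs no input-output equations.

# polynomial rows of c(q) - val (denominators cleared per coordinate)
cmap_fiber_polys <- function(cmap, val) {
  lapply(seq_len(cmap$m2), function(i) {
    e <- cmap$exprs[[i]]
    pl_sub(e$num, pl_scale(e$den, val[i]))
  })
}

# square an overdetermined system down to n equations by degree-preserving
# triangular random combinations: rows are sorted by ascending degree and
# row i mixes only rows 1..i, so the Bezout count is the product of the n
# smallest degrees instead of the largest degree to the n-th power.  The
# solution set contains every common zero; extraneous zeros are filtered by
# the residual of the full system.
triangular_square <- function(rows, n) {
  degs <- vapply(rows, pl_degree, integer(1))
  rows_s <- rows[order(degs)]
  lapply(seq_len(n), function(i) {
    acc <- pl_scale(rows_s[[i]], rand_complex(1L))
    if (i > 1L) for (j in seq_len(i - 1L))
      acc <- pl_add(acc, pl_scale(rows_s[[j]], rand_complex(1L)))
    acc
  })
}

# rows of A %*% (c(q) - offset) as polynomials over the parameters
cmap_slice_polys <- function(cmap, A, b) {
  if (!cmap$polynomial)
    stop("monodromy slices need a polynomial coefficient map")
  m1 <- cmap$m1
  lapply(seq_len(nrow(A)), function(i) {
    acc <- pl_const(m1, -b[i])
    for (j in which(A[i, ] != 0 + 0i))
      acc <- pl_add(acc, pl_scale(cmap$sys$polys[[j]], A[i, j]))
    acc
  })
}

#' Identifiability degree by direct homotopy solving
#'
#' Picks a random complex parameter point p, forms the square system
#' c(q) = c(p) (clearing denominators; random linear combinations of the
#' coordinates when the map has more coefficients than parameters) and
#' solves it by a total-degree homotopy.  The degree k is the number of
#' distinct finite solutions; the base point must be recovered among them.
#'
#' @param cmap an identifiable `ik_cmap` (corank 0).
#' @param settings a [path_settings()].
#' @return list with `k`, `solutions`, `base_point`, `n_paths`.
#' @export
method3_degree <- function(cmap, settings = path_settings()) {
  if (method1_dimension(cmap)$l > 0L)
    stop("unidentifiable; degree undefined")
  m1 <- cmap$m1; m2 <- cmap$m2
  p0 <- rand_complex(m1)
  val <- cmap_eval(cmap, p0)
  rows <- cmap_fiber_polys(cmap, val)
  if (m2 > m1) {
    rows <- triangular_square(rows, m1)
  } else if (m2 < m1) {
    stop("coefficient map has fewer coefficients than parameters; fiber is positive-dimensional")
  }
  sys <- ik_system(rows, cmap$params)
  sol <- total_degree_solve(sys, settings)
  keep <- Filter(function(z) {
    max(abs(cmap_eval(cmap, z) - val)) / max(1, abs(z)) < 1e-6
  }, sol$solutions)
  if (!any(vapply(keep, function(z) max(abs(z - p0)) < 1e-6, logical(1))))
    stop("base point not recovered among the endpoints (tracking failure)")
  list(k = length(keep), solutions = keep, base_point = p0,
       n_paths = sol$n_paths)
}

## ---- pseudowitness sets and monodromy --------------------------------------

#' Start a pseudowitness set for the graph of a coefficient map
#'
#' Selects (or accepts) a general parameter point p, constructs a general
#' linear slice of codimension m1 in coefficient space through c(p), and
#' returns the one-point witness set {(p, c(p))}.
#'
#' @param cmap an `ik_cmap`.
#' @param p0 optional start parameter point (random if omitted).
#' @param slice optional `ik_slice` in coefficient space.
#' @return an `ik_witness`.
#' @export
witness_start <- function(cmap, p0 = NULL, slice = NULL) {
  if (is.null(p0)) p0 <- rand_complex(cmap$m1)
  c0 <- cmap_eval(cmap, p0)
  if (is.null(slice)) slice <- random_slice_through(c0, cmap$m1, cmap$m2)
  structure(list(cmap = cmap, slice = slice, points = list(as.complex(p0)),
                 certified = FALSE), class = "ik_witness")
}

witness_cvals <- function(w) lapply(w$points, function(q) cmap_eval(w$cmap, q))

#' Projection counts of a witness set
#'
#' `#W` is the number of witness points, `deg X = #pi(W)` the number of
#' distinct coefficient values among them, and `k = #W / #pi(W)` the fiber
#' cardinality.
#'
#' @param w an `ik_witness`.
#' @param tol clustering tolerance.
#' @export
witness_counts <- function(w, tol = 1e-6) {
  nW <- length(w$points)
  degX <- length(dedup_points(witness_cvals(w), tol))
  list(n_W = nW, deg_X = degX, k = nW / degX)
}

#' Run one monodromy loop on a witness set
#'
#' Default loops have two legs: the witness points are tracked from the
#' witness slice to a fully random slice and back, each leg along its own
#' random complex arc, which gives a nontrivial loop in the space of slices.
#' Alternatively an explicit `delta` runs the one-parameter translation loop
#' b(t) = b + s(t) * delta with s(t) = 1 - exp(2*pi*i*(1-t)).  Endpoints
#' that do not match a known witness point are returned.
#'
#' @param w an `ik_witness`.
#' @param delta optional complex translation direction for a circle loop.
#' @param settings a [path_settings()].
#' @param tol point-matching tolerance.
#' @return list with `new_points`, `n_failed`.
#' @export
monodromy_loop <- function(w, delta = NULL, settings = path_settings(),
                           tol = 1e-6) {
  m1 <- w$cmap$m1; m2 <- w$cmap$m2
  base <- cmap_slice_polys(w$cmap, w$slice$A, w$slice$b)
  ext <- function(p) pl_remap(p, m1 + 1L, seq_len(m1))
  leg <- function(rows_from, rows_to, starts) {
    hpolys <- lapply(seq_len(m1), function(i) {
      toi <- ext(rows_to[[i]])
      pl_add(toi, pl_mul(pl_var(m1 + 1L, m1 + 1L),
                         pl_sub(ext(rows_from[[i]]), toi)))
    })
    hsys <- ik_system(hpolys, c(w$cmap$params, ".s"))
    track(hsys, starts, "gamma", settings = settings)
  }
  if (!is.null(delta)) {
    hpolys <- lapply(seq_len(m1), function(i)
      pl_add(ext(base[[i]]),
             pl_scale(pl_var(m1 + 1L, m1 + 1L), -delta[i])))
    hsys <- ik_system(hpolys, c(w$cmap$params, ".s"))
    res <- track(hsys, w$points, "circle", settings = settings)
    ok <- vapply(res, function(r) r$status == "converged", logical(1))
    ends <- lapply(res[ok], `[[`, "endpoint")
  } else {
    A2 <- matrix(rand_complex(m1 * m2), m1, m2)
    b2 <- rand_complex(m1) * (1 + mean(abs(w$slice$b)))
    mid_rows <- cmap_slice_polys(w$cmap, A2, b2)
    out <- leg(base, mid_rows, w$points)
    ok1 <- vapply(out, function(r) r$status == "converged", logical(1))
    back <- leg(mid_rows, base, lapply(out[ok1], `[[`, "endpoint"))
    ok2 <- vapply(back, function(r) r$status == "converged", logical(1))
    ends <- lapply(back[ok2], `[[`, "endpoint")
    ok <- c(rep(FALSE, sum(!ok1)), ok2)
  }
  new <- Filter(function(z) {
    !any(vapply(w$points, function(q)
      max(abs(q - z)) / max(1, abs(q), abs(z)) < tol, logical(1)))
  }, ends)
  list(new_points = dedup_points(new, tol), n_failed = sum(!ok))
}

#' Multihomogeneous trace test for a pseudowitness set
#'
#' The first m1 - 1 slice rows cut the graph of the map down to a curve C;
#' the witness points are C intersected with the last row.  A fiber-moving
#' linear trace cannot certify completeness here (the coordinate sum over a
#' moving fiber is a pushforward, not an affine function), so the test uses
#' the bilinear hyperplane family H(t) = {ellp(p) * elly(y) = t}, where
#' elly is the last slice row and ellp a random affine functional on the
#' parameters.  The witness points sit on the elly factor of H(0); the
#' family is populated by monodromy loops in t, completeness of the full
#' intersection is certified by the linear trace in t, and tracking t to 0
#' splits the points between the two factors, giving the bidegree.  Any
#' certified point on the elly side that is missing from the witness set is
#' returned so the caller can absorb it.
#'
#' @param w an `ik_witness`.
#' @param settings a [path_settings()].
#' @param tol relative collinearity residual accepted as a pass.
#' @param max_useless monodromy loop budget (in t) without progress.
#' @param retries fresh attempts (new random family) after an inconclusive
#'   run.
#' @return list with `pass` (`TRUE`/`FALSE`/`NA` for inconclusive),
#'   `residual`, `bidegree` (points on the ellp / elly factors), and
#'   `missing_points` (certified witness points absent from `w`).
#' @export
trace_test <- function(w, settings = path_settings(), tol = 1e-8,
                       max_useless = 8L, retries = 3L) {
  out <- list(pass = NA, residual = NA_real_, bidegree = NULL,
              missing_points = list())
  for (att in seq_len(retries)) {
    out <- trace_test_once(w, settings, tol, max_useless)
    if (!is.na(out$pass)) break
  }
  out
}

trace_test_once <- function(w, settings = path_settings(), tol = 1e-8,
                            max_useless = 8L) {
  m1 <- w$cmap$m1
  base <- cmap_slice_polys(w$cmap, w$slice$A, w$slice$b)
  curve_rows <- base[seq_len(m1 - 1L)]
  ly <- base[[m1]]
  a <- rand_complex(m1 + 1L)
  lp <- pl_const(m1, a[m1 + 1L])
  for (j in seq_len(m1)) lp <- pl_add(lp, pl_scale(pl_var(m1, j), a[j]))
  bil <- pl_mul(lp, ly)
  t0 <- (1 + stats::runif(1)) * exp(2i * pi * stats::runif(1))
  ext <- function(p) pl_remap(p, m1 + 1L, seq_len(m1))
  sysat <- function(tval, svec_coef = 0 + 0i) {
    # bilinear row: bil - tval + svec_coef * s
    last <- pl_add(ext(bil), pl_const(m1 + 1L, -tval))
    if (svec_coef != 0 + 0i)
      last <- pl_add(last, pl_scale(pl_var(m1 + 1L, m1 + 1L), svec_coef))
    ik_system(c(lapply(curve_rows, ext), list(last)),
              c(w$cmap$params, ".s"))
  }
  # move the witness points from t = 0 out to t = t0; points whose outward
  # path fails are dropped here and rediscovered by the monodromy loops
  res <- track_retry(sysat(t0, t0), w$points, "linear", settings = settings)
  ok0 <- vapply(res, function(r) r$status == "converged", logical(1))
  if (!any(ok0))
    return(list(pass = NA, residual = NA_real_, bidegree = NULL,
                missing_points = list()))
  pts <- dedup_points(lapply(res[ok0], `[[`, "endpoint"), 1e-6)
  # populate C cap H(t0) by monodromy loops in t
  useless <- 0L
  while (useless < max_useless) {
    # loop radii spread over decades so that distant branch points of the
    # t-cover are enclosed too
    dt <- rand_complex(1L) * abs(t0) * 10^stats::runif(1, -0.5, 1.5)
    res <- track_retry(sysat(t0, -dt), pts, "circle", settings = settings)
    ok <- vapply(res, function(r) r$status == "converged", logical(1))
    ends <- lapply(res[ok], `[[`, "endpoint")
    new <- Filter(function(z) {
      !any(vapply(pts, function(q)
        max(abs(q - z)) / max(1, abs(q), abs(z)) < 1e-6, logical(1)))
    }, ends)
    new <- dedup_points(new, 1e-6)
    if (length(new) > 0L) { pts <- c(pts, new); useless <- 0L }
    else useless <- useless + 1L
  }
  # linear trace in t over two parallel translates
  do_trace <- function(pts) {
    tau <- (1 + stats::runif(1)) * exp(2i * pi * stats::runif(1)) * abs(t0)
    sums <- list(Reduce(`+`, pts))
    for (step in 1:2) {
      res <- track_retry(sysat(t0 + step * tau, step * tau), pts, "linear",
                   settings = settings)
      if (any(vapply(res, function(r) r$status != "converged", logical(1))))
        return(NULL)
      sums[[step + 1L]] <- Reduce(`+`, lapply(res, `[[`, "endpoint"))
    }
    dev <- (sums[[3L]] - sums[[1L]]) - 2 * (sums[[2L]] - sums[[1L]])
    max(abs(dev)) / max(1, max(abs(sums[[2L]] - sums[[1L]])))
  }
  resid <- do_trace(pts)
  if (is.null(resid))
    return(list(pass = NA, residual = NA_real_, bidegree = NULL,
                missing_points = list()))
  if (resid >= tol) {
    # monodromy may have missed points of one factor; when the Bezout count
    # is affordable, complete each factor system deterministically by a
    # total-degree homotopy and redo the trace
    degs <- vapply(curve_rows, pl_degree, integer(1))
    if (prod(as.numeric(degs)) * max(vapply(list(lp, ly), pl_degree,
                                            integer(1))) <= 2000) {
      extra <- list()
      for (fac in list(lp, ly)) {
        fs <- ik_system(c(curve_rows, list(fac)), w$cmap$params)
        sol <- tryCatch(total_degree_solve(fs, settings)$solutions,
                        error = function(e) list())
        extra <- c(extra, sol)
      }
      if (length(extra) > 0L) {
        res <- track_retry(sysat(t0, t0), extra, "linear", settings = settings)
        okx <- vapply(res, function(r) r$status == "converged", logical(1))
        cand <- c(pts, lapply(res[okx], `[[`, "endpoint"))
        pts2 <- dedup_points(cand, 1e-6)
        if (length(pts2) > length(pts)) {
          pts <- pts2
          r2 <- do_trace(pts)
          if (!is.null(r2)) resid <- r2
        }
      }
    }
  }
  pass <- resid < tol
  # split by factor: track t towards 0 and see which factor degenerates
  eps <- 1e-4 * abs(t0)
  res <- track_retry(sysat(eps, -(t0 - eps)), pts, "linear", settings = settings)
  okend <- Filter(function(r) r$status == "converged", res)
  on_lp <- vapply(okend, function(r) {
    abs(pl_eval(lp, r$endpoint[seq_len(m1)])) <
      abs(pl_eval(ly, r$endpoint[seq_len(m1)]))
  }, logical(1))
  missing <- list()
  if (pass) {
    yside <- lapply(okend[!on_lp], function(r) r$endpoint[seq_len(m1)])
    # polish onto the exact witness slice and report points absent from W
    wit_sys <- lapply(base, unclass)
    yside <- lapply(yside, function(z)
      cpp_newton(wit_sys, m1, as.complex(z), 1e-13, 20L)$z)
    missing <- Filter(function(z) {
      !any(vapply(w$points, function(q)
        max(abs(q - z)) / max(1, abs(q), abs(z)) < 1e-6, logical(1)))
    }, dedup_points(yside, 1e-6))
  }
  list(pass = pass, residual = resid,
       bidegree = c(sum(on_lp), sum(!on_lp)), missing_points = missing)
}

#' Identifiability degree by monodromy with trace-test certification
#'
#' Seeds a pseudowitness set at a random parameter point, grows it by
#' random monodromy loops, and after every enlargement runs the linear
#' trace test.  Stops when the trace test passes (certified) or when
#' `max_useless_loops` consecutive loops produce no new point.
#'
#' @param cmap an identifiable `ik_cmap` (corank 0).
#' @param max_useless_loops loop budget without progress.
#' @param settings a [path_settings()].
#' @return list with `k`, `witness` (`ik_witness`), `certified`, `n_W`,
#'   `deg_X`, `loops`, `census`.
#' @export
method4_degree <- function(cmap, max_useless_loops = 10L,
                           settings = path_settings()) {
  if (method1_dimension(cmap)$l > 0L)
    stop("unidentifiable; degree undefined")
  w <- witness_start(cmap)
  useless <- 0L; loops <- 0L
  while (useless < max_useless_loops) {
    loops <- loops + 1L
    step <- monodromy_loop(w, settings = settings)
    if (length(step$new_points) > 0L) {
      w$points <- c(w$points, step$new_points)
      useless <- 0L
    } else useless <- useless + 1L
  }
  tt <- trace_test(w, settings)
  certified <- isTRUE(tt$pass)
  if (certified && length(tt$missing_points) > 0L) {
    # the trace family certified points the loops had not yet discovered
    w$points <- c(w$points, tt$missing_points)
  }
  w$certified <- certified
  cnt <- witness_counts(w)
  cens <- table(vapply(cluster_points(witness_cvals(w)), length, integer(1)))
  list(k = cnt$k, witness = w, certified = certified, n_W = cnt$n_W,
       deg_X = cnt$deg_X, loops = loops, census = cens,
       trace = tt[c("residual", "bidegree")])
}

## ---- multihomogeneous (bilinear) trace test --------------------------------

#' Bilinear trace test on the graph curve of a coefficient map
#'
#' Restricts the graph of `cmap` to the line y = y0 + r*v in coefficient
#' space, intersects with the bilinear hyperplane family
#' H(t) = {ellp(p) * elly(y) = t}, finds all intersection points by a
#' total-degree homotopy at t = t0, certifies completeness by the linear
#' trace in t, and reports the bidegree by tracking t towards 0 and
#' classifying which factor each point lands on.
#'
#' @param cmap a polynomial `ik_cmap`.
#' @param y0,v complex vectors defining the line in coefficient space.
#' @param ellp affine functional on parameters: list(a = coeffs, b = const)
#'   meaning `sum(a * p) + b`.
#' @param elly affine functional on coefficient space, same format.
#' @param t0 base value of the family parameter.
#' @param settings a [path_settings()].
#' @return list with `pass`, `residual`, `bidegree`, `n_points`.
#' @export
bilinear_trace <- function(cmap, y0, v, ellp, elly, t0 = 1 + 0i,
                           settings = path_settings()) {
  m1 <- cmap$m1; m2 <- cmap$m2
  n <- m1 + 1L  # parameters plus the line coordinate r
  line_rows <- lapply(seq_len(m2), function(i) {
    e <- cmap$sys$polys[[i]]
    acc <- pl_remap(e, n, seq_len(m1))
    acc <- pl_add(acc, pl_const(n, -y0[i]))
    pl_add(acc, pl_scale(pl_var(n, n), -v[i]))
  })
  lp <- pl_const(n, ellp$b)
  for (j in which(ellp$a != 0 + 0i))
    lp <- pl_add(lp, pl_scale(pl_var(n, j), ellp$a[j]))
  # elly on the line: affine in r
  ly <- pl_const(n, elly$b + sum(elly$a * y0))
  ly <- pl_add(ly, pl_scale(pl_var(n, n), sum(elly$a * v)))
  bil <- function(tval) pl_add(pl_mul(lp, ly), pl_const(n, -tval))
  sys0 <- ik_system(c(line_rows, list(bil(t0))), c(cmap$params, ".r"))
  sol <- total_degree_solve(sys0, settings)
  pts <- sol$solutions
  if (length(pts) == 0L) stop("no intersection points found")
  # linear trace in t over two translates
  tau <- (0.3 + 0.4 * stats::runif(1)) * exp(2i * pi * stats::runif(1)) *
    max(1, abs(t0))
  sums <- list(Reduce(`+`, pts))
  for (step in 1:2) {
    shift <- step * tau
    hpolys <- c(lapply(line_rows, pl_remap, new_n = n + 1L, map = seq_len(n)),
                list({
                  bb <- pl_remap(bil(t0 + shift), n + 1L, seq_len(n))
                  pl_add(bb, pl_scale(pl_var(n + 1L, n + 1L), shift))
                }))
    hsys <- ik_system(hpolys, c(cmap$params, ".r", ".s"))
    res <- track(hsys, pts, "linear", settings = settings)
    if (any(vapply(res, function(r) r$status != "converged", logical(1))))
      return(list(pass = NA, residual = NA_real_, bidegree = NULL,
                  n_points = length(pts)))
    sums[[step + 1L]] <- Reduce(`+`, lapply(res, `[[`, "endpoint"))
  }
  dev <- (sums[[3L]] - sums[[1L]]) - 2 * (sums[[2L]] - sums[[1L]])
  resid <- max(abs(dev)) / max(1, max(abs(sums[[2L]] - sums[[1L]])))
  # bidegree: track t -> ~0 and classify by which factor degenerates
  eps <- 1e-3 * abs(t0)
  hpolys <- c(lapply(line_rows, pl_remap, new_n = n + 1L, map = seq_len(n)),
              list({
                bb <- pl_remap(bil(eps), n + 1L, seq_len(n))
                pl_add(bb, pl_scale(pl_var(n + 1L, n + 1L), -(t0 - eps)))
              }))
  hsys <- ik_system(hpolys, c(cmap$params, ".r", ".s"))
  res <- track(hsys, pts, "linear", settings = settings)
  okend <- Filter(function(r) r$status == "converged", res)
  cls <- vapply(okend, function(r) {
    abs(pl_eval(lp, r$endpoint)) < abs(pl_eval(ly, r$endpoint))
  }, logical(1))
  list(pass = resid < 1e-6, residual = resid,
       bidegree = c(sum(cls), sum(!cls)), n_points = length(pts))
}
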