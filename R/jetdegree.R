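# Identifiability degree without input-output equations: all parameter
# values consistent with a fixed truncated input/output are enumerated by
# monodromy on the jet system, then grouped by the next output coefficient.

# partially evaluate a polynomial: keep `keep_cols`, substitute the complex
# values in vals_full for every other variable
pl_partial_eval <- function(p, keep_cols, vals_full) {
  nk <- length(keep_cols)
  if (nrow(p$E) == 0L)
    return(structure(list(E = matrix(0L, 0L, nk), c = complex(0)),
                     class = "ikpoly"))
  cc <- p$c
  other <- setdiff(seq_len(ncol(p$E)), keep_cols)
  for (k in other) {
    e <- p$E[, k]
    if (any(e > 0L)) cc <- cc * vals_full[k]^e
  }
  pl_canon(structure(list(E = p$E[, keep_cols, drop = FALSE], c = cc),
                     class = "ikpoly"))
}

# square system over (p, X) from F_r with inputs and outputs fixed; the jet
# equations are affine in the output jets, so a loop direction delta in
# output space contributes the s-linear part sum_j delta_j * d(row)/d(y_j)
jet_io_system <- function(js, uvals, yvals, delta = NULL) {
  keep <- c(js$p_cols, js$x_cols)
  nbig <- js$n
  vals <- complex(nbig)
  if (length(js$u_cols)) vals[js$u_cols] <- uvals
  vals[js$y_cols] <- yvals
  base <- lapply(js$polys, pl_partial_eval, keep_cols = keep,
                 vals_full = vals)
  vars <- js$vars[keep]
  if (is.null(delta)) return(ik_system(base, vars))
  nk <- length(keep)
  hpolys <- lapply(seq_along(js$polys), function(i) {
    acc <- pl_remap(base[[i]], nk + 1L, seq_len(nk))
    row <- js$polys[[i]]
    for (jj in seq_along(js$y_cols)) {
      if (delta[jj] == 0 + 0i) next
      slope <- pl_deriv(row, js$y_cols[jj])
      if (pl_is_zero(slope)) next
      slope <- pl_partial_eval(slope, keep_cols = keep, vals_full = vals)
      acc <- pl_add(acc, pl_mul(
        pl_scale(pl_var(nk + 1L, nk + 1L), delta[jj]),
        pl_remap(slope, nk + 1L, seq_len(nk))))
    }
    acc
  })
  ik_system(hpolys, c(vars, ".s"))
}

# random square-up: n random combinations of the given polynomials
squareup <- function(polys, n, nvars) {
  A <- matrix(rand_complex(n * length(polys)), n, length(polys))
  lapply(seq_len(n), function(i) {
    acc <- pl_zero(nvars)
    for (j in seq_along(polys)) acc <- pl_add(acc, pl_scale(polys[[j]], A[i, j]))
    acc
  })
}

# next output jet coefficients of a solution (orders r+1 .. r+extend)
extend_outputs <- function(model, js, z, extend = 1L) {
  r <- js$order; ns <- js$ns; m1 <- js$m1; ni <- js$ni
  p <- z[js$p_cols]
  X <- matrix(z[m1 + seq_len(ns * (r + 2L))], ns, r + 2L)
  L <- r + 2L
  if (extend > 1L) stop("output extension beyond one jet order needs input jets that are not part of F_r")
  vals <- c(lapply(seq_len(ns), function(s) X[s, 1:L]),
            lapply(seq_len(m1), function(k) c(p[k], complex(L - 1L))))
  vapply(seq_len(js$no), function(o) {
    nn <- nser_poly(model$output_exprs[[o]]$num, vals, L)
    dd <- nser_poly(model$output_exprs[[o]]$den, vals, L)
    nser_div(nn, dd)[L]
  }, complex(1))
}

#' Identifiability degree from the jet system (no input-output equations)
#'
#' Fixes a truncated input/output (a supplied one, or the jets of a random
#' generic trajectory), enumerates all (parameter, state-jet) solutions of
#' F_r with that input-output by monodromy loops in output-jet space,
#' extends every solution by one more output coefficient y_{r+1}, and
#' clusters the solutions by the extended output: solutions in one cluster
#' have the same input-output behaviour, so the identifiability degree is
#' the size of the cluster containing the seed solution.  A census of all
#' cluster sizes is reported, and unequal cluster sizes raise a warning.
#'
#' @param model an `ik_model`.
#' @param r truncation order (the jet dimension table of
#'   [method2_dimension()] must have reached d_r = 0 by this order).
#' @param Y optional output jets (matrix outputs x (r+1), or vector for one
#'   output), derivative-normalized.
#' @param U optional input jets in the same layout.
#' @param max_useless_loops monodromy budget without progress.
#' @param settings a [path_settings()].
#' @param cluster_tol relative tolerance for output clustering.
#' @return list with `k`, `n_solutions`, `params` (parameter parts),
#'   `y_next` (extended output coefficients), `clusters`, `census`,
#'   `seed_cluster`, `solutions`.
#' @export
jet_degree <- function(model, r, Y = NULL, U = NULL,
                       max_useless_loops = 10L,
                       settings = path_settings(), cluster_tol = 1e-6) {
  js <- truncate_model(model, r)
  ns <- js$ns; no <- js$no; ni <- js$ni; m1 <- js$m1
  pt <- seed_point(js)
  z0full <- pt$assignment
  ustar <- if (ni > 0L) z0full[js$u_cols] else complex(0)
  ystar <- z0full[js$y_cols]
  if (is.null(U)) U <- ustar else U <- as.complex(t(U))
  if (!is.null(Y)) Y <- as.complex(t(Y)) else Y <- ystar
  keep <- c(js$p_cols, js$x_cols)
  nk <- length(keep)
  z0 <- unname(z0full[keep])

  neq <- length(js$polys)
  if (neq < nk)
    stop("jet system is underdetermined in (p, X); the state fiber is ",
         "positive-dimensional - raise r or add state slices")

  solve_residual <- function(sys, z) {
    v <- cpp_eval_system(lapply(sys$polys, unclass), sys$n, unname(z), FALSE)$value
    max(abs(v)) / max(1, max(abs(z)))
  }

  base_sys <- jet_io_system(js, U, Y)
  # move the seed trajectory to the requested input-output along a complex arc
  if (max(abs(Y - ystar)) > 0 || (ni > 0L && max(abs(U - ustar)) > 0)) {
    if (ni > 0L && max(abs(U - ustar)) > 0)
      stop("tracking to a supplied input is not implemented; supply Y only")
    hsys <- jet_io_system(js, U, Y, delta = ystar - Y)
    tr <- track(hsys, list(z0), "gamma", settings = settings)[[1L]]
    if (tr$status != "converged")
      stop("could not track the seed trajectory to the supplied output")
    z0 <- tr$endpoint
  }
  sols <- list(z0)
  useless <- 0L; loops <- 0L
  yscale <- 1 + max(abs(Y))
  while (useless < max_useless_loops) {
    loops <- loops + 1L
    delta <- rand_complex(no * (r + 1L)) * yscale *
      10^stats::runif(1, -1, 0.5)
    hsys <- jet_io_system(js, U, Y, delta = delta)
    res <- track(hsys, sols, "circle", settings = settings)
    ok <- vapply(res, function(x) x$status == "converged", logical(1))
    ends <- lapply(res[ok], `[[`, "endpoint")
    ends <- Filter(function(z) solve_residual(base_sys, z) < 1e-8, ends)
    new <- Filter(function(z) {
      !any(vapply(sols, function(q)
        max(abs(q - z)) / max(1, abs(q), abs(z)) < 1e-6, logical(1)))
    }, ends)
    new <- dedup_points(new, 1e-6)
    if (length(new) > 0L) { sols <- c(sols, new); useless <- 0L }
    else useless <- useless + 1L
  }
  ynext <- lapply(sols, function(z) extend_outputs(model, js, z))
  clusters <- cluster_points(ynext, cluster_tol)
  sizes <- vapply(clusters, length, integer(1))
  seed_cluster <- which(vapply(clusters, function(g) 1L %in% g, logical(1)))
  if (length(unique(sizes)) > 1L)
    warning("unequal input-output cluster sizes: ",
            paste(sizes, collapse = ", "))
  list(k = sizes[seed_cluster], n_solutions = length(sols),
       params = lapply(sols, function(z) z[seq_len(m1)]),
       y_next = ynext, clusters = clusters, census = sizes,
       seed_cluster = seed_cluster, solutions = sols, loops = loops,
       jetsys = js)
}
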