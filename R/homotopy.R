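# Predictor-corrector path tracking, total-degree start systems, linear
# slices and slice-moving homotopies.
#
# Every homotopy is a polynomial system in (z, s) whose last variable s is
# mapped to the tracking parameter t in [1, 0] by one of three smooth paths:
# linear (s = t), a monodromy circle s = 1 - exp(2*pi*i*(1-t)), or a complex
# gamma segment s = gamma*t / (1 + (gamma-1)*t).  The predictor is RK4 on
# the Davidenko ODE and the corrector is Newton's method; steps halve on
# corrector failure and endpoints are Newton-polished at t = 0.

#' Path-tracking settings
#'
#' @param initial_step initial step in t.
#' @param min_step smallest step before a path is declared singular.
#' @param newton_tol relative Newton-step tolerance of the corrector.
#' @param max_newton corrector iterations per step.
#' @param endpoint_tol relative tolerance of the endpoint polish.
#' @param max_steps step budget per path.
#' @param divergence_bound declare divergence when |z| exceeds this.
#' @export
path_settings <- function(initial_step = 0.05, min_step = 1e-8,
                          newton_tol = 1e-9, max_newton = 3L,
                          endpoint_tol = 1e-13, max_steps = 20000L,
                          divergence_bound = 1e8) {
  stopifnot(min_step < initial_step, newton_tol > 0, endpoint_tol > 0)
  structure(list(initial_step = initial_step, min_step = min_step,
                 newton_tol = newton_tol, max_newton = max_newton,
                 endpoint_tol = endpoint_tol, max_steps = max_steps,
                 divergence_bound = divergence_bound),
            class = "ik_path_settings")
}

settings_vec <- function(s) {
  c(s$initial_step, s$min_step, s$newton_tol, s$max_newton, s$endpoint_tol,
    s$max_steps, s$divergence_bound)
}

status_labels <- c("converged", "diverged", "singular", "step-limit")

#' Track solution paths of a homotopy
#'
#' @param hsys an `iksys` whose last variable is the path variable s.
#' @param starts list of complex start vectors (solutions at t = 1).
#' @param stype path type: `"linear"`, `"circle"` (monodromy loop) or
#'   `"gamma"` (complex segment avoiding the real discriminant).
#' @param gamma complex constant for the gamma segment.
#' @param settings a [path_settings()] object.
#' @return list of track results: each has `endpoint`, `status`, `residual`,
#'   `steps_taken`.
#' @export
track <- function(hsys, starts, stype = c("linear", "circle", "gamma"),
                  gamma = NULL, settings = path_settings()) {
  stype <- match.arg(stype)
  code <- match(stype, c("linear", "circle", "gamma")) - 1L
  if (is.null(gamma)) gamma <- exp(2i * pi * stats::runif(1))
  res <- cpp_track(lapply(hsys$polys, unclass), hsys$n - 1L,
                   lapply(starts, function(z) unname(as.complex(z))),
                   code, as.complex(gamma), settings_vec(settings))
  lapply(res, function(r) {
    list(endpoint = r$z, status = status_labels[r$status + 1L],
         residual = r$residual, steps_taken = r$steps)
  })
}

# track with one retry at a tenth of the initial step for failed paths
track_retry <- function(hsys, starts, stype = "linear", gamma = NULL,
                        settings = path_settings()) {
  res <- track(hsys, starts, stype, gamma = gamma, settings = settings)
  bad <- which(vapply(res, function(r) r$status != "converged", logical(1)))
  if (length(bad) > 0L) {
    tight <- settings
    tight$initial_step <- settings$initial_step / 10
    tight$min_step <- min(settings$min_step, 1e-10)
    tight$max_steps <- settings$max_steps * 4L
    res2 <- track(hsys, starts[bad], stype, gamma = gamma, settings = tight)
    for (i in seq_along(bad))
      if (res2[[i]]$status == "converged") res[[bad[i]]] <- res2[[i]]
  }
  res
}

# append a path-variable column to a system's polynomials
with_pathvar <- function(sys) {
  n <- sys$n
  ik_system(lapply(sys$polys, pl_remap, new_n = n + 1L, map = seq_len(n)),
            c(sys$vars, ".s"))
}

#' Solve a square polynomial system by a total-degree homotopy
#'
#' Uses the start system z_i^{d_i} = b_i with random complex b_i and the
#' gamma trick; tracks all prod(d_i) paths and returns the deduplicated
#' finite nonsingular endpoints.
#'
#' @param sys a square `iksys` (as many polynomials as variables).
#' @param settings a [path_settings()].
#' @param cluster_tol relative tolerance for endpoint deduplication.
#' @return list with `solutions` (list of complex vectors), `n_paths`,
#'   `path_status` (table of statuses).
#' @export
total_degree_solve <- function(sys, settings = path_settings(),
                               cluster_tol = 1e-6) {
  n <- sys$n
  if (length(sys$polys) != n)
    stop("total-degree homotopy needs a square system (", length(sys$polys),
         " equations in ", n, " variables)")
  degs <- sys_degrees(sys)
  if (any(degs < 1L)) stop("every equation must have positive degree")
  b <- rand_complex(n) * 2
  gamma <- exp(2i * pi * stats::runif(1))
  # H_i = F_i + s * (gamma * (z_i^d_i - b_i) - F_i)
  hpolys <- lapply(seq_len(n), function(i) {
    Fi <- pl_remap(sys$polys[[i]], n + 1L, seq_len(n))
    Si <- pl_add(pl_var(n + 1L, i, degs[i]), pl_const(n + 1L, -b[i]))
    sFi <- pl_mul(pl_var(n + 1L, n + 1L), pl_sub(pl_scale(Si, gamma), Fi))
    pl_add(Fi, sFi)
  })
  hsys <- ik_system(hpolys, c(sys$vars, ".s"))
  roots <- lapply(seq_len(n), function(i) {
    d <- degs[i]
    b[i]^(1 / d) * exp(2i * pi * (0:(d - 1L)) / d)
  })
  grid <- do.call(expand.grid, lapply(degs, seq_len))
  starts <- lapply(seq_len(nrow(grid)), function(k)
    vapply(seq_len(n), function(i) roots[[i]][grid[k, i]], complex(1)))
  res <- track(hsys, starts, "linear", settings = settings)
  status <- vapply(res, `[[`, character(1), "status")
  good <- lapply(res[status == "converged"], `[[`, "endpoint")
  # guard against coincident endpoints from genuinely distinct paths:
  # polish every converged endpoint before deduplication
  good <- lapply(good, function(z)
    cpp_newton(lapply(sys$polys, unclass), n, as.complex(z), 1e-14, 10L)$z)
  list(solutions = dedup_points(good, cluster_tol),
       n_paths = length(starts), path_status = table(status))
}

## ---- linear slices ---------------------------------------------------------

#' Random linear slice through a point
#'
#' Rows are random complex; constants are chosen so the point satisfies the
#' slice exactly.  When `codimension` equals the ambient dimension the slice
#' is the single point itself.
#'
#' @param point complex vector.
#' @param codimension number of slice rows.
#' @param ambient ambient dimension (defaults to `length(point)`).
#' @return an `ik_slice`: list with `A`, `b`, `codimension`.
#' @export
random_slice_through <- function(point, codimension,
                                 ambient = length(point)) {
  if (codimension > ambient)
    stop("slice codimension exceeds the ambient dimension")
  A <- matrix(rand_complex(codimension * ambient), codimension, ambient)
  structure(list(A = A, b = as.complex(A %*% point),
                 codimension = codimension), class = "ik_slice")
}

slice_residual <- function(slice, point) {
  max(abs(slice$A %*% point - slice$b))
}

# polynomial rows of a slice acting on the given columns of an nbig-variable
# system
slice_polys <- function(slice, cols, nbig) {
  lapply(seq_len(slice$codimension), function(i) {
    terms <- lapply(which(slice$A[i, ] != 0 + 0i), function(j)
      pl_scale(pl_var(nbig, cols[j]), slice$A[i, j]))
    acc <- pl_const(nbig, -slice$b[i])
    for (tm in terms) acc <- pl_add(acc, tm)
    acc
  })
}

#' Move a point from one linear slice to another along its variety
#'
#' Tracks the combined system {constraints = 0, t*slice_from +
#' (1-t)*slice_to = 0} from t = 1 to t = 0 by the literal linear
#' interpolation of the two slices.  The endpoint lies on the constraint
#' variety intersected with `slice_to`.
#'
#' @param constraints an `iksys` vanishing on the variety.
#' @param point start point satisfying constraints and `slice_from`.
#' @param slice_from,slice_to `ik_slice`s of equal codimension.
#' @param cols variable columns the slices act on (default all).
#' @param settings a [path_settings()].
#' @return a track result (see [track()]).
#' @export
move_slice <- function(constraints, point, slice_from, slice_to,
                       cols = seq_len(constraints$n),
                       settings = path_settings()) {
  n <- constraints$n
  if (slice_from$codimension != slice_to$codimension)
    stop("slices must have equal codimension")
  base <- lapply(constraints$polys, pl_remap, new_n = n + 1L,
                 map = seq_len(n))
  from_rows <- slice_polys(slice_from, cols, n)
  to_rows <- slice_polys(slice_to, cols, n)
  moving <- lapply(seq_along(to_rows), function(i) {
    toi <- pl_remap(to_rows[[i]], n + 1L, seq_len(n))
    fri <- pl_remap(from_rows[[i]], n + 1L, seq_len(n))
    pl_add(toi, pl_mul(pl_var(n + 1L, n + 1L), pl_sub(fri, toi)))
  })
  hsys <- ik_system(c(base, moving), c(constraints$vars, ".s"))
  track(hsys, list(point), "linear", settings = settings)[[1L]]
}
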