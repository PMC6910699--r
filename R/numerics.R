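# Numeric rank decisions, point clustering, nullspaces.

#' Numeric corank of (the last N - j columns of) a complex matrix
#'
#' Singular values are compared against `tol` times the largest singular
#' value of the considered block; the rank is the number kept and the corank
#' the number dropped.  A singular value within a factor 100 of the
#' threshold flags the decision as ambiguous, in which case callers should
#' re-evaluate at a fresh generic point.
#'
#' @param M complex matrix.
#' @param j column offset: the corank is computed on the last
#'   `ncol(M) - j` columns (`j = 0` uses the whole matrix).
#' @param tol relative singular-value threshold.
#' @param guard multiplicative half-width of the ambiguity band around the
#'   threshold.
#' @param method `"threshold"` keeps singular values above `tol` times the
#'   largest; `"gap"` instead places the zero group below the largest
#'   relative gap inside the small-singular-value region (used for jet
#'   Jacobians, whose genuine singular values decay with the order while
#'   true zeros stay at the machine floor).
#' @param equilibrate scale rows and then columns to unit maximum modulus
#'   before the SVD.  Exact rank is invariant under such diagonal scalings,
#'   and jet-system Jacobians need it: derivative-normalized jets grow
#'   factorially with the order, which otherwise spreads the singular values
#'   of a full-rank matrix across the rank threshold.
#' @return an object of class `ik_rank_report`: list with `rank`, `corank`,
#'   `singular_values`, `tolerance_used`, `column_offset`, `ambiguous`.
#' @export
numeric_corank <- function(M, j = 0L, tol = 1e-8, equilibrate = FALSE,
                           guard = 100, method = c("threshold", "gap")) {
  method <- match.arg(method)
  j <- as.integer(j)
  if (j > ncol(M)) stop("column offset exceeds the number of columns")
  B <- M[, seq.int(j + 1L, length.out = ncol(M) - j), drop = FALSE]
  if (equilibrate && nrow(B) > 0L && ncol(B) > 0L) {
    rs <- apply(abs(B), 1L, max); rs[rs == 0] <- 1
    B <- B / rs
    cs <- apply(abs(B), 2L, max); cs[cs == 0] <- 1
    B <- sweep(B, 2L, cs, "/")
  }
  if (ncol(B) == 0L) {
    return(structure(list(rank = 0L, corank = 0L, singular_values = numeric(0),
                          tolerance_used = tol, column_offset = j,
                          ambiguous = FALSE), class = "ik_rank_report"))
  }
  sv <- svd(B, nu = 0, nv = 0)$d
  if (identical(method, "gap")) {
    # numerical-zero group = below the largest relative gap found inside the
    # small-singular-value region; robust when genuine singular values decay
    # with the jet order while true zeros stay at the machine floor
    rel <- sv / max(sv, .Machine$double.xmin)
    nz <- sum(rel >= 1e-6)
    rank <- length(sv)
    ambiguous <- FALSE
    if (nz < length(sv)) {
      cand <- seq.int(max(nz, 1L), length(sv) - 1L)
      ratios <- rel[cand] / pmax(rel[cand + 1L], .Machine$double.xmin)
      best <- which.max(ratios)
      if (ratios[best] >= 1e4) rank <- cand[best]
      else if (ratios[best] >= 1e2) ambiguous <- TRUE
    }
    if (rel[1L] < 1e-12) rank <- 0L   # numerically zero matrix
  } else {
    thresh <- tol * max(sv, .Machine$double.xmin)
    rank <- sum(sv > thresh)
    ambiguous <- any(sv > thresh / guard & sv < thresh * guard)
  }
  structure(list(rank = rank, corank = ncol(B) - rank, singular_values = sv,
                 tolerance_used = tol, column_offset = j,
                 ambiguous = ambiguous), class = "ik_rank_report")
}

#' @export
print.ik_rank_report <- function(x, ...) {
  cat(sprintf("<rank %d, corank %d (offset %d, tol %.1e%s)>\n", x$rank,
              x$corank, x$column_offset, x$tolerance_used,
              if (x$ambiguous) ", AMBIGUOUS" else ""))
  invisible(x)
}

rank_report_json <- function(x) {
  jsonlite::toJSON(list(rank = x$rank, corank = x$corank,
                        singular_values = x$singular_values,
                        tolerance_used = x$tolerance_used,
                        column_offset = x$column_offset), auto_unbox = TRUE,
                   digits = NA)
}

#' Jacobian of a polynomial or rational system at a complex point
#'
#' Entry (i, j) is the exact partial derivative of equation i with respect
#' to variable j, obtained by term-wise differentiation of the sparse
#' tables (quotient rule for rational entries).
#'
#' @param system an `iksys`, a list of rational-function pairs, or an
#'   `ik_cmap` coefficient map.
#' @param point complex vector matching the system's variables.
#' @return complex matrix.
#' @export
jacobian_at <- function(system, point) {
  if (inherits(system, "ik_cmap")) system <- system$exprs
  if (inherits(system, "iksys")) {
    out <- matrix(complex(length(system$polys) * system$n),
                  length(system$polys), system$n)
    for (i in seq_along(system$polys))
      for (k in seq_len(system$n))
        out[i, k] <- pl_eval(pl_deriv(system$polys[[i]], k), point)
    return(out)
  }
  # list of rational pairs
  n <- ncol(system[[1L]]$num$E)
  out <- matrix(complex(length(system) * n), length(system), n)
  for (i in seq_along(system)) {
    dval <- pl_eval(system[[i]]$den, point)
    if (abs(dval) < 1e-13)
      stop("denominator of equation ", i, " vanishes at the evaluation point")
    for (k in seq_len(n))
      out[i, k] <- rp_eval(rp_deriv(system[[i]], k), point)
  }
  out
}

#' Cluster complex points by relative distance
#'
#' Groups are the transitive closure of the relation "relative distance
#' below `tol`"; group order is stable by first member.
#'
#' @param points list of complex vectors of equal length.
#' @param tol relative distance threshold.
#' @return list of integer index vectors.
#' @export
cluster_points <- function(points, tol = 1e-6) {
  np <- length(points)
  if (np == 0L) return(list())
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(np - 1L)) for (k in seq.int(i + 1L, np)) {
    scale <- max(1, abs(points[[i]]), abs(points[[k]]))
    if (max(abs(points[[i]] - points[[k]])) / scale < tol) {
      ri <- find(i); rk <- find(k)
      if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  split(seq_len(np), match(roots, unique(roots)))
}

# deduplicate a list of complex vectors, keeping first representatives
dedup_points <- function(points, tol = 1e-6) {
  groups <- cluster_points(points, tol)
  points[vapply(groups, `[`, integer(1), 1L)]
}

# right nullspace (columns) of a complex or real matrix by SVD
nullspace <- function(M, tol = 1e-8) {
  if (nrow(M) == 0L) return(diag(ncol(M)) + 0i)
  s <- svd(M, nu = 0, nv = ncol(M))
  keep <- c(s$d, numeric(ncol(M) - length(s$d))) <= tol * max(s$d, 1e-300)
  s$v[, keep, drop = FALSE]
}
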