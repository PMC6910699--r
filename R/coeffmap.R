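# Coefficient maps c : C^m1 -> C^m2 of input-output equations.

#' Elementary symmetric polynomial
#'
#' `E_k(z_1, ..., z_m)` is the sum over all size-`k` subsets of products;
#' `E_0 = 1`.
#'
#' @param k subset size, `0 <= k <= length(values)`.
#' @param values numeric or complex vector.
#' @export
elementary_symmetric <- function(k, values) {
  m <- length(values)
  if (k < 0 || k > m) stop("k out of range 0..", m)
  # Newton-free DP on the product prod (1 + z_i t)
  e <- c(1 + 0i, complex(m))
  for (z in as.complex(values)) {
    e[2:(m + 1L)] <- e[2:(m + 1L)] + z * e[1:m]
  }
  out <- e[k + 1L]
  if (all(Im(out) == 0)) Re(out) else out
}

#' Construct a coefficient map from expression strings
#'
#' @param coeffs character vector of rational expressions in the parameters.
#' @param params ordered parameter names.
#' @param name identifier for reports.
#' @return an object of class `ik_cmap`.
#' @export
coefficient_map <- function(coeffs, params, name = "c") {
  exprs <- lapply(coeffs, parse_rational, vars = params)
  polynomial <- all(vapply(exprs, rp_is_poly, logical(1)))
  sys <- if (polynomial) ik_system(lapply(exprs, `[[`, "num"), params) else NULL
  structure(list(params = params, exprs = exprs, text = coeffs, name = name,
                 m1 = length(params), m2 = length(coeffs),
                 polynomial = polynomial, sys = sys), class = "ik_cmap")
}

#' @export
print.ik_cmap <- function(x, ...) {
  cat(sprintf("<ik_cmap '%s': C^%d -> C^%d%s>\n", x$name, x$m1, x$m2,
              if (x$polynomial) "" else " (rational)"))
  invisible(x)
}

#' Evaluate a coefficient map at a parameter point
#'
#' @param cmap an `ik_cmap`.
#' @param p complex (or numeric) parameter vector.
#' @return complex vector of length `m2`.
#' @export
cmap_eval <- function(cmap, p) {
  vapply(cmap$exprs, rp_eval, complex(1), z = as.complex(p))
}

ik_cmap_fixtures <- c("linear3_c", "linear3_noleak13_c", "fourcomp_c")

#' Built-in coefficient maps
#'
#' The published input-output coefficient maps of the benchmark models: the
#' five elementary-symmetric coefficients of the three-compartment model
#' with all leaks (`linear3_c`, 7 parameters), the five coefficients of the
#' same model with leaks 1 and 3 removed (`linear3_noleak13_c`, 5
#' parameters), and the seven transfer-function coefficients of the
#' four-compartment model (`fourcomp_c`, 10 parameters).
#'
#' @param name fixture name.
#' @return an `ik_cmap`.
#' @export
coefficient_fixture <- function(name) {
  switch(name,
    linear3_c = {
      A <- "(-(k01 + k21))"; B <- "(-(k02 + k12 + k32))"; C <- "(-(k03 + k13))"
      coefficient_map(c(
        sprintf("%s + %s + %s", A, B, C),
        sprintf("%s*%s + %s*%s + %s*%s - k12*k21", A, B, A, C, B, C),
        sprintf("%s*%s*%s + k13*k32*k21 + k12*k21*(k03 + k13)", A, B, C),
        sprintf("%s + %s", B, C),
        sprintf("%s*%s", B, C)),
        params = c("k01", "k02", "k03", "k12", "k13", "k21", "k32"),
        name = "linear3_c")
    },
    linear3_noleak13_c = coefficient_map(c(
      "k02 + k12 + k13 + k21 + k32",
      "k02*k13 + k02*k21 + k12*k13 + k13*k21 + k13*k32 + k21*k32",
      "k02*k13*k21",
      "k02 + k12 + k13 + k32",
      "k02*k13 + k12*k13 + k13*k32"),
      params = c("k02", "k12", "k13", "k21", "k32"),
      name = "linear3_noleak13_c"),
    fourcomp_c = coefficient_map(c(
      "a11*a23*a34*a42 + a12*a21*a34*a43 - a11*a22*a34*a43 - a12*a21*a33*a44 + a11*a22*a33*a44",
      "a12*a21*a33 - a11*a22*a33 - a23*a34*a42 + a11*a34*a43 + a22*a34*a43 + a12*a21*a44 - a11*a22*a44 - a11*a33*a44 - a22*a33*a44",
      "a11*a22 - a12*a21 + a11*a33 + a11*a44 + a22*a33 + a22*a44 + a33*a44 - a34*a43",
      "-(a11 + a22 + a33 + a44)",
      "a23*a34*a42 - a22*a34*a43 + a22*a33*a44",
      "-a22*a33 + a34*a43 - a22*a44 - a33*a44",
      "a22 + a33 + a44"),
      params = c("a11", "a12", "a21", "a22", "a23", "a33", "a34", "a42",
                 "a43", "a44"),
      name = "fourcomp_c"),
    stop("unknown coefficient map '", name, "'; available: ",
         paste(ik_cmap_fixtures, collapse = ", "))
  )
}

#' Dimension of unidentifiability from input-output coefficients
#'
#' The dimension of a generic fiber of the coefficient map equals the corank
#' of its Jacobian at a random complex parameter point.  The corank is
#' recomputed at a second independent point as a consistency check.
#'
#' @param cmap an `ik_cmap`.
#' @param tol rank tolerance passed to [numeric_corank()].
#' @return list with `l` (the dimension of unidentifiability) and `report`
#'   (an `ik_rank_report`).
#' @export
method1_dimension <- function(cmap, tol = 1e-8) {
  rep1 <- numeric_corank(jacobian_at(cmap, rand_complex(cmap$m1)), 0L, tol)
  rep2 <- numeric_corank(jacobian_at(cmap, rand_complex(cmap$m1)), 0L, tol)
  if (rep1$corank != rep2$corank)
    stop("corank disagrees between two random points (", rep1$corank, " vs ",
         rep2$corank, "); review the rank tolerance")
  list(l = rep1$corank, report = rep1)
}
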