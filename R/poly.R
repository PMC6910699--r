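# Sparse multivariate polynomials over the complex numbers.
#
# A polynomial is a list(E, c) where E is an integer exponent matrix with one
# row per term (columns indexed by a shared variable vector) and c is the
# complex coefficient vector.  These tables back every system the package
# tracks or differentiates: coefficient maps, jet systems, slices and
# homotopies all reduce to them, and derivatives are exact (term-wise), so
# corank decisions never rest on finite differences.

pl_zero <- function(n) {
  structure(list(E = matrix(0L, 0L, n), c = complex(0)), class = "ikpoly")
}

pl_const <- function(n, val) {
  if (is.numeric(val)) val <- complex(real = val, imaginary = 0)
  if (val == 0 + 0i) return(pl_zero(n))
  structure(list(E = matrix(0L, 1L, n), c = as.complex(val)), class = "ikpoly")
}

pl_var <- function(n, k, pow = 1L) {
  E <- matrix(0L, 1L, n)
  E[1L, k] <- as.integer(pow)
  structure(list(E = E, c = as.complex(1)), class = "ikpoly")
}

pl_is_zero <- function(p) nrow(p$E) == 0L

# Merge duplicate terms and drop exact zeros.
pl_canon <- function(p) {
  if (nrow(p$E) <= 1L) {
    if (nrow(p$E) == 1L && p$c[1L] == 0 + 0i) return(pl_zero(ncol(p$E)))
    return(p)
  }
  key <- do.call(paste, c(lapply(seq_len(ncol(p$E)), function(j) p$E[, j]),
                          list(sep = ",")))
  grp <- match(key, unique(key))
  cc <- as.complex(rowsum(Re(p$c), grp)[, 1L]) +
    1i * as.complex(rowsum(Im(p$c), grp)[, 1L])
  E <- p$E[!duplicated(grp), , drop = FALSE]
  keep <- cc != 0 + 0i
  structure(list(E = E[keep, , drop = FALSE], c = cc[keep]), class = "ikpoly")
}

pl_add <- function(a, b) {
  pl_canon(structure(list(E = rbind(a$E, b$E), c = c(a$c, b$c)),
                     class = "ikpoly"))
}

pl_sum <- function(ps) {
  ps <- ps[!vapply(ps, pl_is_zero, logical(1))]
  if (length(ps) == 0L) stop("pl_sum of empty list needs a variable count")
  pl_canon(structure(list(E = do.call(rbind, lapply(ps, `[[`, "E")),
                          c = do.call(c, lapply(ps, `[[`, "c"))),
                     class = "ikpoly"))
}

pl_scale <- function(p, s) {
  if (s == 0 + 0i || pl_is_zero(p)) return(pl_zero(ncol(p$E)))
  structure(list(E = p$E, c = p$c * as.complex(s)), class = "ikpoly")
}

pl_neg <- function(p) pl_scale(p, -1)

pl_sub <- function(a, b) pl_add(a, pl_neg(b))

pl_mul <- function(a, b) {
  na <- nrow(a$E); nb <- nrow(b$E)
  if (na == 0L || nb == 0L) return(pl_zero(ncol(a$E)))
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  pl_canon(structure(list(E = a$E[ia, , drop = FALSE] + b$E[ib, , drop = FALSE],
                          c = a$c[ia] * b$c[ib]), class = "ikpoly"))
}

pl_pow <- function(p, k) {
  k <- as.integer(k)
  if (k < 0L) stop("negative polynomial power")
  out <- pl_const(ncol(p$E), 1)
  while (k > 0L) {
    out <- pl_mul(out, p)
    k <- k - 1L
  }
  out
}

pl_deriv <- function(p, k) {
  keep <- p$E[, k] > 0L
  if (!any(keep)) return(pl_zero(ncol(p$E)))
  E <- p$E[keep, , drop = FALSE]
  cc <- p$c[keep] * E[, k]
  E[, k] <- E[, k] - 1L
  pl_canon(structure(list(E = E, c = cc), class = "ikpoly"))
}

pl_eval <- function(p, z) {
  if (nrow(p$E) == 0L) return(0 + 0i)
  val <- p$c
  use <- which(colSums(p$E) > 0L)
  for (k in use) val <- val * z[k]^p$E[, k]
  sum(val)
}

pl_degree <- function(p) {
  if (nrow(p$E) == 0L) return(0L)
  as.integer(max(rowSums(p$E)))
}

# Compose: substitute subs[[j]] (a polynomial over the new variable set)
# for old variable j.
pl_compose <- function(p, subs, new_n) {
  acc <- pl_zero(new_n)
  for (i in seq_len(nrow(p$E))) {
    term <- pl_const(new_n, p$c[i])
    for (k in which(p$E[i, ] > 0L))
      term <- pl_mul(term, pl_pow(subs[[k]], p$E[i, k]))
    acc <- pl_add(acc, term)
  }
  acc
}

# Re-embed a polynomial into a larger variable set; map[j] gives the new
# column of old variable j.
pl_remap <- function(p, new_n, map) {
  E <- matrix(0L, nrow(p$E), new_n)
  E[, map] <- p$E
  structure(list(E = E, c = p$c), class = "ikpoly")
}

## ---- rational functions: pairs of polynomial tables -----------------------

rp_make <- function(num, den) {
  # normalize constant denominators away
  if (nrow(den$E) == 1L && all(den$E == 0L)) {
    num <- pl_scale(num, 1 / den$c[1L])
    den <- pl_const(ncol(den$E), 1)
  }
  list(num = num, den = den)
}

rp_const <- function(n, v) rp_make(pl_const(n, v), pl_const(n, 1))
rp_var <- function(n, k) rp_make(pl_var(n, k), pl_const(n, 1))

rp_is_poly <- function(r) nrow(r$den$E) == 1L && all(r$den$E == 0L) &&
  r$den$c[1L] == 1 + 0i

rp_add <- function(a, b) {
  if (rp_is_poly(a) && rp_is_poly(b)) return(rp_make(pl_add(a$num, b$num), a$den))
  rp_make(pl_add(pl_mul(a$num, b$den), pl_mul(b$num, a$den)),
          pl_mul(a$den, b$den))
}
rp_neg <- function(a) list(num = pl_neg(a$num), den = a$den)
rp_sub <- function(a, b) rp_add(a, rp_neg(b))
rp_mul <- function(a, b) rp_make(pl_mul(a$num, b$num), pl_mul(a$den, b$den))
rp_div <- function(a, b) {
  if (pl_is_zero(b$num)) stop("division by the zero polynomial")
  rp_make(pl_mul(a$num, b$den), pl_mul(a$den, b$num))
}
rp_pow <- function(a, k) {
  k <- as.integer(k)
  if (k >= 0L) list(num = pl_pow(a$num, k), den = pl_pow(a$den, k))
  else list(num = pl_pow(a$den, -k), den = pl_pow(a$num, -k))
}

rp_eval <- function(r, z) pl_eval(r$num, z) / pl_eval(r$den, z)

# d(n/d) = (n'd - nd')/d^2
rp_deriv <- function(r, k) {
  if (rp_is_poly(r)) return(rp_make(pl_deriv(r$num, k), r$den))
  rp_make(pl_sub(pl_mul(pl_deriv(r$num, k), r$den),
                 pl_mul(r$num, pl_deriv(r$den, k))),
          pl_mul(r$den, r$den))
}

## ---- parsing R expressions into rational polynomial tables ----------------

# Parse a single arithmetic expression (given as a string) over the declared
# variables.  Accepts + - * / ^ and ** (the R parser maps ** to ^); any
# undeclared symbol is an error naming that symbol.
parse_rational <- function(text, vars) {
  n <- length(vars)
  rec <- function(e) {
    if (is.numeric(e)) return(rp_const(n, e))
    if (is.complex(e)) return(rp_const(n, e))
    if (is.symbol(e)) {
      k <- match(as.character(e), vars)
      if (is.na(k)) stop(sprintf("undeclared symbol '%s'", as.character(e)),
                         call. = FALSE)
      return(rp_var(n, k))
    }
    if (!is.call(e)) stop("cannot parse expression component: ", deparse(e),
                          call. = FALSE)
    op <- as.character(e[[1L]])
    if (op == "(") return(rec(e[[2L]]))
    if (op == "-" && length(e) == 2L) return(rp_neg(rec(e[[2L]])))
    if (op == "+" && length(e) == 2L) return(rec(e[[2L]]))
    a <- rec(e[[2L]])
    switch(op,
      "+" = rp_add(a, rec(e[[3L]])),
      "-" = rp_sub(a, rec(e[[3L]])),
      "*" = rp_mul(a, rec(e[[3L]])),
      "/" = rp_div(a, rec(e[[3L]])),
      "^" = {
        ex <- e[[3L]]
        if (is.call(ex) && as.character(ex[[1L]]) == "-" && length(ex) == 2L)
          ex <- -eval(ex[[2L]])
        if (!is.numeric(ex) || ex != round(ex))
          stop("only integer powers are allowed in rational model expressions",
               call. = FALSE)
        rp_pow(a, ex)
      },
      stop(sprintf("unsupported operator '%s' (expressions must be rational)",
                   op), call. = FALSE)
    )
  }
  ex <- tryCatch(parse(text = text)[[1L]],
                 error = function(err) stop(sprintf(
                   "cannot parse expression '%s': %s", text,
                   conditionMessage(err)), call. = FALSE))
  rec(ex)
}

## ---- polynomial systems ----------------------------------------------------

# A system is a list of polynomials over a shared variable vector.
ik_system <- function(polys, vars) {
  structure(list(polys = polys, vars = vars, n = length(vars)),
            class = "iksys")
}

# Evaluate system values at a complex point (R fallback; the C++ evaluator is
# used on hot paths).
sys_eval <- function(sys, z) {
  vapply(sys$polys, pl_eval, complex(1), z = z)
}

sys_degrees <- function(sys) vapply(sys$polys, pl_degree, integer(1))

# Full Jacobian as a list-of-lists of polynomials, computed once and reused.
sys_jacobian_polys <- function(sys, cols = seq_len(sys$n)) {
  lapply(sys$polys, function(p) lapply(cols, function(k) pl_deriv(p, k)))
}
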