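# Truncated Taylor-jet systems F_r.
#
# States, inputs and outputs are expanded as x(t) = sum_j x_j t^j / j!
# (derivative-normalized jets, so published jet values are time-derivatives at
# zero).  Substituting into the cleared-denominator model equations and
# matching coefficients of 1, t, ..., t^r gives blocks G_0..G_r, each with
# one polynomial per state and one per output.  All expansion is done by
# truncated power-series arithmetic on sparse polynomial tables, never by
# symbolic differentiation of compositions.

## ---- series of polynomials (exponential generating convention) ------------

ser_zero <- function(L, n) replicate(L, pl_zero(n), simplify = FALSE)

ser_add <- function(a, b) mapply(pl_add, a, b, SIMPLIFY = FALSE)

# coefficient j (0-based) of the EGF product of series a, b
ser_conv_at <- function(a, b, j) {
  parts <- lapply(0:j, function(l) {
    x <- pl_mul(a[[l + 1L]], b[[j - l + 1L]])
    pl_scale_safe(x, choose(j, l))
  })
  n <- ncol(parts[[1L]]$E)
  acc <- pl_zero(n)
  for (p in parts) acc <- pl_add(acc, p)
  acc
}

pl_scale_safe <- function(p, s) if (pl_is_zero(p)) p else pl_scale(p, s)

ser_mul <- function(a, b, L) {
  lapply(seq_len(L) - 1L, function(j) ser_conv_at(a, b, j))
}

# expand a small-variable polynomial into a series over the jet variables;
# vser[[k]] is the series assigned to small variable k
jet_expand <- function(p, vser, L, nbig) {
  acc <- ser_zero(L, nbig)
  one <- c(list(pl_const(nbig, 1)), ser_zero(L - 1L, nbig))
  for (i in seq_len(nrow(p$E))) {
    ser <- lapply(one, function(q) pl_scale_safe(q, p$c[i]))
    for (k in which(p$E[i, ] > 0L))
      for (rep in seq_len(p$E[i, k]))
        ser <- ser_mul(ser, vser[[k]], L)
    acc <- ser_add(acc, ser)
  }
  acc
}

## ---- jet system construction ----------------------------------------------

#' Build the truncated jet system F_r of a model
#'
#' Variables are ordered as (parameters; state jets x_0..x_{r+1}; input jets
#' u_0..u_r; output jets y_0..y_r).  Rational right-hand sides are cleared to
#' polynomial form (multiplying each equation by its denominator) before jet
#' expansion.  Initial constraints, if any, are appended as extra linear
#' equations on the order-zero state coordinates.
#'
#' @param model an `ik_model`.
#' @param r truncation order, `r >= 0`.
#' @return an object of class `ik_jetsys`.
#' @export
truncate_model <- function(model, r) {
  r <- as.integer(r)
  if (r < 0L) stop("truncation order r must be >= 0")
  ns <- length(model$states); m1 <- length(model$params)
  ni <- length(model$inputs); no <- length(model$outputs)
  L <- r + 1L

  p_cols <- seq_len(m1)
  x_cols <- m1 + seq_len(ns * (r + 2L))          # block-major in jet order
  u_cols <- if (ni > 0L) m1 + ns * (r + 2L) + seq_len(ni * L) else integer(0)
  y_cols <- m1 + ns * (r + 2L) + ni * L + seq_len(no * L)
  nbig <- m1 + ns * (r + 2L) + ni * L + no * L
  xi <- function(j, s) m1 + j * ns + s           # jet j of state s
  ui <- function(j, s) m1 + ns * (r + 2L) + j * ni + s
  yi <- function(j, o) m1 + ns * (r + 2L) + ni * L + j * no + o

  vars <- c(model$params,
            as.vector(vapply(0:(r + 1L), function(j)
              paste0(model$states, ".", j), character(ns))),
            if (ni > 0L) as.vector(vapply(0:r, function(j)
              paste0(model$inputs, ".", j), character(ni))),
            as.vector(vapply(0:r, function(j)
              paste0(model$outputs, ".", j), character(no))))

  # series assignments for the small variable sets
  state_ser <- lapply(seq_len(ns), function(s)
    lapply(0:r, function(j) pl_var(nbig, xi(j, s))))
  param_ser <- lapply(seq_len(m1), function(k)
    c(list(pl_var(nbig, k)), ser_zero(r, nbig)))
  input_ser <- lapply(seq_len(ni), function(s)
    lapply(0:r, function(j) pl_var(nbig, ui(j, s))))
  vser_rhs <- c(state_ser, param_ser, input_ser)   # order: states, params, inputs
  vser_out <- c(state_ser, param_ser)

  # expand cleared numerators / denominators once
  num_ser <- lapply(model$rhs, function(rp) jet_expand(rp$num, vser_rhs, L, nbig))
  den_ser <- lapply(model$rhs, function(rp) jet_expand(rp$den, vser_rhs, L, nbig))
  xdot_ser <- lapply(seq_len(ns), function(s)
    lapply(0:r, function(j) pl_var(nbig, xi(j + 1L, s))))
  gnum_ser <- lapply(model$output_exprs, function(rp)
    jet_expand(rp$num, vser_out, L, nbig))
  gden_ser <- lapply(model$output_exprs, function(rp)
    jet_expand(rp$den, vser_out, L, nbig))
  yser <- lapply(seq_len(no), function(o)
    lapply(0:r, function(j) pl_var(nbig, yi(j, o))))

  polys <- vector("list", (ns + no) * L)
  idx <- 0L
  for (j in 0:r) {
    for (s in seq_len(ns)) {
      idx <- idx + 1L
      polys[[idx]] <- pl_sub(num_ser[[s]][[j + 1L]],
                             ser_conv_at(den_ser[[s]], xdot_ser[[s]], j))
    }
    for (o in seq_len(no)) {
      idx <- idx + 1L
      polys[[idx]] <- pl_sub(ser_conv_at(gden_ser[[o]], yser[[o]], j),
                             gnum_ser[[o]][[j + 1L]])
    }
  }

  ncon <- 0L
  if (!is.null(model$initial_constraints)) {
    for (con in model$initial_constraints) {
      row <- pl_const(nbig, -con$b)
      for (s in which(con$a != 0 + 0i))
        row <- pl_add(row, pl_scale(pl_var(nbig, xi(0L, s)), con$a[s]))
      polys <- c(polys, list(row))
      ncon <- ncon + 1L
    }
  }

  structure(list(
    model = model, order = r, vars = vars, polys = polys, n = nbig,
    p_cols = p_cols, x_cols = x_cols, u_cols = u_cols, y_cols = y_cols,
    held_fixed = c(u_cols, y_cols), m1 = m1, ns = ns, ni = ni, no = no,
    n_constraints = ncon, block_size = ns + no,
    N_r = m1 + ns * (r + 2L)
  ), class = "ik_jetsys")
}

#' @export
print.ik_jetsys <- function(x, ...) {
  cat(sprintf("<ik_jetsys '%s' r=%d: %d equations, %d variables (%d free when inputs/outputs held fixed)>\n",
              x$model$name, x$order, length(x$polys), x$n, x$N_r))
  invisible(x)
}

## ---- numeric jet propagation ----------------------------------------------

# numeric EGF series helpers (complex coefficient vectors, orders 0..L-1)
nser_mul <- function(a, b) {
  L <- length(a)
  out <- complex(L)
  for (j in 0:(L - 1L))
    out[j + 1L] <- sum(choose(j, 0:j) * a[1:(j + 1L)] * b[(j + 1L):1L])
  out
}

nser_div <- function(a, b) {
  L <- length(a)
  out <- complex(L)
  out[1L] <- a[1L] / b[1L]
  if (L > 1L) for (j in 1:(L - 1L)) {
    acc <- a[j + 1L]
    for (l in 1:j) acc <- acc - choose(j, l) * b[l + 1L] * out[j - l + 1L]
    out[j + 1L] <- acc / b[1L]
  }
  out
}

# numeric series value of a small-variable polynomial; vals[[k]] numeric series
nser_poly <- function(p, vals, L) {
  out <- complex(L)
  for (i in seq_len(nrow(p$E))) {
    ser <- complex(L); ser[1L] <- p$c[i]
    for (k in which(p$E[i, ] > 0L))
      for (rep in seq_len(p$E[i, k])) ser <- nser_mul(ser, vals[[k]])
    out <- out + ser
  }
  out
}

#' Generic point on the jet variety
#'
#' Draws random complex parameters, initial states (projected onto any
#' initial constraints) and input jets, then computes the unique higher
#' state jets and output jets by forward recursion through the blocks G_j.
#' The returned assignment satisfies every jet equation to a relative
#' residual below `1e-10`.
#'
#' @param jetsys an `ik_jetsys` from [truncate_model()].
#' @param max_tries resampling budget when a cleared denominator vanishes.
#' @return an object of class `ik_jetpoint`: list with `assignment` (named
#'   complex vector) and `residual`.
#' @export
seed_point <- function(jetsys, max_tries = 20L) {
  m <- jetsys$model
  r <- jetsys$order; L <- r + 1L
  ns <- jetsys$ns; ni <- jetsys$ni; no <- jetsys$no; m1 <- jetsys$m1
  for (try in seq_len(max_tries)) {
    p <- rand_complex(m1)
    x0 <- rand_complex(ns)
    if (!is.null(m$initial_constraints)) {
      A <- do.call(rbind, lapply(m$initial_constraints, `[[`, "a"))
      b <- vapply(m$initial_constraints, `[[`, complex(1), "b")
      # orthogonal projection onto {A x0 = b}
      AH <- Conj(t(A))
      x0 <- x0 - AH %*% solve(A %*% AH, A %*% x0 - b)
      x0 <- as.complex(x0)
    }
    U <- if (ni > 0L) matrix(rand_complex(ni * L), ni, L) else
      matrix(complex(0), 0, L)
    X <- matrix(complex(ns * (r + 2L)), ns, r + 2L)
    X[, 1L] <- x0
    ok <- TRUE
    for (j in 0:r) {
      Lj <- j + 1L
      vals <- c(lapply(seq_len(ns), function(s) X[s, 1:Lj]),
                lapply(seq_len(m1), function(k) c(p[k], complex(max(Lj - 1L, 0L)))),
                lapply(seq_len(ni), function(s) U[s, 1:Lj]))
      for (s in seq_len(ns)) {
        nn <- nser_poly(m$rhs[[s]]$num, vals, Lj)
        dd <- nser_poly(m$rhs[[s]]$den, vals, Lj)
        if (abs(dd[1L]) < 1e-8) { ok <- FALSE; break }
        X[s, j + 2L] <- nser_div(nn, dd)[Lj]
      }
      if (!ok) break
    }
    if (!ok) next
    valsg <- c(lapply(seq_len(ns), function(s) X[s, 1:L]),
               lapply(seq_len(m1), function(k) c(p[k], complex(L - 1L))))
    Y <- matrix(complex(no * L), no, L)
    for (o in seq_len(no)) {
      nn <- nser_poly(m$output_exprs[[o]]$num, valsg, L)
      dd <- nser_poly(m$output_exprs[[o]]$den, valsg, L)
      if (abs(dd[1L]) < 1e-8) { ok <- FALSE; break }
      Y[o, ] <- nser_div(nn, dd)
    }
    if (!ok) next
    z <- c(p, as.vector(X), if (ni > 0L) as.vector(U), as.vector(Y))
    names(z) <- jetsys$vars
    res <- jet_residual(jetsys, z)
    if (res <= 1e-10) {
      return(structure(list(assignment = z, residual = res),
                       class = "ik_jetpoint"))
    }
  }
  stop("could not construct a seed point: a cleared denominator keeps vanishing")
}

jet_residual <- function(jetsys, z) {
  v <- cpp_eval_system(lapply(jetsys$polys, unclass), jetsys$n,
                       unname(z), FALSE)$value
  max(abs(v)) / max(1, max(abs(z)))
}

# Jacobian of F_r at a point, as a complex matrix over all variables.
jet_jacobian <- function(jetsys, z) {
  cpp_eval_system(lapply(jetsys$polys, unclass), jetsys$n,
                  unname(z), TRUE)$jacobian
}
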