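# Integer-coefficient recovery: LLL lattice reduction and sparse-support
# enumeration with rational ratio recovery.

# Lenstra-Lenstra-Lovasz reduction of the lattice spanned by the columns of
# B (double precision, delta = 0.75).  Dimensions here are small (tens).
lll_reduce <- function(B, delta = 0.75) {
  n <- ncol(B)
  gs <- function(B) {
    Q <- matrix(0, nrow(B), n); mu <- matrix(0, n, n)
    for (i in seq_len(n)) {
      v <- B[, i]
      if (i > 1L) for (j in seq_len(i - 1L)) {
        mu[i, j] <- sum(B[, i] * Q[, j]) / sum(Q[, j]^2)
        v <- v - mu[i, j] * Q[, j]
      }
      Q[, i] <- v
    }
    list(Q = Q, mu = mu)
  }
  g <- gs(B)
  k <- 2L
  it <- 0L
  while (k <= n && it < 10000L) {
    it <- it + 1L
    for (j in seq.int(k - 1L, 1L)) {
      q <- round(g$mu[k, j])
      if (q != 0) {
        B[, k] <- B[, k] - q * B[, j]
        g <- gs(B)
      }
    }
    nk <- sum(g$Q[, k]^2); nk1 <- sum(g$Q[, k - 1L]^2)
    if (nk >= (delta - g$mu[k, k - 1L]^2) * nk1) {
      k <- k + 1L
    } else {
      B[, c(k - 1L, k)] <- B[, c(k, k - 1L)]
      g <- gs(B)
      k <- max(k - 1L, 2L)
    }
  }
  B
}

# continued-fraction rational approximation a/b with |b| <= maxden
rationalize <- function(x, maxden = 1e4, tol = 1e-7) {
  if (abs(x) < tol) return(c(0L, 1L))
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0; r <- x
  for (it in 1:40) {
    a <- floor(r)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (abs(k2) > maxden) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(x - h1 / k1) < tol * max(1, abs(x))) break
    if (abs(r - a) < 1e-14) break
    r <- 1 / (r - a)
  }
  if (k1 == 0 || abs(x - h1 / k1) > 1e-5 * max(1, abs(x))) return(NULL)
  c(as.integer(h1), as.integer(k1))
}

primitive_int <- function(v) {
  v <- as.integer(round(v))
  g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), abs(v[v != 0]))
  if (is.null(g) || g == 0) return(v)
  v <- v %/% g
  if (v[which(v != 0)[1L]] < 0) v <- -v
  v
}

# short integer vectors a with M a ~ 0 (M real, columns = terms), found by
# LLL on the embedded lattice [I; N*M]
lll_relations <- function(M, scale = 1e8, height = 1e6, tol = 1e-6) {
  n <- ncol(M)
  if (n > 60L) stop("LLL relation search limited to 60 terms; restrict the basis")
  B <- rbind(diag(n), scale * M)
  R <- lll_reduce(B)
  out <- list()
  scaleM <- max(abs(M), 1)
  for (i in seq_len(n)) {
    a <- round(R[seq_len(n), i])
    if (all(a == 0) || max(abs(a)) > height) next
    resid <- max(abs(M %*% a)) / (scaleM * max(1, max(abs(a))))
    if (resid < tol) out[[length(out) + 1L]] <- primitive_int(a)
  }
  unique(out)
}
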