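# shared fixtures built in code

# the affine restriction b : C^5 -> C^7 used with the all-leak
# three-compartment coefficient map
restriction_b <- function() {
  list(B = rbind(diag(5), c(1, 3, -1, -3, 2), c(2, 3, 5, 1, -3)) + 0i,
       d0 = as.complex(c(0, 0, 0, 0, 0, 4, -5)))
}

# the two published parameter slices for the slice-moving worked example
slice_Lp <- function() {
  structure(list(A = rbind(c(1, -1, 1, -1, 1, -1, 1),
                           c(-1, 2, 2, 1, -1, -2, 2)) + 0i,
                 b = as.complex(c(4, 10)), codimension = 2L),
            class = "ik_slice")
}

slice_L <- function() {
  structure(list(A = rbind(
    c(1, 3 - 1i, -3 + 2i, 1 + 1i, -(2 + 2i), 2 - 1i, -2),
    c(1 - 3i, -3i, -2 + 2i, -2, -1i, 3 + 2i, -1i)),
    b = as.complex(c(1, 1)), codimension = 2L), class = "ik_slice")
}

eq12_endpoint <- function() {
  c(0.6709 - 2.1940i, 3.6921 + 2.5919i, 2.8774 + 0.5068i, 3.3852 - 1.1735i,
    5.1226 - 0.5068i, 6.3291 + 2.1940i, 5.9227 - 1.4185i)
}

# the twelve parameter vectors consistent with the truncated HIV output,
# published to four decimals (rows with +- expanded; conjugates included)
hiv_table5 <- function() {
  r3 <- c(0.3023 + 0.0779i, -3.5234 + 0.5105i, 4.2201 + 1.9168i,
          -1.3367 - 0.0298i, -0.1080 - 0.2292i)
  r4 <- c(-0.3023 + 0.0779i, -3.5234 - 0.5105i, 4.2201 - 1.9168i,
          -1.3367 + 0.0298i, -0.1080 + 0.2292i)
  r5 <- c(0.6847 + 0.2133i, -3.5234 - 0.5105i, 4.2201 - 1.9168i,
          -0.1080 + 0.2292i, -1.3367 + 0.0298i)
  r6 <- c(-0.6847 + 0.2133i, -3.5234 + 0.5105i, 4.2201 + 1.9168i,
          -0.1080 - 0.2292i, -1.3367 - 0.0298i)
  c(list(c(0.1253, -2.4825, 4.4249, -0.9210, -0.2137) + 0i,
         c(-0.1253, -2.4825, 4.4249, -0.9210, -0.2137) + 0i,
         c(0.2602, -2.4825, 4.4249, -0.2137, -0.9210) + 0i,
         c(-0.2602, -2.4825, 4.4249, -0.2137, -0.9210) + 0i),
    list(r3, Conj(r3), r4, Conj(r4), r5, Conj(r5), r6, Conj(r6)))
}

hiv_published_Y <- function() {
  c(0.5, -0.03, -0.15, -0.2, -0.2, -0.17, -0.16, -0.15)
}

# threecomp with the zero initial condition on the third compartment
threecomp_constrained <- function() {
  spec <- jsonlite::read_json(system.file("extdata", "models",
                                          "threecomp.json",
                                          package = "identikit"),
                              simplifyVector = TRUE)
  spec$constraints <- list("x3(0) = 0")
  load_model(spec)
}

# match a set of computed complex vectors against an expected set within tol
sets_match <- function(computed, expected, tol) {
  if (length(computed) != length(expected)) return(FALSE)
  used <- logical(length(expected))
  for (z in computed) {
    hit <- FALSE
    for (i in seq_along(expected)) {
      if (!used[i] && max(abs(z - expected[[i]])) < tol) {
        used[i] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  all(used)
}
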