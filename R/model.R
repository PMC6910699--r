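# Rational ODE models: x'(t) = f(x, p, u), y(t) = g(x, p) with f, g rational.

#' Load a rational ODE model from a structured config
#'
#' Reads a model description (a JSON file or an equivalent named list) with
#' fields `name`, `states`, `params`, `inputs`, `outputs`, `odes` (one
#' rational expression per state), `output_exprs` (one rational expression
#' per output, in states and parameters only) and optional `constraints`
#' (linear equations on the time-zero state coordinates, e.g. `"x3(0) = 0"`).
#' Expressions may use `^` or `**` for powers.  Every symbol appearing in an
#' expression must be declared; an undeclared symbol is an error naming it.
#'
#' @param spec path to a JSON file, or a named list with the fields above.
#' @return an object of class `ik_model`.
#' @export
load_model <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    spec <- jsonlite::read_json(spec, simplifyVector = TRUE)
  }
  stopifnot(is.list(spec))
  states <- as.character(spec$states)
  params <- as.character(spec$params)
  inputs <- as.character(if (is.null(spec$inputs)) character(0) else spec$inputs)
  outputs <- as.character(spec$outputs)
  name <- if (is.null(spec$name)) "model" else as.character(spec$name)
  all_syms <- c(states, params, inputs)
  if (anyDuplicated(all_syms))
    stop("duplicated symbol declaration in model '", name, "'")

  odes <- spec$odes
  if (length(odes) != length(states))
    stop("need exactly one ODE right-hand side per state")
  if (!is.null(names(odes)) && all(names(odes) != ""))
    odes <- odes[states]
  rhs <- lapply(unlist(odes), parse_rational, vars = all_syms)

  oex <- spec$output_exprs
  if (length(oex) != length(outputs))
    stop("need exactly one output expression per output")
  if (!is.null(names(oex)) && all(names(oex) != ""))
    oex <- oex[outputs]
  gex <- lapply(unlist(oex), parse_rational, vars = c(states, params))

  constraints <- NULL
  if (!is.null(spec$constraints) && length(spec$constraints) > 0) {
    constraints <- lapply(spec$constraints, parse_constraint, states = states)
  }

  m <- structure(list(
    name = name, states = states, params = params, inputs = inputs,
    outputs = outputs, rhs = rhs, output_exprs = gex,
    initial_constraints = constraints
  ), class = "ik_model")
  validate_model(m)
  m
}

# "x3(0) = 0" style constraints: linear in the time-zero state coordinates.
parse_constraint <- function(text, states) {
  text <- gsub("\\(0\\)", "", text)
  parts <- strsplit(text, "=", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("constraint must be of the form 'expr = expr'")
  lhs <- parse_rational(parts[1L], states)
  rhs <- parse_rational(parts[2L], states)
  dd <- rp_sub(lhs, rhs)
  if (!rp_is_poly(dd) || pl_degree(dd$num) > 1L)
    stop("initial constraints must be linear in the states")
  # return coefficient row (a, b) with a . x0 = b
  n <- length(states)
  a <- complex(n)
  b <- 0 + 0i
  p <- dd$num
  for (i in seq_len(nrow(p$E))) {
    k <- which(p$E[i, ] > 0L)
    if (length(k) == 0L) b <- b - p$c[i] else a[k] <- a[k] + p$c[i]
  }
  list(a = a, b = b, text = text)
}

validate_model <- function(m) {
  z <- rand_complex(length(m$states) + length(m$params) + length(m$inputs))
  for (i in seq_along(m$rhs)) {
    if (abs(pl_eval(m$rhs[[i]]$den, z)) < 1e-12)
      stop("denominator of the ODE for state '", m$states[i],
           "' vanishes at a random point")
  }
  zg <- rand_complex(length(m$states) + length(m$params))
  for (i in seq_along(m$output_exprs)) {
    if (abs(pl_eval(m$output_exprs[[i]]$den, zg)) < 1e-12)
      stop("denominator of output '", m$outputs[i],
           "' vanishes at a random point")
  }
  invisible(m)
}

#' @export
print.ik_model <- function(x, ...) {
  cat(sprintf("<ik_model '%s': %d states, %d params, %d inputs, %d outputs%s>\n",
              x$name, length(x$states), length(x$params), length(x$inputs),
              length(x$outputs),
              if (!is.null(x$initial_constraints))
                sprintf(", %d initial constraints",
                        length(x$initial_constraints)) else ""))
  invisible(x)
}

# Random complex coordinates a + bi with a, b uniform on +/-[0.1, 1]: generic
# points kept away from the coordinate hyperplanes.
rand_complex <- function(n) {
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  complex(real = sgn(n) * stats::runif(n, 0.1, 1),
          imaginary = sgn(n) * stats::runif(n, 0.1, 1))
}

ik_fixture_names <- c("linear3", "linear3_noleak13", "threecomp", "hiv",
                      "fourcomp", "mapk_6out", "mapk_2out", "mapk_4out",
                      "mapk_mixed")

#' Built-in benchmark models
#'
#' Returns one of the models studied throughout the package: the linear
#' three-compartment model with leaks from all compartments (`linear3`), the
#' same model with the leaks from compartments 1 and 3 removed
#' (`linear3_noleak13`), the three-compartment model with measured second
#' compartment (`threecomp`), the three-state HIV dynamics model (`hiv`),
#' the four-compartment model with measured first compartment (`fourcomp`),
#' and the mass-action MAPK two-site phosphorylation network with its four
#' output variants (`mapk_6out`, `mapk_2out`, `mapk_4out`, and `mapk_mixed`,
#' the latter with ten additional output-mixing parameters for a total of 32).
#'
#' @param name fixture name.
#' @return an `ik_model`.
#' @export
fixture <- function(name) {
  if (!name %in% ik_fixture_names)
    stop("unknown fixture '", name, "'; available: ",
         paste(ik_fixture_names, collapse = ", "))
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "identikit")
  if (path == "") stop("fixture file missing for '", name, "'")
  load_model(path)
}
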