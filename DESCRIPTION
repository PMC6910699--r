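Package: identikit
Title: Structural Identifiability of Rational ODE Models via Numerical
    Algebraic Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides structural identifiability of rational ordinary
    differential equation models by numerical algebraic geometry. Computes
    the dimension of unidentifiability either from the coefficients of
    input-output equations (Jacobian corank at a random complex point) or
    directly from truncated Taylor-jet systems with corank stabilization;
    computes the identifiability degree of identifiable models by
    total-degree homotopy continuation or by monodromy loops on
    pseudowitness sets with trace-test certification, with or without
    input-output equations; and, for unidentifiable models, recovers
    algebraically independent identifiable (and globally identifiable)
    functions of the parameters by fiber sampling, linear interpolation
    over monomial bases, and integer-coefficient recovery. Ships the
    classical compartmental, HIV and MAPK benchmark models as fixtures and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
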