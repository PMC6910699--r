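---
title: "Numerical algebraic geometry for structural identifiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical algebraic geometry for structural identifiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(identikit)
```

## The model class and the two central quantities

`identikit` analyzes ODE models `x' = f(x, p, u)`, `y = g(x, p)` with
rational `f`, `g`, constant unknown parameters `p`, known inputs `u` and
measured outputs `y`. *Structural* identifiability asks what can be
recovered about `p` from perfect (noise-free, arbitrarily long)
input-output data; it is a property of the model equations alone, and a
prerequisite for any practical parameter estimation.

Eliminating the states yields input-output equations whose normalized
coefficients form a rational map `c : C^m1 -> C^m2` on the parameters: two
parameter vectors produce the same data exactly when their coefficients
agree. Everything reduces to the geometry of `c`:

* the **dimension of unidentifiability** `l` is the dimension of a generic
  fiber `c^{-1}(c(p))`, equal to the corank of the Jacobian `Jc` at a
  generic point;
* for `l = 0`, the **identifiability degree** `k` is the generic fiber
  cardinality (`k = 1`: globally identifiable; `k > 1`: locally);
* for `l > 0`, the object of interest is a transcendence basis of
  `rank c = m1 - l` algebraically independent **identifiable functions**
  — functions of `p` constant on the irreducible components of generic
  fibers.

All computations are numerical: generic points are random complex vectors,
varieties are represented by sample points, and path tracking moves those
points around. Working over the complex numbers is essential — fiber
cardinality and component structure are only generically constant there.

## Jet systems: dimension without input-output equations

Differential elimination frequently fails on networks of realistic size
(none of the MAPK variants below admit it in practice). The jet route
avoids it: expand states, inputs and outputs as truncated Taylor series
`x(t) = sum x_j t^j / j!` and match coefficients of `1, t, ..., t^r` in
the (denominator-cleared) model equations. This produces a polynomial
system `F_r` in the parameters and jet variables, built here by truncated
power-series arithmetic on sparse polynomial tables — never by symbolic
differentiation of compositions, which blows up in both time and
expression size.

With the input and output jets held fixed, the projection of the solution
set of `F_r` onto parameter space has dimension
`d_r = corank_0 JF_r - corank_{m1} JF_r` at a generic point (a standard
fiber-dimension argument for coordinate projections). The sequence `d_r`
is nonincreasing and stabilizes at `l`; `method2_dimension()` iterates
until `d_r = 0` or both coranks repeat between consecutive orders, then
computes one confirmation row. Generic points on `F_r = 0` are free:
sample parameters, initial state (projected onto any initial-value
constraints, such as an empty third compartment) and input jets, and the
higher state and output jets follow by forward recursion.

Two numerical choices matter for the corank decisions:

* **Equilibration.** Derivative-normalized jets grow factorially with the
  order, so a full-rank `JF_r` can have singular values spread over ten
  orders of magnitude. Rank is invariant under diagonal row/column
  scaling, and scaling both to unit maximum modulus compresses the
  spectrum before the SVD.
* **Gap detection.** Even after equilibration, the smallest genuine
  singular values of the larger MAPK systems decay with `r` through any
  fixed threshold. Jet-side coranks therefore place the zero group below
  the largest relative gap inside the small-singular-value region (true
  zeros sit at the machine floor, at least five orders below the smallest
  genuine value in every system tested), while coefficient-map Jacobians
  keep a plain relative threshold of `1e-8`. Decisions with a weak gap
  are flagged ambiguous and re-evaluated at fresh generic points; an
  extended-precision fallback is not available in this stack, and the
  fresh-point vote replaces it.

## Path tracking

Every homotopy is a polynomial system in `(z, s)` whose last variable `s`
follows one of three smooth paths in the tracking parameter `t in [1, 0]`:
linear (`s = t`), a monodromy circle `s = 1 - exp(2 pi i (1 - t))`, or a
gamma segment `s = gamma t / (1 + (gamma - 1) t)` with random unit-modulus
`gamma` (the standard genericity device that keeps paths off the real
discriminant). Allowing polynomial — not just affine — dependence on `s`
lets one family cover total-degree start systems, slice interpolation,
loop translations, and base-point paths `c(b(p + s eta))` that arise in
fiber sampling.

The predictor is RK4 on the Davidenko ODE `dz/dt = -Jz^{-1} dH/dt`, the
corrector at most three Newton steps; steps halve on corrector failure
(doubling back after five successes, initial step 0.05, minimum `1e-8`)
and endpoints are Newton-polished at `t = 0`. Convergence of an endpoint
is judged by its relative residual (`1e-9`), not the Newton step size,
which is unreachable in double precision at large endpoints. Paths whose
coordinates exceed `1e8` times the start-point scale are declared
divergent — the scale-relative bound matters because jet coordinates are
legitimately huge at high truncation orders. A path that stalls very
close to `t = 0` is salvaged when Newton converges from its last iterate;
one stalled elsewhere is singular and excluded from solution counts (all
counted solutions in these analyses are nonsingular).

Total-degree solving uses the start system `z_i^{d_i} = b_i` with the
gamma trick and tracks all `prod d_i` paths, so its solution sets are
complete by construction. Overdetermined systems are squared up by
degree-preserving triangular random combinations (rows sorted by ascending
degree, row `i` mixing only rows `1..i`): the Bezout count is then the
product of the smallest degrees rather than the largest degree raised to
the dimension, which for the four-compartment fiber systems means 36
paths instead of 4096. Extraneous zeros introduced by squaring are
filtered by the residual of the full system.

## Degrees: monodromy and the trace test

`method4_degree()` computes `k` without expanding the fiber system:
a pseudowitness set `W = Graph(c) ∩ (C^m1 x L)` for a generic slice `L`
of codimension `m1` through `c(p)` satisfies `#W = k · deg X` and
`#pi(W) = deg X`. `W` is grown by monodromy: each loop tracks all known
points to a fully random slice and back along two independent complex
arcs. (One-parameter translation loops of the slice constants mix far too
slowly and are kept only for reproducing a worked loop with published data;
loops through the base parameter point itself are useless — the seed
point just rides the tautological branch `q(t) = p(t)`.)

Completeness is certified by a trace test, and the choice of trace test is
a genuine design point. The naive linear trace — translate the last slice
row, track only the witness points, check that their coordinate sum moves
affine-linearly — is *invalid* here: translating a `y`-row moves the whole
fiber, so the tracked family is a moving fiber and the sum is a
pushforward under the `k : 1` cover, not an affine function (measured
collinearity residuals are O(1) on witness sets known to be complete).
The package instead uses the multihomogeneous bilinear family: the first
`m1 - 1` slice rows cut the graph down to a curve `C`, `elly` is the last
row, `ellp` a random affine functional of the parameters, and
`H(t) = {ellp · elly = t}`. The witness points sit on the `elly` factor
of `H(0)`; `C ∩ H(t0)` is populated by monodromy in `t` (with loop radii
spread over decades, because the branch points of the `t`-cover scatter
widely) plus, when the Bezout count of the factor systems is affordable, a
deterministic total-degree top-up. The linear trace in `t` over two
parallel translates certifies completeness — residuals are below `1e-10`
on complete families and above `1e-6` on families missing a single point,
and the pass threshold sits at `1e-8` between them. Tracking `t -> 0`
splits the points between the two factors, reporting the bidegree of `C`,
and any certified point on the `elly` side absent from `W` is absorbed.

The jet-side degree (`jet_degree()`) fixes a truncated output, enumerates
all (parameter, state-jet) solutions of `F_r` by monodromy loops in
output-jet space, then extends each solution by one more output
coefficient `y_{r+1}` and clusters: solutions sharing all output jets
produce the same data, and `k` is the size of the cluster containing the
seed solution. One extra order suffices to separate the clusters in every
model tested; the cluster census is always reported and unequal cluster
sizes raise a warning rather than being hidden. Certification of the
enumeration uses the bilinear trace on the output-restricted jet curve;
because it tracks hundreds of 33-variable paths for the HIV benchmark it
lives in `scripts/slow_bidegree.R` rather than the test suite, and the
suite relies on loop saturation plus the published reference values.

## Identifiable functions from samples

For `l > 0`, `sample_fiber()` draws points on the fiber component through
`p`: a random slice of codimension `l` through `p` is moved to fresh random
slices along the literal linear interpolation `t L_p + (1 - t) L` (kept
linear, with no gamma arc, so that a published worked endpoint is reproduced
exactly; the interpolation is generic enough because the slices are
complex). Each sample pair imposes the constraint
`sum a_j (f_j(q) - f_j(p)) = 0` on a candidate function
`sum a_j f_j` over a monomial basis; the nullspace of the stacked
constraints — grown until its dimension is unchanged by two consecutive
pairs — spans the identifiable functions in the basis.

Integer coefficient vectors are recovered by two routes: enumeration of
sparse supports (sizes one to three, with rational ratio recovery by
continued fractions) and, for bases of at most 60 terms, LLL lattice
reduction on the embedded constraint lattice — no integer-relation library
exists in this R stack, so LLL (double precision, delta 0.75) is
implemented in the package. Every candidate is verified on all sample
pairs, and the tests verify on fresh ones. The staged search
(`staged_identifiable_functions()`) orders candidates by degree, support
and height and accepts greedily by Jacobian-rank gain until
`rank c = m1 - l` independent functions are found: on the four-compartment
model this recovers `a11`, `a22`, `a33 + a44` at degree one, `a12 a21` and
`a33 a44 - a34 a43` at degree two, and `a23 a34 a42` at degree three. The
choice of test space is genuinely user-driven; total-degree-bounded
monomials are a default convention, not a canon.

Global identifiability needs points on *every* fiber component.
`all_components()` restricts the parameters through a generic affine map
`b` so that the restricted map is identifiable, enumerates the restricted
fiber (by total degree over a fully generic base point followed by
continuation of the fiber to the requested one — solving directly at a
special, e.g. real, base point loses paths to its non-generic geometry —
or by certified monodromy when the Bezout count is large), and maps the
points back through `b`. Functions constant across all points are globally
identifiable; integer combinations of the locally identifiable ones that
become global are found by a second nullspace over the cross-component
value differences. `fiber_component_orbits()` additionally merges the
points into monodromy orbits of the restriction plane: a single orbit
certifies a single irreducible component (the four-compartment fiber), and
on the all-leak compartment model the two orbits found match the two
branches of the quadratic that the locally identifiable sum satisfies.

## The MAPK analyses and their scope

The mass-action two-site phosphorylation network ships with 12 species, 22
rate parameters and four output configurations (six outputs; kinase and
phosphatase only; the four substrate forms; and four mixed outputs with
ten extra mixing parameters, 32 parameters in all). The published equations
of the source network conflate complex species with products, so the
fixture is the standard mass-action scheme with those species and
parameter names; the dimension tables it reproduces (stabilization at
order 6, 16, 8 and 10-11 respectively) are conditional on that
reconstruction, and the conservation of total kinase, phosphatase and
substrate is asserted in the tests.

For the mixed-output variant the fiber is one-dimensional and sixteen rate
parameters are identifiable. The test suite verifies this at the tangent
level: the kernel direction of the equilibrated jet Jacobian vanishes (to
`1e-8`) on exactly those sixteen coordinates and is bounded away from zero
on the six binding rates and ten mixing parameters, across independent
generic fibers whose directions are linearly independent. The stronger
statement that *no* nonconstant linear function of the sixteen
unidentifiable parameters is identifiable would require on the order of
sixteen independent fibers and is not asserted by the suite.

## Problem sizes and limitations

The suite runs the full dimension tables (truncation orders up to 17 on
the 2-output MAPK variant, Jacobians up to about 250 x 250), monodromy
runs with tens of witness points, the complete 12-point HIV jet
enumeration, and fiber sampling with five pairs per component; these sizes
were chosen as the smallest at which every benchmark quantity is
reproduced and every stochastic step has a comfortable margin.
Known limitations: no certified (interval) tracking; no endgames for
singular endpoints, so positive-dimensional or non-reduced solution
structure at a homotopy target is reported as path failure; rank decisions
are double-precision votes across generic points, not proofs; and the
monodromy stopping heuristic (ten useless loops) is exactly that — a
heuristic — which is why every degree computation that matters is paired
with a trace-test certificate or a total-degree enumeration.
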