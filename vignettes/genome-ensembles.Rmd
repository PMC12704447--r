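---
title: "Modelling 3D genome ensembles with a variational quantum sampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 3D genome ensembles with a variational quantum sampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqconform)
```

## The problem and the model

A Hi-C contact map constrains, but does not determine, the 3D fold of a
chromosome: a bulk experiment pools millions of cells, and even a
single-cell map is compatible with many conformations. `vqconform`
therefore models a *distribution* over conformations. The generative
device is a parameterized quantum circuit simulated exactly: each of the
`3(N-2)` qubits carries one spin of the lattice encoding, so one
measurement of the register is one conformation, and an ensemble is simply
`rho` repeated measurements.

### Lattice encoding

Beads live on a cubic lattice with steps of unit Euclidean norm. Bead 1
sits at the origin and bead 2 at `(1,1,1)/sqrt(3)`; bead `i > 2` adds the
step `(z_x, z_y, z_z)/sqrt(3)` with spins in `{-1, +1}`. Useful
consequences, all exercised in the test suite:

* `D[i,j]^2 <= (i-j)^2` — the chain cannot stretch past collinearity;
* nonzero squared distances are at least 1 (odd separations) or 4/3
  (even separations) — a parity property of the lattice;
* two beads either coincide exactly or are at least one step apart, so
  "clash" (any pairwise distance below 1/4) reduces to coincidence.

The spin-to-bit convention is fixed once and shared by every module:
bit 1 is spin +1, qubit 0 is bead 3's x-axis spin and the least
significant bit of the basis index. Beads are indexed 1-based throughout,
as is natural in R; the two fixed beads are beads 1 and 2.

### Contact likelihood

Given a binary contact map, eligible pairs (`j >= i+2`; shorter
separations cannot be informative since adjacent beads are constitutively
in contact) contribute an attractive propensity when labelled as contacts
and a logistic neutral propensity otherwise (`r = 1.5` lattice units by
default). The per-structure log-likelihood drops its additive constant, so
values are comparable only within one `(N, contact map, r)` setting.

Two numerical guards keep the objective finite:

* the attractive base `1 - |D^2 - r^2|/(sep^2 - r^2)` is clamped to
  `[1e-12, 1]` — it is negative when beads coincide and exactly 0 at the
  collinear saturation point `D^2 = sep^2`;
* the exponent `sep^2 / D^2` floors `D^2` at 1, the smallest nonzero
  squared distance the lattice admits.

The floor value deserves a comment, because it is the one place where the
package departs from a naive "tiny epsilon" guard. Any non-coincident
geometry has `D^2 >= 1`, so flooring at 1 scores every legitimate
structure identically to an epsilon floor. At a coincidence, however, an
epsilon floor inflates the exponent to `sep^2/epsilon` and the penalty to
the order of `1e11`, while the informative part of the objective is of
order 10. With such a dynamic range a derivative-free optimizer spends its
entire budget chasing the penalty cliff and never sees the likelihood
signal; in our experiments COBYLA then stalls with 5–35% of the
measurement mass still on clashing states. Flooring at the lattice minimum
caps the coincidence penalty at `sep^2 * log(1e-12)` (about -110 for the
most common separation), which still dominates every legitimate
log-likelihood but keeps the scales commensurable — after which training
reliably concentrates sampling in the top likelihood quantiles. An
optional cap on the exponent is exposed for chains long enough (hundreds
of beads) that the built-in exponent loses its punch; it is off by
default.

Clash-containing samples are *included* in the training objective (the
likelihood itself penalises them) but *excluded* from inferred-contact
evaluation, where a clashing geometry has no physical reading. The
exclusion is reported (`dropped_shots`) rather than silent.

### Aggregation

The objective `-(1-alpha) * mean_k log P(D_k^2) - alpha * log P(mean_k D_k^2)`
is affine in `alpha`. At `alpha = 0` each sampled structure must fit the
contacts individually — the consensus/single-cell regime; at `alpha = 1`
only the ensemble average must — the population/bulk regime, a
deconvolution of a bulk map into a virtual population. The affinity is
tested by three-point collinearity, and both endpoints have closed-form
identities the tests pin down.

## Circuit, optimizer, training loop

The ansatz is the two-repetition real-amplitude circuit: a y-rotation
layer, then twice (reverse-linear CNOT chain + y-rotation layer), giving
`9(N-2)` parameters. All gates are real, so amplitudes stay real and the
measurement distribution is their square; simulation is exact statevector
(C++ core, microseconds at 12 qubits) followed by one multinomial draw of
`rho` shots — distributionally identical to per-shot execution. A dense
Kronecker-product simulator, written independently in the test helpers,
pins the statevector to 1e-10.

Training uses COBYLA (derivative-free linear approximation), parameters
initialised uniformly on `[0, 2*pi)`, default budget 1000 objective
evaluations with shot count `rho = 4096`. The returned parameters are the
best seen along the trace, not the final iterate — with a stochastic
objective the two differ. Each objective evaluation draws its shots from a
seed stream fixed at construction, so a fit is exactly reproducible from
one integer. Per-structure energies are memoised across evaluations, so
the marginal cost of an evaluation is one statevector plus table lookups.

The expectation-consistency test is the load-bearing correctness check:
for small `N` the probability-weighted objective computed from the
statevector must equal the brute-force expectation over all `8^(N-2)`
enumerated structures to 1e-9, and the sampled objective must agree within
three standard errors at `rho = 1e5`.

## Ground truth by enumeration

For `N <= 8` (cap raisable to 10) the package enumerates every spin
string, flags clashes, extracts contact sets, and partitions the
clash-free states into groups sharing a contact set. A group's contact set
is a simulated Hi-C target whose ground-truth distribution `phi` — the
likelihood of every enumerable state — supports exact evaluation:
coverage and empirical probability of the upper-`q` likelihood quantile
(linear-interpolation quantile, ties included by `>=`), likelihood ratios
of the learned distribution over uniform by energy level (20
equal-occupancy bins by default; the bin count is a package choice), and
Shannon entropy of the sampled ensemble.

One caution the enumeration itself surfaced: likelihood rank does not
always coincide with group membership. At `N = 3` with the single contact
`(1,3)`, the members of the contact group sit at `D^2 = 4/3`, but the
attractive propensity peaks at `D^2 = r^2 = 2.25`, so the three
conformations with `D^2 = 8/3` — *not* in contact — score higher. This is
a property of the model (the propensity rewards proximity to the radius,
not containment within it), visible only because the universe is
exhaustively checkable; the tests freeze the true ranking.

No symmetry reduction (mirror or rotational) is applied to the universe;
symmetric conformations are counted as distinct states, matching the
qubit-register view of the state space.

## Hi-C calibration

Real contact frequencies follow an inverse power law in distance,
`D ~ f^(-lambda)`. With `f_unit` the smallest nonzero adjacent-locus
frequency, entry `(i,j)` is a contact when `f[i,j]/f_unit >= r^(-1/lambda)`;
`lambda` in `{1/3, 1/2, 2/3}` spans the values in common use, and smaller
`lambda` lowers the threshold and admits more contacts. The converse map
sends model distances to inferred contact probabilities: 1 inside the
radius, `(r/D)^(1/lambda)` outside. All-zero rows/columns (unmappable
bins) are dropped with an index map retained; matrix balancing is accepted
as input but never performed. Ensembles are scored by the count-weighted
mean of per-structure inferred matrices over clash-free members.

## Evaluation suite

Beyond the quantile metrics: tie-averaged rank AUC and step-interpolated
average precision over eligible pairs (cross-checked against an
independent ROC implementation); weighted and maximum-threshold
Dice–Sørensen indices, the threshold grid including 0 so the
all-included candidate is reachable on constant inputs, and the all-empty
case defined as 1; scale-invariant RMSD with the closed-form least-squares
scale `s* = sum(D*Dt)/sum(D^2)` (verified against numeric minimisation)
plus Spearman correlation; discrete Jensen–Shannon divergence between
ensembles, by default after merging states with identical contact sets
(an embedding hook accepts external density-based comparisons); and
paired F1 via maximum-weight bipartite matching (checked against an
exhaustive assignment oracle). A sentence in the source describing
"perfectly balanced" labels for AUC/AP admits several readings; the
standard pair-level definition is implemented.

Landscape ruggedness uses the empirical maximum information content:
`128p` uniform samples fix the cost scale, 64 random walks of length `64p`
(per-coordinate uniform steps of 0.1 rad, a package choice) generate cost
differences, symbols in `{-1, 0, +1}` at sensitivity `eps` are pair-counted,
and `H_M` is the maximum over an `eps` grid of the walk-averaged base-6
entropy of unequal symbol pairs. A constant landscape gives 0; perfectly
alternating differences give `log6(2)`.

## What the simulated data do and do not show

The synthetic targets are drawn uniformly over contact groups of the
exhaustively enumerated universe, with the radius, clash rule, shot count
(4096) and trial structure (10 fits per target, fresh initialisation each)
matching the simulated-data protocol this package implements. They are
exact and download-free, but they are small (`N` up to 10), single
chromosome, noise-free, and their contact maps are realisable by
construction — real Hi-C maps need not be. Passing tests therefore
demonstrate correctness of the machinery and reproduction of the
qualitative aggregation trends (entropy, energy-level ratios, landscape
ruggedness across `alpha`), not performance on experimental data. The
calibration path is exercised on synthetic frequency matrices; published
counts for specific cell lines depend on the exact balanced matrix used
and are not asserted.

Problem sizes in the default test and acceptance runs — `N = 6` (4096
states, 12 qubits, 36 parameters), 5–10 training runs per configuration,
landscape walks at `p = 36` — were chosen so the full ground-truth
apparatus stays exact while a complete run finishes in minutes on one CPU.

## Known limitations

* Memory for enumeration grows as `8^(N-2)`; `N > 10` is out of reach of
  the oracle (the sampler itself runs wherever the statevector fits).
* No hardware backends, noise models or transpilation ship with the
  package; the simulator seam (`simulate_probabilities`) is the place a
  vendor client would plug in.
* Inter-chromosomal (multi-polymer) systems and probabilistic (non-binary)
  contact maps are out of scope.
* COBYLA with default budgets can terminate at mediocre optima for
  unlucky initialisations; the experiment driver's multi-trial design (and
  taking the best fit) is the intended remedy.
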