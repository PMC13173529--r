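---
title: "Occupancy-guided QSCI: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy-guided QSCI: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsci)
```

# The problem

Selected configuration interaction (SCI) approximates the ground state of a
molecular electronic Hamiltonian by diagonalizing it in a subspace
$\mathcal{D} = \{\,|\Phi_k\rangle\,\}$ of Slater determinants chosen
adaptively, instead of the full CI space of dimension
$\binom{M}{N_\alpha}\binom{M}{N_\beta}$ for $M$ spatial orbitals and
$(N_\alpha, N_\beta)$ electrons per spin.  Quantum-selected CI (QSCI) lets
measurements of a quantum state steer that subspace construction.  This
package implements — entirely classically, with statevector emulation
standing in for hardware — a QSCI variant in which the guiding signal is the
*orbital occupancy distribution* of a stochastically time-evolved reference
state, and benchmarks it against Heatbath CI (HCI).

The full loop is:

1. **Integrals in.**  A molecular Hamiltonian arrives as an FCIDUMP file:
   core energy $E_\text{core}$, one-electron integrals $h_{pq}$ and
   two-electron integrals $(pq|rs)$ in chemists' notation with 8-fold
   permutational symmetry.
2. **Qubit Hamiltonian.**  `jordan_wigner()` maps the second-quantized
   Hamiltonian onto $2M$ qubits, $H = \sum_j h_j \sigma_j$, with
   $\ell_1$ norm $\lambda = \sum_j |h_j|$.
3. **Stochastic real-time evolution.**  `run_time_grid()` emulates
   $e^{-iHt}$ at $t = k\tau$ via qDRIFT: terms drawn i.i.d. with
   probability $p_j = |h_j|/\lambda$, each contributing a fixed-angle
   rotation $e^{-i\lambda t\,\mathrm{sgn}(h_j)\sigma_j/N}$ with segment
   count $N = \lceil 2\lambda^2 t^2/\epsilon\rceil$.  Computational-basis
   shots are sampled from the evolved statevector.
4. **Occupancy-guided selection.**  `qsci_run()` converts shots into
   per-spin mean occupancies (Eq. below), admits sector-valid bitstrings
   directly as determinants, samples conditional single/double excitations
   from dominant configurations, screens them with
   $d(\Phi_l) = |H_{kl}|\,P(\Phi_l)$, and diagonalizes the growing subspace.
5. **Perturbative closure.**  `enpt2_correction()` adds the Epstein–Nesbet
   second-order correction for the correlation left outside the subspace,
   and `extrapolate_to_zero()` regresses subspace energies against their
   corrections to estimate the full CI energy at the zero-correction limit.

# Conventions fixed throughout

**Spin-orbital ordering is blocked**: spin orbital $i \in [0, M)$ is
$\alpha_i$, spin orbital $M + i$ is $\beta_i$.  This keeps each spin
channel's occupancy vector contiguous in qubit space, which the occupancy
statistics rely on.

**Jordan–Wigner, not a tree encoding.**  Under JW the computational-basis
bit of qubit $i$ *equals* the occupation of spin orbital $i$, so a measured
bitstring is literally an occupation pattern and the mean bit value is the
mean orbital occupancy.  Any encoding without this property would break the
entire sampling scheme, so the mapping is not configurable.

**Bitstrings are written qubit-0-first**: the leftmost character of a
measurement record is spin orbital 0.

**Fermionic phases** use ascending spin-orbital order; the sign of moving
one electron from orbital $p$ to $q$ is $(-1)^{\#\{\text{occupied strictly
between } p, q\}}$, and double excitations apply their two moves
sequentially.  Any self-consistent convention gives the same physics; this
one is validated entrywise against an explicit ladder-operator matrix
construction in the test suite.

**Rotation angle convention.**  The qDRIFT segment applies
$e^{-i\theta\sigma}$ with $\theta = \lambda t\,\mathrm{sgn}(h_j)/N$ — the
full exponent, no extra $1/2$.  This is checked against a dense
matrix-exponential oracle: average infidelity falls roughly linearly in
$\epsilon$, as the channel analysis predicts.

**Identity terms** are excluded from the Pauli term list; their coefficient
(plus $E_\text{core}$) is tracked as an energy offset.  They contribute only
a global phase to the dynamics, and keeping them would inflate $\lambda$ —
and hence circuit depth — with no effect on measured populations.

# The occupancy distribution and the sampler

For a measurement set $\{b_k\}$ of $N_\text{shots}$ bitstrings, the
occupancy distribution per spin $\sigma$ is the shot-weighted mean bit
value,

$$ \bar n^{(\sigma)}_i = \frac{1}{N_\text{shots}} \sum_k
   \langle b_k | a^\dagger_{\sigma i} a_{\sigma i} | b_k \rangle
   \in [0, 1], $$

with a normalized variant $P^{(\sigma)}_\text{occ} \propto \bar n^{(\sigma)}$
used as selection weights.

The sampler draws excitations away from a dominant configuration $\Phi_k$
conditioned on its occupations.  The conditioning is implemented as
**restrict and renormalize**: occupied indices are drawn from the
normalized occupancy weights restricted to orbitals occupied in $\Phi_k$;
unoccupied indices from weights proportional to $1 - \bar n$ restricted to
orbitals empty in $\Phi_k$.  Two deliberate choices here:

* The *virtual* weight uses the complement of the raw mean occupancy
  ($1 - \bar n$), not the complement of the normalized vector.  $\bar n$ is
  the only quantity with a physical $[0, 1]$ scale; complementing a
  normalized vector can distort or sign-flip weights.
* Each channel (single $\alpha$, single $\beta$, same-spin double per spin,
  opposite-spin double) is chosen uniformly among the channels that have
  positive-weight support; channels without support are skipped and
  reported.  The mixture over channels is a free design choice — nothing in
  the screening metric depends on it strongly, because the recorded
  probability $P(\Phi_l)$ is always the product of the per-index conditional
  factors.

Same-spin index pairs must be distinct; they are drawn by **rejection**
(redraw i.i.d. pairs while the indices coincide), so the realized pair
frequencies are proportional to the product weights on distinct pairs —
matching the product form of the selection probability, which the tests
verify against exhaustive enumeration on a four-orbital system.

Candidates are screened with $d(\Phi_l) = |H_{kl}| \cdot P(\Phi_l)$, where
$\Phi_k$ is the dominant configuration that generated the candidate; a
candidate generated by several sources keeps its maximum score, and
duplicate draws keep the maximum recorded probability (summing would
conflate sampling multiplicity with probability).  Candidates with score
exactly zero — symmetry-forbidden couplings or zero sampling weight — are
never appended, so a Hamiltonian with no off-diagonal coupling leaves the
subspace at the Hartree–Fock determinant.

# The orchestration loop

`qsci_run()` loops time steps outermost and sampling rounds innermost:
measurement sets are collected once, up front, from a fixed Hartree–Fock
reference, and each step's set drives `N_rounds` of
solve → prune → sample → screen → append → admit-rectified.  Two
interpretation points are fixed here as package policy:

* **Rectified determinants are admitted first** (at initialization, from
  the first measurement set) and re-admitted each round after the
  occupancy-guided appends, all against the shared cap `D_max`.
* **Pruning** with `eps_wf` removes determinants whose coefficient
  magnitude fell below threshold from the subspace entirely (they may
  re-enter later through sampling or rectification); the Hartree–Fock
  reference is never pruned.

The PT2 correction is computed at per-time-step checkpoints (the subspace
snapshot after each step's rounds), not per round — the correction is the
most expensive quantity in the loop, and the checkpoint sequence is exactly
what the zero-correction extrapolation consumes.

Adaptive re-preparation of the reference state between steps is explicitly
out of scope; the reference stays Hartree–Fock throughout a run.

# Heatbath CI benchmark

`hci_run()` implements the classical benchmark: starting from the
Hartree–Fock determinant with threshold $\delta_0 = 0.1$, each threshold
level alternates expansion — append every $\Phi_l \notin \mathcal{D}$ with
$|H_{kl} v_k| > \delta$ for some $\Phi_k \in \mathcal{D}$ — and
re-diagonalization until a fixed point, then halves $\delta$.  The run
stops when an expansion would exceed `D_cap`, when the full CI space is
reached, or when $\delta$ underflows `min_delta` (default $10^{-9}$; the
inner fixed-point criterion is applied literally, and the per-level trace
of $(\delta, K, \epsilon)$ makes the schedule auditable).  Double-excitation
screening magnitudes are read directly off the integral arrays — for a
double excitation $|H_{kl}|$ depends only on the four moved indices — while
singles are evaluated in full; a reference per-determinant Slater–Condon
scan is kept as `method = "scan"` and the two paths are asserted identical.

# Epstein–Nesbet PT2 and the extrapolation

The model Hamiltonian is the full block inside $\mathcal{D}$ plus the bare
diagonal outside, so the perturber denominators use the variational
subspace energy $\epsilon_0$ — not Møller–Plesset orbital energies:

$$ \epsilon^{(\text{PT2})}_0 = -\sum_{\Phi_k \notin \mathcal{D}}
   \frac{\bigl|\sum_{\Phi_l \in \mathcal{D}} H_{kl} v_l\bigr|^2}
        {\langle\Phi_k|H|\Phi_k\rangle - \epsilon_0}. $$

Every summand is non-positive for the ground state, the sum runs only over
external determinants connected by single/double excitations, and the
accumulation is hash-keyed by external determinant so memory scales with
the connected complement.  Denominators below $10^{-12}$ in magnitude abort
with the offending determinant named — a vanishing Epstein–Nesbet
denominator signals a near-degeneracy the subspace should absorb instead.

The extrapolation is an **unweighted** ordinary-least-squares line of
subspace energy against correction (the reference leaves the weighting
unspecified; unweighted is the neutral choice, and the fit diagnostics
expose when it is inadequate).  Regressing correlation energy instead of
total energy shifts the intercept by exactly the reference constant — a
property asserted by test, so the choice of regression variable is
immaterial.

# The synthetic fixture generator

`make_fixture()` writes self-contained FCIDUMP files so every stage is
testable without external data:

* `toy2` — a two-orbital, two-electron set with minimal-basis-like
  magnitudes (core energy 0.7137, paired-orbital repulsions around
  0.66–0.70, exchange 0.18);
* `toy4` — a deterministic four-orbital chain with hopping $-0.25$ and
  distance-decaying repulsion;
* `hubbard_like` — hopping plus on-site repulsion only;
* `random` — seeded random integrals whose two-electron magnitudes decay
  exponentially with index distance, symmetrized to the full 8-fold class,
  with positive on-diagonal repulsion.  The decay keeps $\lambda$ bounded
  (roughly 3 at $M = 3$, 11 at $M = 5$) so qDRIFT segment counts stay
  realistic at emulation scale.

What these fixtures emulate: non-trivial but bounded off-diagonal coupling,
a dominant Hartree–Fock reference, and measurement statistics whose
occupancy signal actually localizes the important excitations.  What they
do **not** emulate: real molecular integral structure (point-group
symmetry, shell structure, near-degeneracies at bond dissociation),
hardware noise beyond independent readout bit flips (no correlated errors,
no decoherence during evolution — the statevector is exact between
rotations), and scale (a passing 8–10 qubit recovery says the machinery is
correct, not that the method is competitive at 42 qubits).

# Numerical choices

* Integral symmetry is *enforced on read* (8-fold expansion from canonical
  representatives) and validated on write; `molecular_integrals()` checks
  both symmetries to $10^{-8}$ by default.
* Jordan–Wigner coefficients below `drop_tol = 1e-10` are dropped: below
  integral-symmetry noise, far above double-precision epsilon.
* Diagonalization is dense `eigen()` up to a configurable cutoff (default
  1500 determinants) and ARPACK (smallest-algebraic, via igraph's
  interface) above it; the two paths agree to $10^{-8}$ on the fixtures.
  Eigenvector sign is fixed by making the largest-magnitude coefficient
  positive; screening ties break lexicographically on the determinant
  masks, so every run is reproducible from its seed.
* Statevectors are capped at 16 qubits by default ($2^{16}$ complex
  amplitudes); the cap is an argument, not a hard limit.
* All randomness flows through a single seed per run; sub-seeds are derived
  with a Lehmer step and stay below $2^{31}$.  Seeding is
  save-and-restore, so package calls never disturb the caller's RNG state.

# Problem sizes in the tests

The suite exercises: dense-oracle agreement on 20 random instances at 4–8
spin orbitals; sampler frequency checks at $10^5$ draws (3σ per-term bounds
in the normal regime plus a chi-squared goodness-of-fit); qDRIFT channel
accuracy with 200 realizations per point on a 3-point $\epsilon$ ladder at
6 qubits; end-to-end noiseless FCI recovery at 8 and 10 qubits with the
subspace cap set to the full CI dimension; and a readout-noise sweep
($p_\text{flip} \in \{0, 0.02, 0.05\}$, five seeds each) on the 8-qubit
chain with a deliberately constrained subspace budget (`D_max = 25` of 36)
so that degraded measurement quality is visible in the median energy error
rather than hidden by a saturated subspace.

# Known limitations

* Two-electron integrals are stored densely ($M^4$ doubles), which is the
  right trade-off at emulation scale ($M \lesssim 24$) and the wrong one
  beyond it.
* The Epstein–Nesbet sum is deterministic; no semistochastic estimator is
  provided, so PT2 cost grows with the connected complement.
* No point-group or $S^2$ symmetry handling: sectors are fixed by particle
  number per spin only.
* The per-round trace records the variational energy only; PT2 appears at
  checkpoints.
* `space_dimension()` is exact only while the binomial product stays below
  $2^{53}$ — comfortably true for every system the in-memory solvers can
  face.
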