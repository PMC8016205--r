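---
title: "Multilevel coupled cluster in reduced orbital spaces: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel coupled cluster methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the multilevel CC2 and CCSD models, the orbital-space constructions, the
Cholesky factorization of the electron repulsion integrals, the solvers,
and the numerical decisions taken where the design was genuinely open.

## Models and assumptions

All methods assume a closed-shell restricted Hartree–Fock reference;
open-shell electron counts are rejected at input. The cluster operator of
MLCC2 is $X_1 + S_2$ with unrestricted singles and doubles restricted to an
active orbital space; $S_2$ is treated perturbatively as in CC2, so in a
basis where the active–active occupied–occupied and virtual–virtual Fock
blocks are diagonal ("semicanonical") the doubles amplitudes have the
closed form $s_{aibj} = -\tilde g_{aibj} / (\epsilon_a + \epsilon_b -
\epsilon_i - \epsilon_j)$, where $\tilde g$ are the $X_1$-transformed
two-electron integrals. MLCCSD is implemented in its two-level CCS/CCSD
form: a single active space for a full $T_2$, no intermediate $S_2$ tier.
Only excitation energies (right eigenvalues of the Jacobian) are targeted;
left eigenvectors, transition moments and gradients are out of scope.

The working equations are formulated entirely in terms of Cholesky vectors
in the $X_1$-dressed basis, $\tilde L^J = \Lambda^p L^J \Lambda^{h,T}$ with
$\Lambda^p = \begin{pmatrix} I & 0 \\ -t_1 & I\end{pmatrix}$ and
$\Lambda^h = \begin{pmatrix} I & t_1^T \\ 0 & I \end{pmatrix}$, so the
similarity transformation costs $n_{\mathrm{MO}}^2 N_J$ per iteration. The
closed-shell spin adaptation of the doubles residual (the ring, ladder and
effective-Fock contractions, including all terms quadratic in $T_2$) was
derived by explicit spin summation; every contraction was verified to
machine precision against an independent spin-orbital implementation at
random amplitudes, and the Jacobians against central finite differences of
the residuals. This verification strategy — rather than transcription from
a printed appendix — anchors the correctness of the amplitude equations,
and is exercised by the test suite on every run.

With an empty active space both models reduce exactly to CCS (singlet CIS
energies, zero correlation energy up to the Cholesky consistency error
discussed below); with all orbitals active they are exactly CC2 and CCSD.
These limit identities are asserted numerically in the tests.

## Orbital spaces

**CNTOs.** CCS excitation vectors $R_1$ for the requested states are
augmented with CIS(D)-style approximate doubles
$R_{aibj} = -\bar g_{aibj} / (\epsilon_a+\epsilon_b-\epsilon_i-\epsilon_j-
\omega^{\mathrm{CCS}})$, where $\bar g$ is the one-index ($R_1$)
transformation of $(ai|bj)$ assembled from the Cholesky factors;
denominators below $10^{-6}$ are level-shifted with a warning. The
occupied and virtual CNTO matrices are $M = R_1^T R_1 + \tfrac12
(\text{doubles contraction})$ and its virtual mirror — both symmetric
positive semidefinite Gram forms — summed element-wise over all requested
states (degenerate multiplets should always be summed together, keeping
the selection basis-independent). Active orbitals are the eigenvectors
with the largest eigenvalues; the count rule is either explicit
$(n_o^a, n_v^a)$ or the ratio rule $n_v^a = \mathrm{round}(n_o^a N_v/N_o)$
with round-half-up for determinism. Eigenvalue ties at the cut include
both tied orbitals (with a warning) to avoid seed-dependent physics.

**Cholesky/PAO.** For spatially local states, active occupied orbitals
come from a pivoted Cholesky decomposition of the idempotent Hartree–Fock
density $D = C_{occ} C_{occ}^T$ with pivots restricted to AOs on active
atoms (pivot threshold $10^{-2}$ by default), and active virtuals from
projected atomic orbitals $C^{PAO} = (I - DS)$ restricted to active-atom
columns, orthonormalized by the canonical Löwdin procedure with a
linear-dependence cutoff (default $10^{-6}$ relative). Inactive sets
complete the spans; the partition is always S-orthonormal and complete.

**Region selection.** Radius-based selection keeps solvent molecules
atomically: a molecular fragment (connected components under a
1.3 × covalent-radius-sum bond criterion) enters when any of its heavy
atoms lies within the radius of a center atom. This avoids dangling bonds
and matches the solute/solvent intent of reduced-space calculations.

## Frozen-Fock reduced-space embedding

In a reduced-space run only the occupied Cholesky orbitals and PAOs of the
selected region are retained; every remaining occupied orbital is frozen
and contributes only its mean-field term $F^f = 2J(D_f) - K(D_f)$. The
package folds $F^f$ into the effective one-electron Hamiltonian
$h_{\mathrm{eff}} = h + F^f$ *before* the $X_1$ dressing; with this choice
the effective Fock matrix of the correlated problem equals the Fock matrix
of the total density exactly, the Brillouin condition survives the
truncation, and a reduced-space run with nothing actually frozen is
numerically identical (below $10^{-9}$ hartree) to the standard
calculation. Frozen core is implemented the same way: the lowest
(element-core-count) orbitals, canonical or semicanonicalized-retained,
are moved to the frozen set. The multilevel Hartree–Fock reference of the
original framework is not implemented; the reference is always a standard
RHF (optionally frozen-Fock-reduced afterwards), and the iterative
MO-basis effective-Fock update that an MLHF optimization would need is
deliberately out of scope.

## Two-step Cholesky factorization and MO screening

Step 1 selects the pivot set by greedy max-diagonal pivoting on the
(optionally screened) ERI diagonal, with a Schwarz-style prescreen that
drops pairs whose initial screened diagonal is below $\tau \times 10^{-2}$
from pivot candidacy; ties are broken toward the lowest pair index for
platform determinism, and the updated diagonal is clamped at zero with a
breakdown error if it falls significantly negative. Step 2 factorizes
$S_{KL} = (K|L) = QQ^T$ and assembles the vectors directly in the MO basis,
$L = X Q^{-T}$ with $X_{pq,K} = (pq|K)$, in batches over the first MO
index; batching is exactly result-invariant. The unscreened decomposition
guarantees a maximum AO-basis reconstruction error of $\tau$ (checked
exhaustively on small fixtures), and the vector count follows the familiar
$N_J \approx M N_{AO}$ rule at $\tau = 10^{-M}$.

For the method-specific MO screening, pivot *selection* uses the screened
diagonal $\tilde D_{\alpha\beta} = D_{\alpha\beta} w_\alpha w_\beta$ with
$w_\alpha = (\sum_p |C^a_{\alpha p}|)^2$ built from the full reduced-space
coefficient matrix. During implementation it became clear that terminating
on $\tilde D \le \tau$ alone does not certify the quantity one actually
cares about — the MO-basis reconstruction error — which on seeded fixtures
crept up to about $2\tau$; conversely, rescaling $\tau$ by the rigorous
worst-case amplification factor of the transformation is so pessimistic
that the screened pivot set grows beyond the unscreened one, defeating the
purpose. The package therefore *terminates* on the exact residual MO-pair
diagonal $M_{pq,pq}$, tracked incrementally at $n_{\mathrm{MO}}^2$ cost per
pivot: since the residual matrix is positive semidefinite, Cauchy–Schwarz
gives $|\Delta_{pq,rs}| \le \sqrt{M_{pq,pq} M_{rs,rs}} \le \tau$, a
rigorous MO-error certificate. Across seeded fixtures this yields
screened-to-unscreened vector ratios of 0.65–0.9 (improving with system
size) with observed MO errors of 0.7–1.0 τ, while the AO-basis error is
large — exactly the signature of a factorization that describes only the
integrals the reduced-space calculation uses. Default thresholds:
$\tau = 10^{-3}$ unscreened, $10^{-4}$ screened.

## Solvers

Ground states use DIIS (subspace 8, coefficients constrained to sum to
one, drop-oldest retry on singular normal equations) over quasi-Newton
steps preconditioned by orbital-energy differences. Excited states use a
real non-symmetric Davidson solver: modified Gram–Schmidt
orthonormalization (twice) of the expansion vectors, Ritz extraction by
lowest real part, orbital-energy-difference preconditioning, restart by
collapse onto the current Ritz vectors at the subspace cap, and a
deterministic seeded perturbation of the unit start vectors. Complex Ritz
pairs may appear transiently in the subspace and are handled by taking
real parts; a complex pair that survives to convergence raises an error
naming the state, as the targeted states are real. Default residual
thresholds follow standard practice: SCF gradient $10^{-8}$, ground-state
$|\Omega| < 10^{-6}$, excited-state residual $10^{-4}$; identity-type
checks in the tests tighten these so that solver error (which enters
eigenvalues roughly as the residual squared) sits far below the asserted
tolerances.

## Integral engine and bundled basis sets

Integrals over contracted Cartesian Gaussians (6d) are computed with the
McMurchie–Davidson scheme up to g functions, with Schwarz screening of
shell quartets and per-component normalization through the overlap
diagonal. STO-3G uses the published least-squares fits with standard
per-element scale factors. The double-zeta sets use the standard cc-pVDZ
primitive exponents for H/C/N/O; the two general s-contractions of C, N
and O are derived in-repo from closed-shell ten-electron-ion RHF atomic
orbitals computed in the uncontracted primitive set — a reproducible,
near-optimal general-contraction scheme (water RHF lands within about one
millihartree of the accepted contracted value, the deficit being ordinary
contraction loss). Because every validation in the package is an internal
consistency or property check, small deviations from the official
contraction tables are immaterial. Cartesian d components slightly enlarge
the space relative to spherical sets; all quoted numbers refer to the
bundled Cartesian basis.

## The solvated fixture generator

`generateSolvatedFixture()` emulates the solute-in-water systems used to
study reduced-space methods: rigid water molecules at random orientations
are packed shell-wise around the solute with a rejection threshold of
1.8 Å between new and existing atoms, deterministically for a fixed seed.
It reproduces the *geometric* situation the methods care about — a local
chromophore with increasingly distant, weakly coupled solvent — but not
hydrogen-bond network statistics, thermal sampling, or bulk density, so
passing tests demonstrate correct method behavior on realistic topologies,
not solvation thermodynamics. The convergence study conditions used by the
tests and the acceptance script are: formaldehyde plus 10 waters in
STO-3G (82 AOs), lowest state, CNTO spaces of 4, 8, 12 and 16 active
occupied orbitals under the ratio rule, Cholesky threshold $10^{-5}$; the
smallest space misses the full-CC2 excitation energy by about 0.2 eV and
the largest by a few $10^{-4}$ eV. Desk-scale problem sizes throughout the
test suite range from 7 to 82 AOs.

## Numerical choices and degenerate inputs

* Density convention $D = C_{occ} C_{occ}^T$; all factors of two live in
  the Fock and energy expressions.
* The correlation energy is evaluated with undressed integrals,
  $E = \sum (t_2 + t_1 t_1) (2 g_{iajb} - g_{ibja}) + 2 \sum F_{ia} t_{ai}$.
* Orbital energies for denominators always come from the semicanonical
  diagonal; a vanishing active-space denominator raises an error pointing
  at semicanonical degeneracies rather than silently shifting.
* The Fock matrix used for orbital energies is built from exact AO
  integrals while the residuals use Cholesky-reconstructed ones; the CCS
  limit therefore shows a residual correlation energy of order the
  decomposition threshold squared divided by the gap. Identity tests
  tighten τ accordingly.
* Doubles amplitudes are stored as full active-space arrays; excitation
  vectors pack the unique pairs $(ai) \ge (bj)$.
* Eigen-decompositions are wrapped to return ascending eigenvalues
  (base R returns descending), a convention bug that the H₂ fixture
  catches instantly if reintroduced.

## Known limitations

Desk scale only: the full ERI tensor is held in core, so a few hundred
AOs is the practical ceiling. Closed-shell references only; two-level
CCS/CCSD only (no CCS/CC2/CCSD three-level operator, no triples); energies
only (no transition moments or gradients); no point-group symmetry; the
optional on-disk factor cache mentioned in some Cholesky-based codes is
not provided. The CNTO construction targets singly-excited states — states
with doubly-excited character will be poorly ranked, which is a property
of the construction rather than of this implementation.
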