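# mlccx

Multilevel coupled cluster excitation energies in reduced orbital spaces,
as a self-contained R package. `mlccx` is aimed at quantum-chemistry method
development and teaching at desk scale: it computes CC2- and CCSD-quality
excitation energies of closed-shell molecules while restricting the
expensive double-excitation cluster operator to an *active orbital space*,
and it can embed the whole correlated calculation in a frozen Hartree–Fock
environment so that only a molecular subregion enters the coupled cluster
equations at all.

## The models

For a closed-shell Hartree–Fock reference |HF⟩ the multilevel CC2 (MLCC2)
wave function is

    |CC⟩ = exp(X₁ + S₂) |HF⟩

with unrestricted singles X₁ and doubles S₂ restricted to excite within an
active set of n_oᵃ occupied and n_vᵃ virtual orbitals; S₂ is treated
perturbatively exactly as in CC2, so the doubles equations

    Ω_μ2 = ⟨μ₂ˢ| Ĥ + [F, S₂] |HF⟩ = 0

are solved analytically each iteration in a *semicanonical* basis (the
active–active occupied–occupied and virtual–virtual Fock blocks are
diagonal), while the singles equations Ω_μ1 = 0 are solved with a
DIIS-accelerated quasi-Newton scheme. Multilevel CCSD in its CCS/CCSD
two-level form replaces S₂ by a full (untruncated-in-order) T₂ restricted
to the same kind of active space. Excitation energies ω are right
eigenvalues of the Jacobian A = ∂Ω/∂t, obtained matrix-free with a
non-symmetric Davidson solver; with an empty active space both models
collapse to CCS (singlet CIS energies), and with every orbital active they
are exactly CC2 and CCSD.

Everything is formulated over Cholesky-factorized electron repulsion
integrals, g_pqrs = Σ_J L_pq^J L_rs^J. The factors are built by a
*two-step* pivoted decomposition: the pivot set ("Cholesky basis") is
selected first by greedy max-diagonal pivoting to a threshold τ, then the
vectors are assembled directly in the MO basis through the RI-like
expression L = X Q⁻ᵀ with S_KL = (K|L) = Q Qᵀ, so AO-basis vectors are
never stored. For reduced-space work a method-specific *MO screening*
shrinks the pivot set further while certifying the reconstruction error of
the MO-basis integrals.

Active spaces come from either

* **CNTOs** — correlated natural transition orbitals, built from CCS
  excitation vectors augmented with CIS(D)-style approximate doubles; the
  eigenvalue spectra of the occupied/virtual transition densities rank the
  orbitals, or
* **Cholesky/PAO** — occupied Cholesky orbitals (pivoted decomposition of
  the Hartree–Fock density with pivots restricted to active-atom AOs) plus
  projected atomic orbitals for the virtual space, for spatially local
  states.

The AO integral engine (overlap, kinetic, nuclear attraction, ERI over
contracted Cartesian Gaussians; McMurchie–Davidson) is part of the package,
with STO-3G, cc-pVDZ and aug-cc-pVDZ data bundled for H, C, N and O.

## A worked example

Three lowest singlet states of water in the bundled double-zeta basis,
with a CNTO active space of 3 occupied orbitals (the ratio rule then picks
15 of 20 virtuals), compared with full CC2:

```r
library(mlccx)
sys  <- geomWater("cc-pvdz")
r    <- mlccRun(sys, runConfig(method = "mlcc2", n_states = 3, n_active_occ = 3))
full <- mlccRun(sys, runConfig(method = "cc2", n_states = 3))
print(r)
compareRuns(list(r, full))
```

```
MLCC run: mlcc2 ( cnto )
  AOs: 25  MOs: 24  active occ/virt: 3 / 15  N_J: 75 
  E(SCF)  = -76.0256432667 hartree
  E(corr) = -0.1391758903 hartree
  omega [hartree]: 0.30693725 0.38829964 0.40276164 
  omega [eV]     :  8.3521879 10.5661715 10.9597024 

  n_active_occ n_active_virt omega1_ev delta1_ev omega2_ev delta2_ev omega3_ev delta3_ev
1            3            15  8.352188  0.269435  10.56617  0.378823  10.95970  0.211050
2            4            20  8.082753  0.000000  10.18735  0.000000  10.74865  0.000000
```

The report lists the problem sizes (25 AOs; 24 correlated MOs after
freezing the oxygen 1s core; N_J = 75 Cholesky vectors at the default
τ = 10⁻³), the SCF and correlation energies in hartree, and the excitation
energies in hartree and eV (1 hartree = 27.211386 eV). With 3 of 4 occupied
and 15 of 20 virtual orbitals active, the lowest MLCC2 excitation energy is
0.27 eV above its full-CC2 limit; `compareRuns` tabulates those deltas
against the largest-active-space run, and the deltas shrink toward zero as
the active space grows.

A command-line interface wraps the same workflow:

```sh
inst/cli/mlccx run --method mlcc2 --basis cc-pvdz --n-states 3 \
    --active-occ 3 --out report.json geometry.xyz
inst/cli/mlccx compare report_small.json report_big.json
```

Every key of the YAML config file (`--config run.yml`) is mirrored by a
flag; the JSON report contains every number the CLI prints.

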