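---
title: "Models and methods behind idrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idrsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

idrsim models intrinsically disordered protein regions (IDRs) as
one-bead-per-residue heteropolymers, simulates their conformational
ensembles with Langevin dynamics, and layers sequence design, proteome
informatics, homolog conservation analysis and a fast recurrent-network
surrogate on top of the simulator. This vignette describes the models,
the tunable parameters and the numerical and design choices, and states
what the synthetic test conditions do and do not establish.

## The coarse-grained model

Each residue is a single bead. Three energy terms act on the chain:

* **Harmonic bonds** between consecutive beads,
  $U_b(r) = k\,(r - r_0)^2$, with defaults $k = 9.6$ kcal/mol/Å² and
  $r_0 = 3.81$ Å (the Cα–Cα virtual bond length).
* **Wang–Frenkel pair potential** between all non-bonded bead pairs,
  $$U_{\mathrm{WF}}(r) = \varepsilon\,\alpha
    \left[\left(\tfrac{\sigma}{r}\right)^{2\mu} - 1\right]
    \left[\left(\tfrac{r_c}{r}\right)^{2\mu} - 1\right]^{2\nu},$$
  with $r_c = 3\sigma$ and $\alpha$ the closed-form normalization that
  makes the well depth exactly $-\varepsilon$. Unlike Lennard–Jones, the
  potential is identically zero at and beyond its cutoff, so no
  truncation artifacts arise.
* **Debye–Hückel electrostatics** between charged beads
  (R, K: $+1$; D, E: $-1$; H: 0 at neutral pH),
  $$U_{\mathrm{DH}}(r) = \frac{C\,q_i q_j}{\epsilon_r\, r}
    e^{-r/\lambda_D},$$
  energy-shifted to zero at a 35 Å cutoff ($\approx 4.4\,\lambda_D$; the
  shift preserves force continuity). The screening length is computed
  from the closed form
  $\lambda_D = \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}$,
  which gives 7.95 Å at the default 150 mM ionic strength, 300 K and
  relative permittivity 80.

Bonded 1–2 pairs are excluded from the non-bonded sums; 1–3 pairs are
included, the standard choice for bead–spring models. All pair physics
is parameter-set-agnostic: `load_parameter_set()` reads a structured
text file with bead masses, charges and diameters, a full 210-entry pair
table ($\varepsilon$, $\sigma$, $\mu$, $\nu$ per unordered residue
pair), bond constants and electrostatic constants, and validates
completeness and symmetry before any simulation.

### The shipped parameter set

The shipped file `params_mpipi_synthetic.prm` keeps this functional form
but is a *synthetic* parameter set: its pair epsilons are constructed by
geometric-mean combination of per-residue stickiness values (aromatics
strongest, then aliphatics, then polar residues) with cation–π boosts
for arginine–aromatic (×2.0) and lysine–aromatic (×1.3) pairs, and its
bead diameters are standard amino-acid van der Waals diameters. It is a
physically sensible default for method development and testing, not a
published, experimentally benchmarked pair table; a benchmarked table in
the same file format can be dropped in without code changes (the
`mpipi-gg` slot exists for a fine-tuned file).

## Simulation protocol

`simulate_protocol()` builds a random coil in the excluded-volume limit
(sequential placement at the bond length with hard-core rejection),
minimizes it (steepest descent with backtracking line search; at most
1,000 iterations or a maximum per-bead force below $10^{-8}$
kcal/mol/Å), then integrates Langevin dynamics with the BAOAB splitting
scheme, which samples the canonical distribution accurately at large
steps. Defaults follow the full production protocol: 20 fs timestep,
300 K, friction $\gamma = 1/(100\ \mathrm{ps})$, a 500 Å cubic periodic
box (a "500-Å cube"; a 500 Å³ *volume* could not contain a chain), 10 ns
discarded equilibration, frames saved every 2 ns, and production of 6 µs
below 250 residues or 10 µs above. A chain of exactly 250 residues falls
between the two stated rules and is assigned the shorter schedule with a
warning.

The **desk preset** keeps the same physics but scales the schedule
(200 ns production, 5 ns equilibration, 1 ns saving) so that a
30–50-residue chain completes in about a minute on one CPU. Desk-scale
ensembles are adequate for the package's correctness checks and for
ranking sequences, but they are not converged production ensembles; the
paper-scale preset exists for that purpose.

Velocities are drawn from the Maxwell–Boltzmann distribution at the
target temperature; per-frame potential and kinetic energies are stored
with the trajectory, so the instantaneous kinetic temperature
$T_{\mathrm{kin}} = 2\,\mathrm{KE}/(3 N k_B)$ is available for
thermostat checks. With a 20 fs step the BAOAB kinetic temperature
carries a small $O(\Delta t^2)$ bias (about 1 % low for the stiffest
bond mode); tests allow for this explicitly. Trajectories are written as
multi-frame XYZ plus a one-CA-per-residue PDB topology and a JSON
sidecar with full configuration provenance.

## Ensemble observables

`chain_dimensions()` builds the mass-uniform gyration tensor (one-bead
models have near-uniform bead masses; mass weighting is an option),
giving $R_g$, the end-to-end distance $R_e$, and the eigenvalues used by
the asphericity
$$\delta = 1 - 3\,
  \frac{\langle \lambda_1\lambda_2 + \lambda_1\lambda_3 +
        \lambda_2\lambda_3\rangle}{\langle(\lambda_1 + \lambda_2 +
        \lambda_3)^2\rangle},$$
which is 0 for spherically symmetric configurations and 1 for a rod.
Numerator and denominator are ensemble-averaged before the ratio (the
common simulation convention; per-frame averaging is an option — both
stay in $[0,1]$).

`internal_scaling()` averages inter-residue distance over all pairs at
each sequence separation $\Delta$, and `fit_scaling_law()` fits
$R(\Delta) = R_0\,\Delta^\nu$ by least squares in log–log space. The fit
excludes $\Delta < 10$ by default: short separations are dominated by
bond structure rather than polymer scaling. Log-space fitting weights
relative errors uniformly across the decade span of the profile, which
is what a scaling exponent estimate should do.

The Gaussian-chain null (`afrc_reference()`) is
$R_e^{\mathrm{null}} = b_{\mathrm{eff}}\sqrt{N}$,
$R_g^{\mathrm{null}} = R_e^{\mathrm{null}}/\sqrt{6}$ — a Flory exponent
of exactly 0.50. The default $b_{\mathrm{eff}} = 3.81$ Å was calibrated
once from a long bonds-only (ideal-chain) simulation of a 50-mer with
the shipped force field, which measured
$\sqrt{\langle R_e^2\rangle / N} = 3.81$ Å, fitted $\nu = 0.501$, and
$\langle R_e^2\rangle/\langle R_g^2\rangle = 5.93$ (the freely-jointed
chain expectation at $N = 50$ is $5.88$, approaching 6 as
$N \to \infty$). Only the exponent 0.50 is a model guarantee; the
prefactor is a calibrated package constant and is configurable.
Normalized dimensions divide measured $R_g$/$R_e$ by these nulls, so 1
means Gaussian-chain-like, above 1 expanded, below 1 compact.

Replicate summaries report the across-replicate s.e.m. (sample standard
deviation over $\sqrt{k}$); with one replicate the s.e.m. is reported as
unavailable rather than zero.

## Sequence features and the design library

Charge patterning features follow their standard definitions: NCPR and
FCR are net and total charge per residue; $\kappa$ compares blob-level
(window sizes 5 and 6, averaged) charge asymmetry against the fully
segregated arrangement of the same composition, so 0 is well-mixed and 1
maximally segregated; SCD is the $\sqrt{|j-i|}$-weighted charged-pair
sum; SHD is the $1/(j-i)$-weighted hydropathy-pair sum. Histidine is
treated as uncharged (consistent with its near-zero bead charge at
neutral pH) and is not pooled with the aromatics. No specific hydropathy
scale is canonical for SHD; the package defaults to Kyte–Doolittle
rescaled to $[0,1]$ and accepts any user scale.

The design module emulates a synthetic IDR library: composition designs
use largest-remainder apportionment so counts are exact and testable,
with the unspecified remainder filled deterministically from a
disorder-promoting alphabet (G, S, T, N, Q, P, E, D, K, R, A) — the seed
shuffles positions but never changes composition, so replicate designs
are compositionally identical. Restricting the background to
disorder-promoting residues keeps the library plausibly disordered
without calling an external disorder predictor; a predicate hook
(`disorder_filter`) accepts one when available. $\kappa$-targeted design
runs a seeded greedy pair-swap search (up to $10^5$ swaps) from a
composition design, with the segregated arrangement returned in closed
form for target 1. Titration series default to 100 sequences per feature
value at length 100. Sticker–spacer constructs concatenate
glycine–serine dipeptide spacers (length read as residues, 2–120) with
polytyrosine stickers (0–8), eight repeats by default.

## Proteome scan and homolog conservation

The sliding-window scan computes, for every 51-residue window of an
IDR, an estimated $R_e$ divided by the 51-mer Gaussian null. The
estimator is a plugin (sequence → Å): the shipped options are a
closed-form composition stub (fast, for tests and examples), the
simulator at desk scale, and a trained surrogate. Compact and expanded
subregions are the bottom and top 2.5 % of the pooled window population;
thresholds are order statistics chosen so that strict-inequality
labeling marks exactly $\lfloor nq \rfloor$ windows when values are
distinct (ties shrink the tails, never grow them, and an all-equal
population yields no calls). IDRs are length-filtered to 35–3,000
residues on loading. Windows are reported individually; an optional
merge produces maximal overlapping runs, and per-protein counts are
emitted both ways because "ten or more subregions" can be read against
either. Amino-acid enrichment uses pseudocounted (0.5 per residue class)
log2 frequency ratios, so tail-vs-background swaps negate the table
exactly.

Homolog analysis consumes pre-aligned MSAs (aligned FASTA or Clustal).
Reference domain boundaries (ungapped coordinates, tiling the protein)
are projected to alignment columns; each member's homologous IDR is its
ungapped residues in the IDR column span, which absorbs member
insertions relative to the reference between folded domains. Filters
follow the stated rules: drop sets whose reference IDR is shorter than
40 residues, drop members shorter than 15, keep sets with strictly more
than 10 members including the reference. Dispersion uses the sample
(n−1) standard deviation of member lengths and estimated $R_e$; a set
whose $R_e$ varies less than its length variation would predict is the
operational signature of conformational buffering. MSA similarity
implements SumOfPairs (all row pairs per column) and StarScore
(alphabetically tie-broken consensus against all rows per column) over
BLOSUM62, normalized by row count and alignment length; gap-containing
pairs contribute zero but columns still count toward the normalization
(the conservative choice; configurable via a custom matrix). The
BLOSUM62 fixture ships in NCBI text layout and is verified against the
Biostrings reference matrix in the test suite.

## The recurrent surrogate

The sequence-to-scalar surrogate is a stacked bidirectional GRU over
one-hot encoded sequences (fixed alphabet order ACDEFGHIKLMNPQRSTVWY),
with the final forward and backward hidden states pooled through a
linear head. It trains with an L1 objective and Adam (learning rate
0.001), a 64:16:20 train/validation/test split with largest-remainder
counts, 5-fold cross-validation over train+val for hyperparameter
comparison (500 epochs), and final weights taken from the epoch with the
lowest validation loss (750 epochs by default). Default hyperparameters
(2 layers, hidden dimension 32, batch 16) sit inside the searched ranges
(1–2, 10–55, 4–32); values outside warn but proceed. The forward and
backward passes are implemented in C++ with exact analytic
backpropagation through time — the test suite checks the gradient
against central differences to $10^{-6}$. Sequences are evaluated at
their own lengths (gradient accumulation over the batch), so batched and
single-sequence predictions are identical by construction; loss
monotonicity is never asserted (stochastic optimization), only the
argmin-epoch selection contract. One model predicts one property; five
separate single-property models (Rg, Re, asphericity, ν, R0) are the
intended deployment, trained from simulator-labeled libraries.

## What the synthetic conditions establish

The package's tests run on synthetic sequences and desk-scale ensembles:
designed compositions, closed-form labels, constructed MSAs, and
short-schedule simulations with fixed seeds. They establish that the
energies and forces are exact against independent oracles, that the
integrator samples the canonical ensemble (dimer bond statistics,
kinetic temperature, free-bead diffusion, NVE drift), that an ideal
chain recovers Gaussian statistics ($\nu = 0.5$,
$R_e^2/R_g^2 \approx 6$), and that every informatics computation matches
brute-force or hand-computed references. They do not establish
agreement with experimental SAXS/FRET dimensions, which depends on the
quality of the pair table, nor surrogate accuracy on natural proteomes,
which requires a large simulator-labeled corpus. Problem sizes were
chosen to make the full suite complete in minutes on one CPU: dimer
150 ns, 30-mer thermostat check 30 ns, ideal chain 300 ns, surrogate
recovery on 300 designed 40-mers for 150 epochs; the acceptance script
runs the 30-mer at the full desk schedule (200 ns).

## Known limitations

* Single chains only: no multi-chain or condensate simulations, no
  hydrodynamic interactions.
* The shipped pair table is synthetic (combination-rule) — quantitative
  comparison with experiment requires loading a benchmarked table.
* The desk preset trades sampling for speed; its s.e.m. estimates are
  honest but wide.
* Disorder prediction is out of scope; IDR boundaries are inputs.
* The $\kappa$ swap search is stochastic and can report unreachable
  targets for extreme compositions; it then errors with the best value
  found rather than silently returning it.
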