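---
title: "Methods: identifying protein CoAlation and its redox biochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying protein CoAlation and its redox biochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalscan)
```

# The problem

Protein CoAlation is the covalent modification of a protein cysteine by
coenzyme A through a mixed disulphide (P-S-S-CoA). It is a
redox-regulated post-translational modification: under oxidative stress
the reactive thiol of an enzyme such as GAPDH is either irreversibly
overoxidised (sulphinate/sulfonate) or reversibly protected by
S-thiolation with a low-molecular-weight thiol. `coalscan` implements
the complete desk-scale analysis by which CoAlation is identified from
tandem-MS data and characterised biochemically: modified-peptide mass
enumeration, CoA-diagnostic neutral-loss scanning, b/y annotation and
site localization, intact-mass occupancy, inactivation and
Michaelis-Menten kinetics, and cysteine pKa titration.

# Mass calculus

Peptide neutral masses are sums of monoisotopic residue masses (20
standard residues, five decimals, CODATA/IUPAC values) plus one water
(18.010565 Da) plus any modification deltas; ions follow
$m/z = (M + z\,m_p)/z$ with $m_p = 1.007276$ Da. The modification
catalog carries exact and nominal deltas; CoAlation is CoA − 2H
= +765.09956 Da exact.

A documented systematic offset: published theoretical m/z values for
the reference peptides sit ~0.003–0.005 below ours at 2+/3+ because the
constants behind them (proton vs hydrogen mass, rounding) are not
stated. We therefore compare published theoretical m/z at 0.005
absolute tolerance and do not attempt to resolve the offset.

Lys-C digestion cleaves C-terminal of every lysine, *including* K-P
bonds — that is the protease's canonical specificity, unlike trypsin —
with a toggle for the trypsin-like exception. Missed cleavages
concatenate up to `max_missed` adjacent fragments (default 1). Residue
numbering starts at 1 at the first residue of the supplied sequence; to
reproduce coordinate conventions of a different construct, supply the
corresponding FASTA.

# Peptidoform enumeration

Because identification workflows alkylate all free thiols with
iodoacetamide before digestion, a cysteine always carries exactly one
state; the unmodified state is excluded by default
(`allow_unmodified = TRUE` restores it). For a peptide with $c$
cysteines and $s$ per-site states, enumeration yields $s^c$ per-site
assignments plus, when intramolecular disulphides are allowed,
$\binom{c}{2} s^{c-2}$ pairings — the count law the tests verify by
brute force. At most one CoAlation per peptide is allowed by default
(the published assignments annotate a single CoA per peptide);
cross-peptide disulphides are out of scope. When one observation
matches several forms, all are reported ranked by |error| — the in vivo
data genuinely cannot distinguish which of the two active-site-peptide
cysteines carries the CoA, and the output preserves that ambiguity.

# CoA fragmentation diagnostics

Under CID the CoA moiety fragments preferentially, releasing neutral
losses of nominally 410, 428 and 508 Da while the cysteine retains
+258, +338 or +356 Da. The nominal loss + remnant sums are 765 ± 1; the
1-Da mismatches reflect hydrogen-transfer ambiguity, so both the
nominal losses and their H-shift variants (409/427/507) are accepted
and neither is privileged. Diagnostic and remnant matching therefore
uses nominal masses with a ±1.0 Da window, whereas peptide backbone b/y
ions use exact masses at the workflow's stated 0.5 Da tolerance.

The scanner searches each loss $L$ at product charges
$z' = z, z-1, \ldots, 1$ (the product charge is not determinable from
the source data; searching the superset is conservative), i.e. at
$(M_\mathrm{prec} + z' m_p - L)/z'$. A spectrum is a CoAlation
candidate when ≥ 2 distinct losses (default; all three are present in
clean spectra, and requiring two suppresses single spurious matches)
are found above 5% of the base peak (unstated in the source; exposed in
the configuration).

Disulphide-ringed forms suppress b/y ions for cleavage sites inside the
ring by default — a single backbone cleavage between paired cysteines
leaves the halves connected — with `ring_open = TRUE` to emit
ring-opened ions.

Site localization scores each candidate by the intensity-weighted count
of matched *site-determining* ions (those whose m/z differs between
candidates). The score is transparent counting, not a probabilistic
localization model, mirroring how such assignments are made by manual
inspection; equal top scores set an explicit tie flag rather than
forcing a winner.

# Kinetics

Inactivation time courses are fitted to
$A(t) = A_0 e^{-k_\mathrm{obs} t}$ by nonlinear least squares on the
linear scale — log-linear regression is offered as an option but not
the default, because log-transforming amplifies noise at low
activities. The apparent second-order constant is the origin-forced
slope of $k_\mathrm{obs}$ on concentration (buffer-only controls show
no spontaneous inactivation; an intercept is optional). Half-times are
reported under two conventions: $\ln 2 / k_\mathrm{obs}$ from the
model, and direct interpolation of the 50% crossing. Published
half-times read from inactivation curves (e.g. 1.07 min at 1 mM
CoA-disulphide) are steeper than $\ln 2/(k_2 C)$ with the published
$k_2$ (≈ 3.9 min); the two are not reconciled in the source — possibly
biphasic decay — so the package reports both and does not force
agreement.

Michaelis–Menten fitting is ordinary nonlinear least squares on
$v = V_\mathrm{max} S/(K_m + S)$. The turnover number uses the *native
tetramer* mass by default (4 × 35 363 g/mol):
$k_\mathrm{cat} = V_\mathrm{max} \cdot 10^{-3} M_\mathrm{native}/60$
s⁻¹, since only that convention converts the published specific
activities into the published turnover numbers (152 U/mg → ≈ 358 s⁻¹);
a per-subunit mode is available via `native_molar_mass`.

# Titration and thiols

The pH-activity titration is fitted to the single-site sigmoid
$R = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom})/(1 +
10^{\mathrm{pH} - pK_a})$, a rearranged Henderson–Hasselbalch relation
with the Hill coefficient fixed at 1 (a single ionizing thiol). Whether
the top plateau was fixed during the original fitting is unstated; we
fix it at 100% by default — activity is expressed relative to the
untreated maximum, so the top plateau is 100 by construction — and
`top = NULL` frees it. Thiol counting is Beer–Lambert arithmetic on the
DTNB chromophore (ε₄₁₂ = 14 150 M⁻¹cm⁻¹, path 1 cm by default — path
length is unstated in the source; concentrations are per subunit).

# Synthetic data: the stated world

The generators produce every input the pipeline consumes, at the
conditions the analyses assume:

* **Spectra** — all theoretical b/y ions (remnant variants included)
  at uniform or random intensity, optional precursor-minus-loss peaks,
  Gaussian m/z jitter, and uniform noise peaks over the m/z 50–2000
  acquisition window. No isotope envelopes, line shapes or
  chromatography.
* **Time courses** — $100\,e^{-k_2 C t}$ on a 0–20 min grid at the
  published concentration series (250–1000 µM for the CoA disulphide,
  2.5–10 mM for glutathione disulphide), multiplicative Gaussian noise
  truncated at zero. 3% relative noise is used as the stated
  measurement-noise level in recovery tests.
* **Titrations** — 12 pH points spanning 4–9 with additive noise in
  percentage points (3 points in noisy tests).
* **Initial rates** — 8 substrate points spanning 0.1–10 mM around the
  published $K_m$.

All generators are pure functions of their seed. A green closed-loop
test establishes that the estimators are consistent under the stated
noise model — not that real instrument data (isotope interference,
baseline drift, biological replicate scatter) would behave as cleanly.
In particular, the replicate spread of the recovered $k_2$ under 3%
measurement noise (≈ 1%) is tighter than the published between-
experiment errors (≈ 8–9%), which include biological variability the
generator does not model; the tests assert unbiasedness and that the
simulated spread does not exceed the published one.

# Numerical choices

* `nls` fits use `scaleOffset = 1` so that zero-residual (noiseless)
  problems converge cleanly, with log-linear or heuristic start values.
* Greedy annotation matches each theoretical ion to the nearest unused
  observed peak within tolerance; each observed peak is used at most
  once.
* Matching ties (one observation, several forms) are all reported,
  ranked by absolute error.
* Degenerate inputs fail loudly: empty proteins, non-standard residues
  (named with their position), non-positive charges, non-decreasing
  time courses (k_obs = 0 with a warning), titrations without a
  transition, and both-zero intact-mass intensities are all rejected
  with specific messages.

# The identification fixture

The full protein sequence of the study organism's GAPDH is not printed
in the source and is not bundled; instead a clearly-labelled
**synthetic carrier protein** (`synthetic_gapdh_protein()`) embeds the
two published cysteine-containing Lys-C peptides at their native
coordinates (138–159 and 269–295), with cysteine- and lysine-free
filler elsewhere. The bundled fixture combines its digest, the
published precursor observation table and a synthetic CoAlated
spectrum; `run_identify()` on it reproduces the published assignment
table's structure, flags the CoAlated spectrum by its neutral losses
and localizes the site. This validates the machinery, not the in vivo
biology: which peptides are CoAlated in stressed cells is an
experimental finding outside desk scale.

# Known limitations

* No FDR estimation, decoy search, retention-time modelling or
  probabilistic localization scores.
* No deisotoping or precursor deconvolution; spectra are assumed
  centroided.
* Intact-mass analysis takes centroided peak lists; no raw-spectrum
  peak picking, adduct deconvolution or multi-site occupancy fitting.
* Kinetic models are single-exponential / single-site; no mechanistic
  multi-step oxidation ODEs or global fits across conditions.
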