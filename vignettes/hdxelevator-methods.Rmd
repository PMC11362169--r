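---
title: "Methods: differential HDX-MS and conformational geometry of elevator transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential HDX-MS and conformational geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxelevator)
```

# Scope

`hdxelevator` analyses the conformational dynamics of elevator-type membrane
transporters from three directions: (i) peptide-level differential
hydrogen-deuterium exchange mass spectrometry (HDX-MS) with a hybrid
two-stage significance test and projection onto residues; (ii) rigid-body
geometry of transporter conformations (backbone dihedral hinges, Kabsch
superposition, screw-axis decomposition, helix-axis angles, binding-site
displacement, buried interface area); and (iii) quantification of the
supporting biochemical assays (homologous-competition radioligand binding,
cysteine-alkylation labelling efficiency, differential scanning
fluorimetry). A synthetic-data module generates every input class with known
ground truth, so the whole pipeline is testable without instrument data.

# The two-stage significance test

For each peptide ("precursor") measured in two conditions A and B over a set
of labelled exposures (0 s never enters, it is the undeuterated reference),
the uptake difference at exposure $t$ is
$\Delta D_t = \bar{D}_{B,t} - \bar{D}_{A,t}$ in Da.

**Stage 1 (per-exposure gate).** The SEM of the difference at each exposure
is pooled across conditions; the default pooling is quadrature,
$\mathrm{SEM}_t = \sqrt{\mathrm{SEM}_{A,t}^2 + \mathrm{SEM}_{B,t}^2}$,
which is the statistically standard variance addition for a difference of
independent means. These are averaged over the labelled exposures into
$\overline{\mathrm{SEM}}$, and the first test value is
$T_1 = \overline{\mathrm{SEM}} \cdot t_{1-\alpha_1/2,\,n_\mathrm{rep}-1}$
with $\alpha_1 = 0.05$ (95% CI) and $n_\mathrm{rep}-1 = 3$ degrees of
freedom at the standard quadruplicate design. An exposure is significant
when $|\Delta D_t| \ge T_1$ — ties count as significant. The peptide passes
stage 1 when significant exposures form a *strict majority* (3 of 4 at four
labelled exposures; the strict-majority rule generalises the published
"3 out of 4" to other designs).

**Stage 2 (summed-difference gate).** The summed difference
$\Sigma = \sum_t \Delta D_t$ is compared against
$T_2 = n_\mathrm{exp}\,\overline{\mathrm{SEM}} \cdot
t_{1-\alpha_2/2,\,n_\mathrm{exp}-1}$ with $\alpha_2 = 0.01$ (99% CI).
A peptide is reported significant only when both stages pass. No further
multiple-testing correction is applied by default — the two compounding
gates are deliberately conservative, and a null simulation with 1000+
peptides shows an empirical false-positive fraction far below 0.05 (see the
acceptance checks).

Two wrinkles in the published description are genuinely ambiguous and both
readings are implemented:

* **SEM pooling.** The verbatim sentence ("dividing the SEM across the
  quadruplicates in every timepoint and condition through the total number
  of time points") sums per-exposure, per-condition SEMs and divides by the
  number of exposures. This `pooling = "literal"` mode is available;
  `"quadrature"` is the default, and every output labels the mode used.
  Neither is presented as canonical.
* **Stage-2 degrees of freedom.** Whether the 0 s point counts toward "the
  number of time points" is unstated; the default is
  $n_\mathrm{labelled}-1$ (df = 3 at the standard design), overridable via
  `df2`.

```{r}
two_stage_test(rbind(
  data.frame(protein = "p", start = 1, end = 10, sequence = "AAAAAAAAAA",
             max_uptake = 9, state = "A", exposure = c(30, 360, 900, 2700),
             n = 4, mean_uptake = 0, sd = 0.2, sem = 0.1),
  data.frame(protein = "p", start = 1, end = 10, sequence = "AAAAAAAAAA",
             max_uptake = 9, state = "B", exposure = c(30, 360, 900, 2700),
             n = 4, mean_uptake = 1, sd = 0.2, sem = 0.1)))$peptides[,
  c("test_value_1", "test_value_2", "significant")]
```

# From centroids to residues

Uptake is the centroid mass at exposure $t$ minus the undeuterated
reference centroid, taken as the mean of the peptide's exposure-0 replicate
centroids within the same state. Relative uptake divides by the peptide's
maximum uptake, `length - prolines - 1` (prolines carry no amide hydrogen;
the N-terminal amide back-exchanges too fast to retain label). No
back-exchange correction is applied at any stage, matching common practice
for relative comparisons: both states suffer identical losses, which cancel
in differences.

Peptide filtering keeps peptides with identification score strictly above 6
and identification in at least 3 of 4 replicates of the non-deuterated
runs; the replicate rule is applied to the identification runs rather than
per exposure (a strict `per_exposure` mode exists). Every exclusion is
recorded in an audit log.

The residue-level map assigns each residue the aggregate (mean by default)
of the per-peptide mean uptake difference over covering peptides, excluding
each peptide's first residue and prolines. Residues without coverage are
flagged `NA` — "no data" is never rendered as zero. Following the published
practice of using only peptides that pass both stages, the pipeline default
(`significant_only = TRUE`) aggregates over stage-passing peptides only and
reports an exact 0 ("no change") for covered residues without a significant
peptide; `significant_only = FALSE` gives the raw aggregate of all covering
peptides.

# Structural geometry

* **Dihedrals** use the standard four-atom signed torsion (atan2 form) on
  backbone N/CA/C atoms, reported in degrees on $(-180, 180]$. Residues
  with missing backbone atoms (including chain termini) are flagged
  undefined, never zero-filled. Differences are wrapped absolute values in
  $[0, 180]$, symmetric in argument order.
* **Superposition** is the Kabsch least-squares fit over atoms paired by
  (chain, residue number, atom name) — no sequence alignment is performed,
  so mutant/wild-type pairs must share numbering and cross-protein
  comparisons need a user-supplied correspondence. The SVD solution is
  reflection-corrected, so the returned rotation always has det +1.
  Calpha-only pairing is the default (domain comparisons here are
  rigid-body questions); backbone or all-atom pairing is available via the
  `atoms` argument.
* **Screw decomposition** extracts the unique rotation axis (eigenvector of
  the rotation for eigenvalue 1), the angle from the trace, the pitch as
  the translation component along the axis, and a point on the axis from
  the in-plane fixed-point equation, solved with the rank-completing
  $aa^\top$ trick. Rotations below `angle_tol` (default $10^{-7}$ degrees)
  are reported as pure translations with an undefined axis rather than a
  numerically garbage one.
* **Helix axes** are the dominant right-singular vector of centred Calpha
  coordinates (at least 5 required), sign-fixed N→C. Poorly rod-like
  selections trigger a warning rather than silent acceptance. Angles are
  reported both as line-line angles in $[0, 90]$ and signed (direction
  aware) in $[0, 180]$.
* **Site displacement** superposes conformation B onto A over a static
  selection (typically the scaffold domain), then reports total movement of
  the site's Calpha centroid and its component along a reference normal.
  `normal = "auto"` uses the dimer two-fold axis (screw axis of the
  chain-2 → chain-1 fit) as a membrane-normal proxy, and refuses monomers.
  Both the total and the along-normal component are reported because a
  printed "elevation" figure can denote either.
* **Buried surface area** is Shrake-Rupley sphere sampling: each atom's
  accessible sphere (Bondi vdW radius + 1.4 Å probe) carries a 960-point
  Fibonacci lattice, and buried area is SASA(side alone) − SASA(side in
  complex), computed per side. Hydrogens are ignored (crystal structures
  lack them); unknown elements fall back to 1.70 Å with a warning. The
  result is symmetric under swapping the side labels.

The packaged UraA selections (`uraa_domain_selections()`) are an explicit
**reconstruction**: the residue ranges behind the published domain fits are
not printed anywhere, so the shipped scaffold (TM5-7 + TM12-14) and
transport (TM1-4 + TM8-11) ranges are approximate and must be edited
against the user's own topology assignment before quantitative comparison
with deposited structures.

# Assay models

* **Homologous competition** (scintillation counts vs unlabelled
  competitor): $\mathrm{CPM} = B_\mathrm{max}\,[hot] / ([hot] + [cold] +
  K_d) + \mathrm{bg}$, fitted to all replicate points jointly by bounded
  Levenberg-Marquardt with auto-initialisation (bg = min, $B_\mathrm{max}$
  = range, $K_d$ = hot concentration). The background term is fitted by
  default (matching the printed model); `fit_background = FALSE` supports
  pre-subtracted counts. Flat signals are flagged non-identifiable instead
  of returning silent defaults. The hot-ligand symbol is treated
  generically — any radioisotope label obeys the same mass-action form.
* **Labelling efficiency**: the sample's labelled-band fraction over the
  denatured control's labelled-band fraction, × 100; invariant to uniform
  lane rescaling; a zero control fraction is an error, not an Inf.
* **Melting temperature**: maximum of the first derivative of the
  fluorescence trace. The trace is smoothed with a Savitzky-Golay filter
  (window 9, order 2), differentiated by central differences, and the
  interior maximum refined by quadratic interpolation. At the usual
  0.5 °C sampling of a 25-90 °C ramp, a 9-point window spans 4 °C — well
  inside a protein transition — and on matched-noise synthetic curves
  yields ~0.1 °C precision with < 0.002 °C bias, whereas a 5-point window
  leaves ~0.2 °C scatter; hence the wider default. Maxima on the ramp ends
  or peaks that do not stand out from the baseline derivative (3 × MAD
  prominence rule) are reported as "no transition detected".

# What the synthetic data emulates — and what it does not

The EX2 generator draws per-residue deuteration
$D_i(t) = (1 - \beta)(1 - e^{-k_i t / 10^{P_i}})$ with intrinsic rate
$k_i$, log10 protection factor $P_i \ge 0$ and global back-exchange
$\beta$; peptide uptake sums residues `start+1 .. end` excluding prolines;
Gaussian noise is applied at the peptide-centroid level (matching how
centroid mass is actually measured), and undeuterated centroids come from
average residue masses. Defaults mirror the study design: exposures
0/30/360/900/2700 s, four technical replicates, 0.1 Da centroid noise,
25% back-exchange, baseline protection uniform on $[0.5, 3]$ log units,
intrinsic rate 1 s⁻¹ (a single-rate lookup; fully sequence-dependent
intrinsic-rate tables are deliberately out of scope), peptide maps of mean
length 10 advancing ~3 residues. The two-state scenario places the affected
residues (default 20% at +1 log unit) in contiguous blocks, the way real
protection changes follow structural elements.

Not emulated: isotope envelopes or any m/z-domain effect, EX1 bimodality,
chromatographic artifacts, peptide-level identification failures correlated
with exposure. Passing tests therefore demonstrate the statistical
machinery and its operating characteristics under the stated noise model —
not robustness to spectral pathologies.

Problem sizes used by the validation suites, chosen to make the measured
fractions stable: the null (type-I) simulation uses a 1500-residue protein
with a dense map (≥ 1000 peptides); the power/concordance simulation uses a
430-residue protein — the size of the transporter that motivated the
package — giving roughly 38 affected peptides, where measured sensitivity
(0.86-0.92) and residue-map Spearman concordance with truth (0.82-0.86)
are reproducible across seeds. The toy hinge structures are ideal
poly-alanine helices built from standard internal coordinates; their
construction is exactly deterministic, which is what makes 10⁻⁶-degree
round-trip assertions meaningful.

```{r}
ds <- simulate_two_state_dataset(n_res = 120, frac_affected = 0.2, seed = 7)
res <- run_hdx_pipeline(ds$table, "A", "B", protein_length = 120)
res$audit[c("peptides_tested", "peptides_significant", "residues_covered")]
```

# Known limitations

* Atom pairing by identical numbering precludes automatic cross-protein
  comparisons; supply a correspondence table by renumbering one structure.
* The SASA sampler is pure R; for complexes beyond ~10⁴ heavy atoms expect
  runtimes of minutes at the default 960 points per atom.
* Residue maps inherit peptide-level resolution: block edges smear by about
  one peptide length, and residues whose exchange saturates before the
  first labelled exposure are invisible to the statistics regardless of
  their true protection change — a physical, not statistical, limit.
* The literal-average SEM pooling reproduces the published sentence; it
  systematically differs from quadrature by a factor approaching
  $\sqrt{2}$ at equal per-condition SEMs, and verdicts near the threshold
  can differ between modes.
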