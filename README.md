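# hdxelevator

Tools for dissecting the conformational dynamics of elevator-type membrane
transporters — proteins whose mobile "transport" domain slides against a
static "scaffold" domain to carry substrate across the membrane, with
short, partly helical interdomain linkers acting as hinges.

The package serves structural biologists and membrane-protein biochemists
who combine three kinds of evidence:

1. **Differential HDX-MS.** Peptide-level deuterium-uptake tables
   (DynamX-style state data) are parsed, filtered (identification score
   > 6, identified in ≥ 3 of 4 reference replicates), converted from
   centroid masses to uptake, and tested for condition differences with a
   hybrid **two-stage significance test**: stage 1 requires a strict
   majority of labelled exposures with
   |ΔD| ≥ avgSEM · t(0.975, n_rep − 1); stage 2 requires
   |ΣΔD| ≥ n_exp · avgSEM · t(0.995, n_exp − 1). Significant peptides are
   projected onto residues, with uncovered residues explicitly flagged
   "no data" (never zero).
2. **Conformational geometry.** Backbone φ/ψ dihedral differences
   (wrapped to [0, 180]°), Kabsch superposition of domains with
   reflection-corrected rotations, screw-axis decomposition of the
   mobile-domain motion (axis, angle, pitch, axis point), helix-axis
   angles, binding-site displacement along a membrane normal (or the
   dimer two-fold axis), Shrake–Rupley buried interface areas and 4 Å
   contact maps — the quantities used to describe wide inward-open /
   occluded transitions and nanobody epitopes.
3. **Assay quantification.** Homologous-competition binding
   (CPM = Bmax·[hot]/([hot]+[cold]+K_D) + background, bounded
   Levenberg–Marquardt), cysteine-alkylation labelling efficiency (band
   ratios vs a denatured control), and DSF melting temperatures (maximum
   of the smoothed first derivative).

A first-class **synthetic-data module** generates every input with known
ground truth — per-residue EX2 exchange kinetics with state-dependent
protection factors, redundant peptide maps, two-conformation toy hinge
structures built from ideal internal coordinates, and noisy binding/melt
curves — so the entire pipeline is validated end to end without any
instrument data or downloads.

## Worked example

```r
library(hdxelevator)

# a 430-residue protein, 20% of residues gain 1 log unit of protection
ds  <- simulate_two_state_dataset(n_res = 430, frac_affected = 0.2,
                                  delta_logpf = 1, seed = 1)
res <- run_hdx_pipeline(ds$table, "A", "B", protein_length = 430)
res$differential
#> <hdx_differential> B - A: 146 peptides, 29 significant (quadrature pooling)

head(subset(res$differential$peptides, significant,
            c(start, end, sum_delta, test_value_2, n_sig_exposures)), 3)
#>   start end sum_delta test_value_2 n_sig_exposures
#> 1    14  21    -1.610        1.495               3
#> 2    17  25    -4.240        1.559               4
#> 3    20  30    -7.854        1.440               4
```

146 peptides survive filtering; 29 show significant protection in state B
(negative summed uptake differences, in Da, each exceeding its
peptide-specific stage-2 threshold). `res$residue_map` carries the
per-residue projection used for structure painting, and `res$audit`
records counts at every stage.

Geometry round trip on a synthetic hinge:

```r
th  <- make_toy_hinge_structures(12, hinge_angle = 25,
                                 hinge_axis = c(0, 0, 1))
superpose(th$a, th$b, selection = "A:13-24")$transform
#> <rigid_transform> rotation 25.00 deg about (0.000, 0.000, 1.000), pitch 0.000 A
```

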