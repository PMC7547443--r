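# mcphd

Ligand-based 3D molecular similarity by the **maximum common property**
approach, with the evaluation statistics used in virtual-screening studies.

Classical maximum-common-substructure (MCS) similarity asks how much
*topology* two molecules share. This package instead asks how much
*physicochemical property, at geometrically consistent positions*, they
share — a reading of similarity much closer to bioisosterism, where
structurally different groups elicit similar biology because they carry
similar electronic character. It is aimed at cheminformaticians and
medicinal chemists doing ligand-based screening on small 3D datasets
(e.g. antimalarial ester series), and at anyone wanting a transparent,
fully scriptable R implementation of the method.

## The method

1. **Per-atom index.** Every heavy atom gets an electrotopographic state
   index

   `Sstate3D_i = I_i + ΔI_i`,  with
   `I_i = ((2/N)² δᵛ + 1) / δ`  and  `ΔI_i = Σ_{j≠i} (I_i − I_j) / r_ij²`,

   where `N` is the principal quantum number, `δᵛ = Zᵛ − h` the
   valence-electron count of the hydrogen-suppressed atom, `δ` its heavy
   degree, and `r_ij` the 3D Euclidean distance in Å. This is the
   Kier–Hall intrinsic state with a through-space (topographic) rather
   than through-graph perturbation; pairwise contributions are
   antisymmetric, so `Σ ΔI_i = 0`.

2. **Graph reduction.** The molecule is reduced to *descriptor centers*
   (DCs): fused ring systems `Rn`, branching clusters `C3`/`C4`,
   heteroatom groups `X`, and terminal groups `M3`/`M2`/`M`. Each DC
   carries the sum of its members' `Sstate3D` and a center of mass; DCs
   are connected by their Euclidean center-of-mass distances.

3. **Matching.** DC pairs whose property similarity (continuous Tanimoto
   `ab/(a²+b²−ab)`) exceeds a threshold `u` (default 0.95) are candidate
   correspondences; a pair is kept alongside an anchor pair when the two
   intramolecular DC–DC distances agree by Canberra distance
   `|d₁−d₂|/(d₁+d₂) ≤ 0.15`. The largest mutually consistent one-to-one
   correspondence wins, and the matched DCs plus the shortest bond paths
   connecting them form the common fragments `f₁`, `f₂`.

4. **Score.** With `a`, `b` the heavy-atom counts of the molecules and
   `c = min(|f₁|, |f₂|)`:

   `Tc_MCPhd = c / (a + b − c)` ∈ [0, 1].

The evaluation layer adds `TcIC50` (the same continuous Tanimoto applied
to two IC50 potencies, a pseudo-ground-truth of activity similarity),
threshold screening tables over active/inactive pair categories, Pearson
correlations, and Mann–Whitney U tests (min convention, midranks,
asymptotic two-sided p).

## Worked example

Deterministic synthetic structures stand in for real input (any V2000
SDF works via `read_sdf()`):

```r
library(mcphd)

a <- make_molecule(fixture_spec("two_dc_linker", 2, id = "biring_a"))
b <- make_molecule(fixture_spec("two_dc_linker", 3, id = "biring_b"))

tidy(reduce_graph(a))
#>   molecule_id label kind  n_members members     total_sstate3d    cx    cy    cz
#> 1 biring_a    R6_1  R6            6 1,2,3,4,5,6           8.75   0       0     0
#> 2 biring_a    R6_2  R6            6 9,10,11,12…           8.75   7.7     0     0

mcphd_similarity(a, b)
#> <mcphd_sim> biring_a vs biring_b: Tc = 0.9333 (c = 14, a = 14, b = 15, 2 DC pairs)
```

Both hexagonal-ring DCs match (property similarity ≈ 1, consistent
geometry), the fragments close over the linker carbons, and
`Tc = 14/(14+15−14) = 0.93`: the molecules share their whole skeleton up
to one linker atom. All-against-all:

```r
mcphd_matrix(list(a, b,
                  make_molecule(fixture_spec("ring", 6, id = "cyclohexane")),
                  make_molecule(fixture_spec("branch", 5, id = "neopentane"))))
#>             biring_a biring_b cyclohexane neopentane
#> biring_a        1.00     0.93        0.43       0.36
#> biring_b        0.93     1.00        0.40       0.33
#> cyclohexane     0.43     0.40        1.00       0.83
#> neopentane      0.36     0.33        0.83       1.00
```

Cyclohexane matches one ring of the bi-ring molecule (`6/14 = 0.43`);
neopentane's `C4` cluster carries a summed index close to a ring's, so
the two five/six-atom molecules score `5/6 = 0.83` — property matching,
not substructure matching.

The packaged published reference tables drive the statistics layer:

```r
sim <- reference_tables()$similarity
b7j <- dplyr::filter(sim, reference == "7j")
pearson_r(b7j$mcphd, b7j$tcic50)
#> [1] 0.4256845   # prints as 0.43
```

A thin command-line front end over these functions ships in
`inst/cli/mcphd.R` (subcommands `estate`, `reduce`, `sim`, `matrix`,
`screen`, `compare`, `fixtures`, `pipeline`).

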