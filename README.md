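# coformr

Virtual coformer screening for pharmaceutical cocrystal design.

Cocrystals — stoichiometric crystalline solids of a drug (API) and a
benign partner molecule (coformer) held together by non-covalent
interactions — are a route to better dissolution and solubility for poorly
soluble drugs. The hard part is choosing the coformer: experimental
screening of hundreds of GRAS-listed candidates is slow and wasteful.
`coformr` implements a quality-by-design computational funnel that narrows
a coformer library to a short, ranked candidate list for experimental
follow-up. It is aimed at formulation and solid-state scientists doing
early cocrystal screening, and at method developers who want the individual
stages as testable building blocks.

## The method

**Stage 1 — molecular complementarity.** Molecules that cocrystallise tend
to match in polarity and shape. For each API conformation *i* (a seeded
ETKDG/MMFF ensemble, default 9 conformers) and each coformer *c*, five
descriptor deltas are computed:

```
Δd = | d(API_i) − d(c) | ,   d ∈ { dipole μ, FPV, M/L, S/L, S }
```

where μ = |Σ qᵢrᵢ| (Gasteiger charges, Debye), FPV is the fraction of the
van der Waals volume contributed by polar atoms (N, O, S), and S ≤ M ≤ L
are the edges of the minimum rectangular box enclosing the vdW volume. A
conformation is passed when every delta is within its cutoff (defaults:
Δμ ≤ 5.94 D, ΔFPV < 0.294; the geometric cutoffs are study-specific and
config-mandatory). Coformers passing > 50 % of conformations advance, and
an **optimal deviancy** (mean fractional use of the tolerances, in %;
lower = more complementary) ranks them.

**Stage 2 — hydrogen-bond propensity.** A logistic model

```
π = exp(α + Σ_k χ_k β_k) / (1 + exp(α + Σ_k χ_k β_k))
```

over donor–acceptor pair descriptors χ (competition, steric densities,
functional-group categories, aromaticity) scores every possible pairing in
the two-component system. Hydrogen bonds in training clusters are detected
geometrically: D–A distance ≤ vdW(D) + vdW(A) + 0.1 Å and a D–H···A angle
> 120°, with bifurcated donors counted once per acceptor. The
**multi-component score** = max hetero π − max homo π; positive values
favour heterosynthons (cocrystal-forming), negative values flag
homosynthon-preferring pairs.

The final report sorts by pass count, then multi-component score, then
polarity closeness ahead of geometric closeness.

## Worked example

```r
library(coformr)
ext <- function(f) system.file("extdata", f, package = "coformr")

# train a propensity model on synthetic observations with known structure
obs <- generate_observations(2000, alpha = -1,
  betas = c(competition = 1.5, acceptor_cat_aromatic_N = 0.8), seed = 7)
write_observations(obs, "obs.csv", header = "synthetic training set, seed 7")

res <- screen_coformers(list(
  api_path     = ext("pf4_like.smi"),      # synthetic flexible API stand-in
  library_path = ext("coformers.smi"),     # the 10 named GRAS coformers
  cutoff_file  = ext("cutoffs.yaml"),      # published polarity cutoffs +
                                           # illustrative geometric cutoffs
  n_conformers = 9, seed = 42, hbp = "obs.csv"))

dplyr::select(res$ranking, rank, coformer, pass_count,
              optimal_deviancy, multicomponent_score)
```

```
    rank coformer     pass_count optimal_deviancy multicomponent_score
   <int> <chr>             <int>            <dbl>                <dbl>
 1     1 dl_mandelic…          9             50.7             0.0119
 2     2 l_tyrosine            9             30.2             0.00579
 3     3 biotin                9             37.6            -0.000698
 4     4 hesperitin            9             31.2            -0.0396
 5     5 ethylparaben          9             34.7            -0.0523
 6     6 genistein             5             37.5            -0.0401
 7     7 pamoic_acid           1             54.7            NA
 8    NA thiabendazo…          0             NA              NA
 9    NA nicotinamide          0             NA              NA
10    NA l_tryptophan          0             NA              NA
```

Reading the output: `pass_count` is how many of the 9 API conformations
each coformer was complementary to; `optimal_deviancy` is how much of the
pass/fail tolerance the passed conformations used (lower = closer match);
`multicomponent_score` is the heterosynthon-vs-homosynthon margin under the
fitted propensity model (only the advancing coformers are scored; the model
here is trained on synthetic data, so these values illustrate the
machinery, not a literal prediction for these molecules). Coformers that
passed no conformation are "not rankable" (`rank = NA`). With
`output_dir` set, every stage is written as a CSV audit trail whose headers
carry the tool version, a config hash and the seed; identical config + seed
give byte-identical reports.

A thin command-line wrapper ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","coformr",package="coformr"))')" \
    fixture --query max_mcs        # -> 0.51
```

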