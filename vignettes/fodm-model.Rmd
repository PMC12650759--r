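---
title: "The hydrophobicity-distribution model behind fodm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hydrophobicity-distribution model behind fodm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model

A folded globular protein in water tends to organize hydrophobicity like a
micelle: apolar residues buried centrally, polar residues exposed. `fodm`
measures how far a structural unit departs from that ideal, and in which
direction.

Every residue is reduced to one *effective atom*, the arithmetic mean of
its heavy-atom positions (hydrogens are rarely present in X-ray models and
are excluded by construction). Three unit-sum distributions are evaluated
at the effective atoms:

* **T** — the unit is centred, rotated onto the principal axes of its
  point cloud, and enclosed in a 3D Gaussian whose per-axis spread is set
  by the three-sigma rule, $\sigma_a = \max_i |a_i| / 3$, so the whole unit
  sits within three standard deviations. $T_i$ is the product of the three
  axis-wise Gaussian densities at residue $i$, normalized to sum to 1.
* **O** — observed hydrophobicity, collected pairwise with Levitt's
  distance weight $w(\rho) = 1 - \tfrac12(7\rho^2 - 9\rho^4 + 5\rho^6 -
  \rho^8)$, $\rho = r_{ij}/c$, which is 1 at contact and falls smoothly to
  0 at the cutoff $c$. Residue $i$ accumulates $(H_i + H_j)\,w(r_{ij})$
  over all partners within $c$; the sums are normalized. $H$ is the
  residue's intrinsic hydrophobicity after min-max rescaling of the chosen
  scale to $[0, 1]$ (rescaling guarantees the sums are nonnegative, which
  a raw signed scale would not).
* **R** — the uniform distribution $1/N$, the no-core reference.

Distributions are compared with the Kullback–Leibler divergence in base 2,
with the usual $0 \log 0 = 0$ convention. The headline statistic is the
relative distance

$$\mathrm{RD} = \frac{D_{KL}(O|T)}{D_{KL}(O|T) + D_{KL}(O|R)} \in [0, 1],$$

read against the 0.5 midpoint: below it, O is closer to the centric-core
ideal than to featurelessness.

Environments other than bulk water (a membrane, a binding partner, a
chaperone cavity) push the target away from T toward its complement. The
modified target is

$$M(K) = \mathrm{normalize}\!\left(T + K \cdot
  \mathrm{normalize}(T_{\max} - T)\right),$$

and $K$ is fitted by exhaustive search for the grid value minimizing
$D_{KL}(O|M(K))$. At $K = 0$, $M = T$; as $K \to \infty$, $M$ approaches
the normalized complement — the membrane-like profile with hydrophobicity
at the surface. A note on this definition: normalizing only the
$K(T_{\max}-T)$ term and then renormalizing that term alone would cancel
$K$ entirely, so the modification magnitude must scale the *normalized
complement inside the sum*, which is what the formula above does; this is
the only reading under which $K$ parameterizes anything.

### Unit mode and fragment mode

A *unit* (complex, chain, domain, sheet treated on its own) gets its own
envelope and its own O restricted to the unit's residues. A *fragment* of
a unit (a chain inside a complex, a sheet inside a domain) never gets a new
envelope: the unit's T and O are restricted to the fragment's positions and
renormalized, R is rebuilt as $1/|\text{fragment}|$, and RD and K are
recomputed with $T_{\max}$ taken within the fragment. The fragment numbers
therefore quantify the fragment's *contribution to the unit's
organization*, not its stand-alone quality — the two modes genuinely
disagree for asymmetric assemblies, which is the point of reporting both.

```{r modes}
s <- make_structure(120, "two_blob_complex", seed = 23)
cx <- analyze_unit(s, label = "complex")
glance(cx)
glance(analyze_fragment(cx, "chains=A"))     # chain as part of the complex
glance(analyze_unit(s, "chains=A"))          # same chain on its own
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 9 Å | range of the pairwise interaction weight; the conventional value for this interaction function |
| hydrophobicity scale | Kyte–Doolittle | any scale works after min-max rescaling; Fauchère–Pliska and the Eisenberg consensus are bundled, and two-column text files are accepted |
| `k_grid` | 0–10, step 0.1 | exhaustive K search grid; one-decimal resolution matches how K is conventionally reported, and ties resolve to the smaller K |
| `include_self` | `FALSE` | whether residue $i$'s own $2H_i$ term enters $O_i$; O is defined here as *inter*-residue interaction, but the switch is exposed |
| `target_abs_r`, `max_fraction` | 0.7, 0.2 | outlier elimination: stop once the correlation magnitude reaches the target with its initial sign, or once 20 % of residues are removed |

The published serpin analyses that motivate the packaged study
configuration do not name their hydrophobicity scale, so the scale is a
declared parameter everywhere and exact reproduction of published RD/K
values is not guaranteed under any particular bundled scale.

## B-factor correlations and outlier elimination

Per-residue mean B-factors act as a mobility proxy. In a core-ordered unit
the T profile anticorrelates with mobility (buried = immobile). Because
$M(K)$ is an affine function of T with slope $1 - K/(N T_{\max} - 1)$, the
correlation of M with any vector equals that of T exactly whenever the
slope is positive — the package asserts this identity rather than merely
expecting it.

"Outstanding points" in the T-versus-B relation are removed stepwise: fit
an ordinary least-squares line, drop the single largest absolute residual,
recompute the correlation, repeat. Largest-OLS-residual is a deliberate
operationalization — it is simple, deterministic, and reproduces the
qualitative behaviour expected of the procedure; alternatives (leverage,
studentized residuals) are out of scope. RD is then recomputed on the
retained residues by fragment-style renormalization, without re-fitting the
envelope: the question is how the remaining residues sit inside the *same*
field.

## The synthetic generator

`make_structure()` emulates the statistical organization the analysis
assumes, not protein geometry. Coordinates are an anisotropic Gaussian
cloud with a 3.5 Å minimum spacing (rejection sampling), so no two
effective atoms collapse into degenerate contact. Residue identities are
assigned by *rank matching*: drawn names are sorted by scale value and
paired with residues sorted by distance from the centre (inverted for the
hydrophobic-surface regime). Rank matching guarantees the intended ordering
without assuming anything quantitative about the scale. B-factors follow
`b0 + b1 · radius + noise`, the buried-to-surface mobility gradient.

What passing tests on these fixtures shows: the statistics separate the
organizations they claim to separate, the estimators recover planted
parameters, and every pipeline stage composes. What it does not show:
behaviour on real backbone geometry, real packing densities, sequence
correlations, or crystallographic artefacts — the generator has none of
those. Conclusions about particular proteins require particular structures.

```{r generator}
glance(analyze_unit(make_structure(100, "micellar", seed = 1)))$rd   # < 0.5
glance(analyze_unit(make_structure(100, "inverted", seed = 1)))$rd   # > 0.5
```

## Numerical choices and degenerate inputs

* Divergences are in bits (base-2 logarithm) throughout.
* The K grid is built as integers over 10 (`(0:100)/10`), so grid values
  are the exact binary doubles closest to their decimals and recovered K
  values compare cleanly against reported one-decimal numbers.
* Principal-axis rotation is canonicalized by sorting axes by decreasing
  variance and flipping signs so the most extreme coordinate on each axis
  is positive. T is invariant to this choice (the Gaussian is even and the
  sigma follows its axis); canonicalization only makes the reported
  envelope deterministic.
* $q$-side zeros in $D_{KL}(p|q)$ raise an error instead of being clamped:
  T, R and M are strictly positive by construction, so a zero there is a
  malformed user input, not a numerical edge.
* Exactly uniform T makes the modification direction undefined
  ($T_{\max} - T \equiv 0$); `modified_profile()` returns T flagged
  degenerate, and `fit_k()` returns the smallest grid K.
* Collinear or coincident effective atoms give a zero axis sigma and a
  declared error; an O with no pair inside the cutoff ("no observed
  hydrophobic interactions") likewise errors rather than returning NaN.
* Units are analyzed at a minimum of 3 residues; outlier elimination
  refuses to go below 4 remaining points.

## Problem sizes in the test suite

The suite works at sizes where the Monte-Carlo properties are sharp but
cheap: 100-residue structures and 100 seeds for the organization-detection
rates, 50-residue profiles for K recovery (the full 101-point grid times 50
random profiles, exactly; 100 noisy seeds at 1 %), 200 random structures up
to 200 residues for the brute-force equivalence of the pairwise
aggregation, and a five-form synthetic study of 80-residue chains. These
are the package's reference conditions; all are regenerated from seeds at
test time.

## Known limitations

* PDB input only (first model; blank/'A' altlocs preferred, then
  occupancy); no mmCIF, no symmetry expansion, no structure repair.
* Domain boundaries are user-supplied configuration — the package does not
  compute domain decompositions, and the bundled serpin configuration
  leaves them unset for that reason.
* The published serpin RD/K values depend on an unnamed hydrophobicity
  scale and envelope convention; with the bundled defaults the packaged
  study reproduces the analysis *procedure*, and agreement with published
  numbers should be checked, not assumed, once the deposited structures
  are supplied.
* B-factors are used as given (mean over heavy atoms); no normalization
  across structures or resolution correction is attempted, so correlation
  magnitudes are comparable within a structure, not between crystals.
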