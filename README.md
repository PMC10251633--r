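# coopbind

Equilibrium thermodynamics of cooperative, multivalent RNA-protein
binding.

Most RNA-binding domains (RBDs) bind short, degenerate motifs weakly --
dissociation constants of micromolar to hundreds of micromolar -- yet
multi-domain RNA-binding proteins (RBPs) reach nanomolar effective
affinities in the cell. `coopbind` is for structural biologists and
biochemists who want to put numbers on that gap: given the measured
affinities of the isolated domains and the geometry of protein and RNA,
it computes the **avidity** (effective association constant) of the
full-length protein with no free parameters, and shows how strongly
binding responds to the *density* of motifs on the RNA.

## The model in brief

An idealized protein with $n$ domains binds an RNA with $n$ cognate
sites; domain $i$ binds only site $i$, one protein per RNA, linkers are
inert worm-like chains. The $2^n$ binding configurations are bitstrings
(`"101"` = sites 1 and 3 bound) with statistical weights

$$ w(S) = K_{a,i_1} \prod_{k=2}^{m} c_{i_{k-1} i_k} K_{a,i_k},
   \qquad
   K_\mathrm{av} = \sum_{S \ne \emptyset} w(S), $$

where the effective local concentration of a tethered domain follows
Gaussian worm-like-chain statistics,

$$ c_{ij} = (2\pi\sigma^2)^{-3/2} e^{-d_{ij}^2 / 2\sigma^2}
   \times 1.66054\ \mathrm{M\,nm^3},
   \qquad \sigma^2 = \tfrac{2}{3}\, l_p\, l_{ij}, $$

with $l_{ij}$ the tether contour length (0.55 nm/nt of RNA, 0.38 nm/aa
of peptide; $l_p$ = 2.7 nm for ssRNA, 0.304 nm for disordered peptide)
and $d_{ij}$ the 3D distance between rigidly linked domains; flexible
peptide linkers add their variances (convolved Gaussians). On an RNA
with $N \ge n$ equally spaced sites,
$K_\mathrm{av}(N,n) \approx K_\mathrm{av}(N{-}n{+}1)$, and the density
response is quantified by fitting the Hill function $1/(1+(D_0/D)^h)$.
An exact Gillespie simulation of the full reaction network provides an
independent stochastic cross-check, and a validation pipeline predicts
full-length Kds of multi-domain proteins from per-domain parameters.

## Worked example

A two-domain protein (Kd 10 uM and 50 uM, domains rigidly linked 2.5 nm
apart) binding two sites separated by a 12-nt linker:

```r
library(coopbind)
rbp <- rbp_model(kd = c(10e-6, 50e-6), geometry = rigid_geometry(2.5, n = 2))
rna <- rna_target(12)
avidity_exact(rbp, rna, warn = FALSE)
#> <avidity_result> K_av = 4.079e+06 1/M (Kd = 2.452e-07 M), method = exact
#>   configuration weights (1/M):
#>     10 : 1e+05
#>     01 : 2e+04
#>     11 : 3.959e+06
```

Two micromolar domains cooperate to a 245 nM protein: the doubly bound
configuration (weight `11`) carries ~97% of the avidity, because the
12-nt tether holds the second domain at an effective concentration of a
few millimolar -- far above its 50-uM Kd. At 0.1 uM RNA this protein is
29% bound (`occupancy(4.079e6, 1e-7)` = 0.290), while either single
domain alone would be essentially unbound.

The density response under the package's reference scan (per-domain Kd
50 uM, 200-nt RNA, 0.1 uM RNA, d = 2 nm):

```r
hill_cooperativity(2, kd = 50e-6, rna_length_nt = 200,
                   rna_conc = 1e-7, d_nm = 2)
#> <hill_fit> h = 2.35, D0 = 0.07202 sites/nt, rss = 0.0011
```

A two-domain protein already responds to motif density with a Hill
coefficient of 2.35; with four domains the response is switch-like
(h > 5), and doubling the site count from 8 to 16 on a 200-nt RNA raises
the avidity more than 40-fold.

A command-line front end (`inst/cli/coopbind`) exposes the same
operations as subcommands (`compute`, `density-scan`, `hill-fit`,
`simulate`, `validate`, `synth`), writing TSV with `#`-header lines that
echo version, seed and constants.

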