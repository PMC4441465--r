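---
title: "Molecular Distance Maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular Distance Maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrmap)
```

This vignette explains the model behind `cgrmap`, the choices made where
the design was genuinely open, and what the synthetic benchmarks do and do
not demonstrate.

## The model

`cgrmap` measures relatedness between DNA sequences through their k-mer
occurrence patterns, with no alignment anywhere in the pipeline. Three
stages are composed:

**CGR encoding.** The Chaos Game Representation places the four bases at
the corners of the unit square — A bottom-left, then C, G, T clockwise —
and reads the sequence left to right, each letter moving the current point
(initially the centre) halfway toward its corner. The construction has a
key arithmetic property: after reading at least k letters, the current
point lies strictly inside the dyadic cell of side 2^-k addressed bit by
bit by the last k letters (the most recent letter contributes the *most*
significant bit, i.e. selects the coarsest quadrant). A 2^k × 2^k raster
therefore puts every k-mer in bijection with one pixel, and we blacken the
pixel of every k-mer that occurs as a sliding window of the sequence.

Two details follow from taking that pixel semantics seriously:

* Encoding enumerates the k-mer windows directly rather than rasterizing
  the trajectory. The first k − 1 trajectory points still carry the
  start-point transient (a residual 2^-i term from the centre), so plotting
  them would blacken pixels of words that never occur. The trajectory is
  kept as an independent *oracle*: the test suite checks, over hundreds of
  random sequences, that the black-pixel set equals the quantized
  trajectory points from index k onward.
* Floor quantization needs no tie-breaking: from the recurrence, the final
  point of a k-mer sits strictly inside its cell, never on a boundary.

Pixel intensities are 8-bit: black = 0 (occurring), white = 255 (absent).
A count-weighted grayscale mode (log-scaled window counts) exists as an
extension but is not used by the distance pipeline defaults.

**DSSIM distance.** Images are compared with the structural similarity
index computed per window position from Gaussian-weighted local moments,
then averaged; the distance is DSSIM = 1 − SSIM, ranging over [0, 2] with
value 0 for identical images, ≈1 for an all-black versus an all-white
image (only the luminance stabilizer keeps it a hair under 1:
1 − C1/(L² + C1) ≈ 0.9999), and approaching 2 for anti-correlated images
of equal luminance. Because a DSSIM below 1 is dominated by shared
structure, typical distances between CGRs of unrelated genomes land in the
0.8–1.0 band, while closely related genomes fall well below.

**Classical MDS.** The distance matrix is embedded by Torgerson scaling:
double-centre the squared distances, eigendecompose, and scale the top q
eigenvectors by the square roots of their eigenvalues. Fit quality is
Kruskal's Stress-1 with disparities f(Δ) = aΔ + b fitted by unconstrained
least squares of the realized map distances on the input distances; values
at or below 0.20 are conventionally considered acceptable, though the
benchmark is a guideline, not a law. Finally each axis is affinely mapped
onto [−1, 1] for display.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 9 | CGR resolution exponent; image side 2^k pixels (512). k = 9 compares occurrences of all oligomers up to length 9; sequences of a few kb upward give well-populated rasters. Smaller k (5–7) is appropriate for short sequences or fast exploration. |
| `window_side` | 11 px | SSIM window; the canonical reference value. |
| `window_sigma` | 1.5 px | Gaussian weighting of the window, canonical. |
| `K1`, `K2` | 0.01, 0.03 | stabilizers; `C1 = (K1 L)²`, `C2 = (K2 L)²`, `C3 = C2/2` folded into the two-term SSIM form. |
| `L` | 255 | dynamic range; images enter SSIM as 8-bit intensities, never as 0/1 booleans. |
| `q` | 2 | embedding dimension; 3 is supported and typically lowers Stress-1. |

## Numerical choices

* **Border handling is "valid":** only SSIM windows fully inside the image
  contribute. Padded-convolution variants shift values at the 3rd–4th
  decimal, which is why the convention is recorded in every run manifest.
* **No downsampling pre-stage.** Later SSIM variants pre-filter by viewing
  distance; here pixel identity *is* k-mer identity, and merging pixels
  would merge k-mers.
* **Negative eigenvalues** (DSSIM matrices are generally non-Euclidean)
  are clamped to zero for coordinate construction — the standard Torgerson
  treatment — but reported in full for diagnostics. Eigenvalues within
  rounding error of zero (relative tolerance 1e-12) count as zero, and
  deficient axes are zero-filled with a warning.
* **Sign convention:** each eigenvector is flipped so its
  largest-magnitude entry is positive. MDS output is only defined up to
  rotation/reflection; pinning the sign makes runs reproducible across
  platforms.
* **Stress-1 before scaling.** The per-axis [−1, 1] scaling is
  anisotropic and changes inter-point distances, so Stress-1 is always
  evaluated on the unscaled configuration.
* **Degenerate inputs:** an all-equal distance matrix makes the disparity
  regression undefined (slope set to 0 with a warning); coincident points
  give Stress-1 = 0 by convention; a degenerate map axis scales to all
  zeros.
* **Summary statistics:** the "average DSSIM distance" of a run is the
  mean over unordered pairs, diagonal excluded.
* **Ranking ties** are broken lexicographically by sequence id so ranked
  outputs are deterministic.

## Sequence handling

FASTA input is cleaned deterministically: lowercase is uppercased, `U`
maps to `T` so RNA-alphabet files are accepted, and every other symbol
(N, IUPAC ambiguity codes, gaps) is *deleted* and counted per record.
Deletion, rather than random substitution, keeps the pixel semantics exact
and the pipeline deterministic; the skipped count is retained so the
provenance of removed symbols is never lost. Reverse complements are not
merged: the CGR of a sequence and of its reverse complement are distinct
signatures, and conflating them is a modelling decision the user can make
upstream if wanted.

## The trinucleotide-preserving shuffle

Comparing a genome against randomizations that keep its length and its
exact overlapping 3-mer counts asks how much signature information lives
beyond trinucleotide frequencies. Exact preservation was chosen over
Markov resampling (which preserves counts only in expectation) because the
question is about sequences with *the same* trinucleotide frequencies; a
Markov mode remains available behind a flag for comparison.

The sampler works on the order-2 de Bruijn multigraph — nodes are
dinucleotides, each trinucleotide occurrence is one edge — where every
preserving randomization is exactly an Eulerian path starting from the
input's first dinucleotide (which also guarantees such a path exists). A
uniform path is drawn by the arborescence construction: sample the
spanning arborescence of last-exit edges toward the terminal node with
Wilson's loop-erased random walk (probability proportional to the product
of edge multiplicities), permute each node's remaining exits uniformly,
and walk. This is exact and rejection-free; a fully homogeneous input such
as `AAAA` has a single Eulerian arrangement and is returned unchanged.

## What the synthetic generator emulates — and what it does not

`simulate_markov_family()` draws one order-2 (by default) Markov
transition table per family as a convex perturbation of a shared base
table, `T_f = (1 − divergence) · base + divergence · R_f`, with flat
Dirichlet draws for `base` and each `R_f`. This mimics the salient feature
the pipeline exploits — family-specific oligomer usage against a shared
background — at a chosen strength. The benchmark configuration used in the
tests is 4 families × 5 sequences of 20,000 bases at divergence 0.5 with
k = 9, on which the 2-D map recovers family membership by nearest
neighbour at ≥ 90% accuracy and within-family distances fall below
between-family ones. Elsewhere the suite scales down (sequences of
0.8–5 kb, k = 4–7, images of 16–64 px) to keep each property check tight
and fast.

Real genomes are *not* order-2 Markov: they carry repeats, skews,
compositional domains, coding constraints and shared ancestry, and real
datasets add length heterogeneity (CGR darkness grows with sequence
length) and database artifacts. Passing the synthetic benchmark therefore
shows the pipeline is implemented correctly and separates
oligomer-composition signal at realistic strengths; it does not by itself
validate taxonomic conclusions on any particular real dataset.

## Known limitations

* DSSIM compresses large and small image differences into numerically
  close distances near 1, which suits closely related collections better
  than very broad taxonomic sweeps.
* A 2-D map always distorts some distances (that is what Stress-1
  quantifies); conclusions about individual points should be checked
  against the distance matrix itself, e.g. with `rank_distances()`.
* Sequence length influences CGR darkness and hence distances; comparing
  wildly different lengths is possible but the length effect is not
  modelled out.
* Pairwise DSSIM cost grows quadratically in the number of sequences;
  per-image moment caching makes each pair a single cross-convolution, but
  very large collections still call for patience or parallel evaluation
  (pairs are independent by contract).
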