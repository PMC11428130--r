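---
title: "Scaffold-conditioned diffusion generation of transition-metal complex ligands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmcdiff methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmcdiff)
```

## The problem

Mononuclear transition-metal complexes (TMCs) — one d-block centre
coordinated by several ligands — underpin catalysis, photophysics and
molecular magnetism. Designing a new complex usually means keeping part
of an existing, experimentally validated scaffold (the metal and some
ligands) and replacing the rest. `tmcdiff` implements this as *scaffold
inpainting with a denoising diffusion model*: the metal plus any subset
of retained ligands form a frozen context, and the model generates the
missing ligands as 3D point clouds, conditioned on how many ligands to
build and what denticity each should have.

The package contains the whole pipeline at desk scale: the domain model
for complexes and ligand partitioning, the masking combinatorics used to
expand a training corpus, the variance-preserving diffusion process, an
equivariant geometric-vector-perceptron (GVP) noise predictor trained by
explicit backpropagation, the standard generation metrics, deterministic
synthetic fixture corpora, and a spin-crossover (SCO) screening workflow
with pluggable energy backends.

## Representation

A complex with $N$ heavy atoms is a point cloud
$x = [r, h_a, h_L, h_c]$: coordinates $r \in \mathbb{R}^{N\times 3}$
(Angstrom, metal at the origin), one-hot atom types $h_a$ over the
15-element heavy vocabulary {C, N, O, F, P, S, Cl, Br, Cr, Mn, Fe, Co,
Ni, Cu, Zn}, one-hot ligand codes $h_L$, and one-hot denticity classes
$h_c \in \{1,\dots,6\}$. Hydrogens are stripped on ingest; re-addition
is an external backend hook, not package chemistry. The feature blocks
are scaled by $(0.1, 0.25, 1)$ for $(r, h_a, h_{Lc})$ at featurization —
the coarse geometry and atom types are down-weighted so the
ligand/denticity conditioning, which steers generation, is relatively
emphasized. Diffusion itself operates on unscaled coordinates and raw
one-hot types; the scaling is purely an input transformation of the
network.

Two representation choices were genuinely open and are resolved as
follows:

* **Granularity of $h_c$.** The conditioning one-hot could distinguish
  donor atoms from body atoms inside a ligand; we condition at ligand
  granularity (every atom of a ligand carries that ligand's denticity
  class), which is sufficient to steer the assigned denticity and keeps
  decoding unambiguous. The metal row carries the total coordination
  number as its class.
* **Ligand-code layout.** Codes are indexed 1..`l_max` with the first
  code reserved for the metal; `l_max = 12` leaves room for
  higher-coordinate transfer inputs. Exceeding it raises a dedicated
  context-overflow error instead of silently truncating.

## Bond perception, ligands and denticity

Curated crystal-structure corpora carry connectivity; ad-hoc XYZ input
does not, so bonds are perceived with the covalent-radius rule
$d_{ij} \le r_i + r_j + 0.4$ Å. Ligands are the connected components of
the bond graph with the metal vertex deleted, ordered deterministically
by smallest atom index. A ligand's denticity is the number of its atoms
within the metal-donor cutoff, the same rule with a looser 0.6 Å
tolerance to capture long dative contacts. Both tolerances are config
keys. For Mn, Fe and Co the *low-spin* Cordero radii are used: with the
high-spin radii plus the 0.6 Å tolerance, chelate backbone atoms and
pyridine ortho-carbons (which sit near 2.9-3.0 Å from the metal) would
be miscounted as donors.

## Masking combinatorics

Training-set expansion masks every non-empty subset of a complex's $l$
ligands, giving $2^l - 1$ samples — 63 for a hexa-monodentate complex, 3
for a complex of two tridentate ligands. Ligands are treated as
distinguishable by position even when chemically identical (the worked
count of 63 for six identical monodentate ligands fixes this
convention). For generation, the freed coordination number
$\mathrm{CN}_g = 6 - \mathrm{CN}_c$ is partitioned into ligand
denticities $\mathrm{LD}_g$: all integer partitions in canonical
non-increasing form ("21" means one bidentate plus one monodentate).
There are $p(6) = 11$ assignments for total generation and
$\sum_{n=1}^{5} p(n) = 18$ for partial generation; a two-tridentate
reference admits $3 + 3 + 11 = 17$ generation variations. These counts
are exact and are re-derived in the test suite against brute-force
subset and partition oracles.

## Diffusion process

The forward process is variance preserving: at step $t$ of $T$ the
masked block is $x_t = \alpha_t x_0 + \sigma_t\,\epsilon$ with
$\alpha_t^2 + \sigma_t^2 = 1$, $\epsilon \sim \mathcal{N}(0, I)$ applied
to the masked atoms' coordinates and atom-type channels only; the
context and $h_{Lc}$ are never noised. The default schedule is the
power-2 polynomial $\alpha_t \propto 1 - (t/T)^2$ (clipped into
$(10^{-4}, 1-10^{-4})$), with a cosine alternative; $T = 1000$ by
default. Both shape and $T$ are config keys: this layer of the method is
conventional and the package makes the convention explicit rather than
baking it in.

Sampling initialises placeholder atoms from a standard normal and runs
ancestral reverse steps using the exact posterior
$q(x_{t-1}\mid x_t, \hat{x}_0)$ with
$\hat{x}_0 = (x_t - \sigma_t \hat\epsilon)/\alpha_t$. Numerical
safeguards: $\hat{x}_0$ coordinates are clipped *by row norm* to 15 Å
from the metal (a per-axis box would break rotational equivariance);
atom-type channels are clipped to $[-2, 3]$; non-finite values abort
with the step index. Final atom types are decoded by argmax with ties
resolved toward the lowest channel index.

Two deterministic-sampling contracts are worth spelling out:

* **Seed fan-out.** One integer seed spawns one substream per generated
  ligand, and each substream pre-draws its full noise trajectory. Adding
  a ligand to a request therefore does not perturb the draws consumed by
  earlier ligands.
* **Rotation covariance.** Noise vectors are drawn in a
  context-canonical SO(3) frame (Gram-Schmidt on the first two
  non-collinear context atoms; right-handed completion). Rotating the
  context rotates the frame, so the same seed yields an exactly rotated
  trajectory: `sample_ligands(R(context), seed)` equals
  `R(sample_ligands(context, seed))` to floating precision. Collinear
  contexts fall back to an axis-aligned frame with a warning.

## The GVP denoiser

The noise predictor $\phi$ keeps, per atom, a rotation-invariant scalar
channel vector $s$ and rotation-equivariant 3D vector channels $V$.
Initial scalars are the scaled $h_a$, the ligand and denticity codes,
the masked flag, a sinusoidal embedding of $t/T$ plus the raw fraction;
no coordinate-derived scalar enters here, which keeps the initial
scalars bit-identical under rotation. The single initial vector channel
is the scaled displacement from the metal. Messages flow on the complete
graph — every atom except the atom itself is a neighbour, so the metal
and all context atoms inform every update — combining sender and
receiver scalars, the scaled inter-atomic distance, the sender's vector
channels and the unit displacement. Aggregation is by mean (stable from
6-atom toys to 200-atom complexes), followed by residual scalar/vector
updates through GVP blocks: vector channels are mixed linearly, their
norms join the scalar pathway, and a sigmoid gate computed from the
scalars rescales the output vectors. Because scalars only ever see
norms, scalars are exactly O(3)-invariant and vectors O(3)-equivariant,
including reflections; the readout takes $\hat\epsilon_r$ from the final
vector channels and $\hat\epsilon_h$ from the final scalars of masked
atoms.

The network, its reverse-mode gradients and the Adam optimiser are
implemented in vectorised base R. Hand-written backpropagation is the
one genuinely error-prone part of that choice, so a finite-difference
gradient check on a 5-atom toy (agreement to 1e-4 relative, every
parameter block) is part of the test suite. Default width follows the
modest desk-scale setting of 5 layers, 128 scalar and 16 vector
channels; all are config keys, and the tests deliberately use smaller
instances.

Training minimises the mean squared error between $\hat\epsilon$ and the
injected $\epsilon$ over masked coordinate and atom-type channels, with
$t$ drawn uniformly per example and one Adam update per sample.

## Synthetic fixtures and what they do (not) show

No structural database ships with the package; the fixture module builds
toy complexes from ~13 hand-constructed template ligands (denticities 1,
2, 3, 4 and 6, N/O/C/S/Cl donors) placed on ideal coordination vectors
of six geometries (octahedral and the CN 3-5 shapes), with donors near
2.0 Å, a 0.05 Å Gaussian jitter (config key) and deterministic seeding.
Template internals are tuned so that perception reproduces the intended
connectivity with margin: chelate backbones sit on arcs at 3.0 Å radius
(outside every training metal's donor cutoff), and diatomic ligands use
deliberately long 1.28 Å bonds so a jittered bond never crosses the
0.7-covalent-sum clash floor. Corpus draws make polydentate ligands
systematically larger than monodentate ones (sizes below 10 for
denticity < 3, 10-30 otherwise), mirroring the size-denticity
relationship the method assumes.

These fixtures exercise every code path — partitioning, masking
expansion, training, sampling, metrics, screening — but they are
structurally sane, not chemically realistic: passing tests demonstrate
the machinery (equivariance, determinism, conservation laws, exact
combinatorics), not that a trained model produces synthesizable
chemistry. Conclusions about real corpora require real training data.

The *parameter-recovery task* is the strongest end-to-end statement the
fixtures support: complexes whose masked ligand is always a single
nitrogen at exactly 2.0 Å trans to a sulfur marker, randomly rotated per
sample. The only learnable fact is that placement. The package's
acceptance experiment trains a 3-layer, 48/8-channel denoiser with
$T = 300$ on 500 samples for 30 epochs (a few minutes on one CPU) and
requires at least 80% of 50 generated atoms to land within 0.3 Å of the
2.0 Å target distance, while an untrained model must fail the same
bound. In runs during development the trained model placed 100% within
the bound (median error near 0.05 Å) and the untrained model 0%.

## Generation metrics

The five standard ratios are reported with exact integer counts so
concatenated batches average correctly: ligand validity (an explicit
valence screen on the perceived hydrogen-free bond graph — every atom a
curated non-metal and no degree above its maximum plausible valence),
connectivity among valid ligands (single bonded component), complex
validity (all generated ligands valid and connected; realised total
denticity equal to the target CN; no inter-atomic distance below 0.7
times the covalent sum; every generated ligand coordinating — four
individually toggleable rules reconstructing the intent of the external
checker used in the original protocol), novelty (canonical-SMILES
absence from the training set) and uniqueness (distinct strings over all
generated). Canonicalisation goes through OpenBabel; strings are
hydrogen-free skeleton identifiers with unit bond orders, and
stereochemistry is deliberately not compared. Structural analyses
include mean metal-donor bond lengths (for HS/LS comparisons) and
Kabsch-superposed conformer RMSD.

## SCO screening workflow

The screening pipeline chains: variation enumeration (all maskings of
each reference crossed with all denticity partitions, generated-ligand
sizes drawn between the denticity and a 10-heavy-atom cap), ligand
generation, complex validation, hydrogen/charge hooks (pass-through
defaults; real protonation and charge assignment belong to external
tooling), paired high-spin/low-spin optimisation through an energy
backend, ground-state classification ($E_{HS} < E_{LS} \Rightarrow$ HS;
ties classify LS with a warning), and the spin-gap filter
$|E_{HS} - E_{LS}| \le 10$ kcal/mol, boundary inclusive. The absolute
value is used because both HS-ground and LS-ground near-degenerate
complexes are crossover candidates. Energies are handled in kcal/mol;
backends declaring hartree are converted at ingestion (627.509474
kcal/mol per hartree). Multiplicities are per-item inputs (defaults
follow the Fe(II) convention, 2S+1 of 5 and 1). Every stage logs
retained/dropped counts and conserves items; backend failures flag the
item and continue. The shipped backend is a mock — deterministic
synthetic energies or a JSON lookup — because the pipeline, not the
quantum chemistry, is the package's subject.

## Numerical choices, in one place

* Bond tolerance 0.4 Å; metal-donor tolerance 0.6 Å; low-spin radii for
  Mn/Fe/Co.
* Schedule: polynomial power-2, $T = 1000$ default, coefficients clipped
  to $(10^{-4}, 1 - 10^{-4})$.
* $\hat{x}_0$ clipping: 15 Å by row norm (coordinates), $[-2,3]$ per
  channel (types). Argmax ties: lowest channel index.
* Degenerate geometry: inter-atom distances floored at $10^{-8}$ in unit
  vectors; vector norms inside GVP blocks carry an $10^{-8}$ additive
  epsilon under the square root.
* Generation-size warning: a polydentate assignment with fewer than
  twice its denticity in heavy atoms warns that the denticity may not be
  realised (a bidentate with 3 atoms tends to come out monodentate);
  sizes below the denticity itself are impossible and warn for the same
  reason.
* Problem sizes in the shipped tests: 500-sample/30-epoch recovery
  training with $T = 300$ and a 3-layer 48/8 network; 100-rotation
  equivariance sweeps on ~20-atom embeddings; 10^4-draw moment checks.
  These were chosen as the smallest sizes at which each property is
  convincingly demonstrated.

## Known limitations

* The valence screen is a degree heuristic, not an aromaticity- or
  charge-aware sanitizer; it is deliberately permissive for dative-rich
  systems.
* Bond orders are not inferred; SMILES identifiers treat every bond as
  single, which is the right equivalence for hydrogen-free skeleton
  comparison but not for depiction.
* The mock energy backend contains no physics; reported HS/LS statistics
  on fixtures characterise the pipeline, never chemistry.
* Full-scale corpus training (hundreds of thousands of masked samples,
  wide networks) is outside the intended envelope of the base-R
  implementation; the architecture is the contribution here, and the
  implementation is sized for the experiments it ships.
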