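---
title: "Dual-mode molecular data storage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode molecular data storage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualstore)
```

`dualstore` models a storage system with two co-located media on one
substrate: a nanodot bitmap ("concise" data — small, frequently read, read
by AFM) and immobilized DNA strands ("detailed" data — dense, archival, read
by in-situ amplification and sequencing). This vignette explains the models
behind each module, the parameters that matter, and the design decisions
that were genuinely open, so that a reader can judge what the package's
passing tests do and do not demonstrate.

## The detailed-data codec

### Strand anatomy

Each strand carries one 25-byte block of the payload. The core is

```
[ mod primer A | M_A(index ‖ payload) | M_B(inner RS parity) | mod primer B | seed ]
       4 nt          4 + 100 nt               8 nt                 4 nt       ≥ 4 nt
```

for a 124-nt minimum, and the full strand appends 20-nt PCR primers on both
ends plus an 8-nt outer Reed–Solomon parity region (172 nt minimum). The
2 bits/nt byte–base map is A=00, C=01, G=10, T=11, most significant pair
first, so all region lengths are multiples of 4 nt and every region
boundary is byte-aligned.

### Modulation

Composition constraints (GC content, homopolymer runs) make some payloads
unrepresentable verbatim. *Modulation* maps a sequence onto an alternative
sequence of the same length by adding a 4-nt primer cyclically, position-wise
mod 4 — a Vigenère cipher over the quaternary alphabet. It is exactly
invertible given the primer, and composing two modulations is itself a
modulation (the keystreams add), which the test suite checks as a group
action. The encoder screens an ordered pool of admissible 4-nt primers
(those with GC 0.5 and no long runs; 96 of the 256 words) for the first
(A, B) pair whose assembled core satisfies the constraints, extending the
seed in 4-nt steps up to 16 nt if no pair suffices. First-success search
makes encoding deterministic given the RNG seed; reproducibility was
preferred over optimizing, say, the GC margin.

The constraint thresholds — GC within [0.40, 0.60] and homopolymer runs of
at most 3 nt — are the community-standard synthesis/sequencing limits for
archival DNA storage.

### Error correction

Both protection layers are Reed–Solomon codes over GF(256) (field polynomial
0x11D, generator element 2, first root $\alpha^0$), systematic, with 2
parity bytes (= 8 nt) each:

* the **inner** code protects (index ‖ payload ‖ both modulation-primer
  identifiers), so a decoder can even recover a corrupted modulation primer
  and re-demodulate;
* the **outer** code covers all bytes of the core, whatever the seed length.

Two parity symbols correct one symbol error per codeword. A consequence
worth stating plainly: a codeword with *two* byte errors sits at distance 2
from its own codeword and distance ≥ 1 from some neighbour, so roughly 10%
of double corruptions decode — in this package and in any bounded-distance
RS decoder — to a *neighbouring* codeword rather than an error report. What
the decoder guarantees, and the tests assert, is that a double corruption is
never silently returned as the *original* message, and that its behaviour
agrees exactly with a brute-force syndrome-search decoder.

RS decoding uses Berlekamp–Massey for the error locator, a Chien search for
positions, and a GF(256) linear solve for magnitudes, then re-verifies all
syndromes before accepting a correction.

## The concise-data codec

Text is UTF-8 encoded, preceded by a 32-bit big-endian byte count, and the
bit stream fills the smallest square row-major from the top-left; protruded
sites are 1, flat sites 0. A header was chosen over sentinel padding because
it fails loudly (declared length beyond capacity) instead of decoding
garbage. Concise files append a `PRIMERS|<fwd>|<rev>` trailer line carrying
the paired detailed file's PCR primers — the linkage that makes random
access self-contained — with a backslash-escape for body lines that would
collide with the trailer. The catalog (unit 0) serializes one
`id|name|row|col` record per line; pipe-delimited so a bitmap dump remains
human-readable.

## The AFM channel

### Forward model

Each 1-cell becomes an isotropic Gaussian bump: FWHM 50 nm and height 10 nm
by default (the demonstrated dot geometry), $\sigma = \mathrm{FWHM} /
(2\sqrt{2\ln 2}) \approx 21.2$ nm. Gaussian is the minimal parametric shape
consistent with a dot characterized only by FWHM and height. Dots sit on a
square lattice (pitch 100 nm default, ≥ 2×FWHM keeps neighbours resolvable)
over a tilted background plane plus iid Gaussian height noise (1 nm sd
default, a tenth of the dot height). Pixels default to 5 nm so a dot spans
~10 px. The model deliberately omits tip convolution, drift/creep and
feedback artifacts of real scans; passing round-trip tests therefore show
codec correctness under the stated noise model, not robustness to every
instrumental artifact.

### Read-out

1. **Flattening** removes the least-squares plane `z ~ 1 + x + y` — a
   projection, hence idempotent, and it makes decoding invariant to tilt and
   global offset (tested).
2. **Lattice detection** works on row/column projections of the positive
   part: peaks above a prominence threshold, pitch from the cluster of
   smallest peak gaps (robust to interior dot-free lines, which produce
   doubled gaps), then a least-squares line through peak positions vs
   integer lattice index — half-pixel pitch accuracy on clean input.
   Irregular peak spacing (residual sd > 0.15 pitch) raises a
   "no periodic structure" error, which is how pure-noise images are
   rejected.
3. **Boundary refinement**: an edge row or column whose cells are all 0
   leaves no projection peak. The detector therefore grows the fitted
   lattice outward while an extrapolated line still contains at least one
   dot-like site (window maximum above 0.4 of the robust amplitude).
4. **Thresholding**: per site, the maximum height within a pitch/2 window;
   the robust amplitude is the median of site maxima above the Otsu split,
   and a site is 1 iff its maximum exceeds half that amplitude. An image
   whose amplitude does not clear 5× the noise floor (estimated from
   adjacent-pixel differences, which dots — smooth at this sampling — barely
   affect) decodes to all zeros, so blank fields do not hallucinate dots.
5. **Square disambiguation** (`read_matrix_auto()`): encoded matrices are
   square, but a small payload's header row can be entirely zero and thus
   physically absent. The reader tries each placement of the detected
   sub-grid within the square and keeps the first whose bits actually
   decode. An entirely blank matrix (empty text) is the one case this
   cannot rescue — there is nothing to detect — and is a documented
   limitation of bitmap-encoded empty files.

## The sequencing channel and read decoding

### Channel

Reads per strand are Poisson with mean `coverage` (default 100, the
demonstration depth); each read passes an iid per-base channel with
substitution/insertion/deletion probabilities 3%/2%/3% — long-read
nanopore-like magnitudes — and is reverse-complemented with probability 0.5,
since surface amplification releases the complementary strand. The channel
has no homopolymer-conditional error structure and no quality scores; both
are stated simplifications.

### Why the decoder polishes a consensus

At these rates a 132-nt trimmed read carries ~10.6 errors in expectation and
the probability of an error-free read is ~10⁻⁶: virtually every read is
unique, and two reads of the *same* strand differ by ~21 edits. A sphere
clustering with a small radius therefore cannot group same-strand reads, and
any single read is far beyond what the 2-byte RS layers can repair. The
pipeline consequently:

* filters and trims by semi-global (infix) alignment of both 20-nt primers
  (≤ 4 edits each, found near the respective read ends, interior length
  within ±12 nt of the design window — tolerances chosen to pass ≥ 99% of
  clean-channel reads);
* clusters trimmed reads greedily at a **channel-matched radius of 30**:
  comfortably above the same-strand pair distance (≈ 21 ± 5) and far below
  the cross-strand distance of random payloads (≳ 50). For near-duplicate
  payload blocks this separation would shrink — a limitation for highly
  repetitive files;
* polishes each selected cluster by iterated positional-majority consensus:
  members are banded-aligned to the current template, votes are tallied per
  template position (base/deletion) and per junction (insertion), and the
  majority is applied, for up to 8 rounds or until a fixed point. Insertions
  are emitted at a >1/3 plurality rather than an absolute majority because
  equal-cost alignments leak insertion evidence into neighbouring
  substitution columns; noise pileup at homopolymer junctions stays below
  ~10%, so the two regimes are well separated. Up to 48 members vote, which
  bounds the per-position majority error well below the RS layers' capacity;
* decodes consensus interiors (outer RS → parse → inner RS → demodulate) in
  abundance order. The expected-strand count *n* comes from the library
  manifest. When the top-*n* clusters leave indices missing — a strand's
  reads occasionally split into two clusters, displacing a rare strand —
  decoding simply continues down the cluster list.

`cluster_reads()` itself keeps plain greedy sphere semantics with a default
radius of 3 and is verified against a brute-force oracle; the polishing
and the wide radius are `recover_file()`'s read-channel policy, and both are
exposed as arguments.

The `DecodeReport` error rate is the fraction of expected strands not
recovered; edit-distance-based comparison against known originals is a
separate evaluation (`evaluate_against_originals()`, minimum-cost assignment
via the Hungarian algorithm when indices are unavailable, with unmatched
originals counting their full length).

## Aging, repeated access and analytics

Thermal decay is first order — the standard model for DNA backbone
hydrolysis and the only one under which a half-life is well defined — with
Arrhenius temperature dependence: $k(T) = \exp(\ln A - E_a / RT)$ per year,
each molecule surviving time $t$ with probability $e^{-kt}$. `arrhenius_fit()`
converts survival observations to rates and fits $\ln k$ on $1/T$;
`half_life()` extrapolates $t_{1/2} = \ln 2 / k(T)$. Units are fixed
throughout: years, kelvin, kJ/mol, $R = 8.314$ J mol⁻¹ K⁻¹. Because the raw
accelerated-aging observations behind the demonstrated 97.81 kJ/mol are not
distributed with the package, the shipped tests validate *parameter
recovery*: data simulated through the stochastic aging channel at a known
activation energy (10⁵ molecules, three temperatures spanning 343–373 K,
survivals between ~0.2 and ~0.9) must return it within 3%.

Repeated access contrasts the two retrieval chemistries. In-situ
amplification copies surface-bound templates without consuming them, so
template counts are exactly constant across accesses. Pooled access removes
a Binomial(count, 1%) aliquot per access and re-amplifies with per-strand
efficiencies drawn once from Normal(0.9, 0.05) truncated to [0, 1] over 20
cycles, renormalized to constant total — so relative-abundance dispersion
(CV) grows strictly with access count. The consumed fraction and efficiency
spread are free parameters with these documented defaults; only the
qualitative contrast (flat vs divergent) is asserted.

Densities are closed forms: one bit per dot gives $\rho = d^{-2}$
(4×10⁸ bit/mm² at the demonstrated 50-nm dots; 10¹⁰ at 10 nm), and DNA at
intermolecular spacing $d$ with $L$ bits per molecule gives
$\rho = L\,d^{-2}$ (2.48×10¹² bit/mm² for 248-bit minimal strands at 10 nm;
2.76×10¹³ at the ~3-nm framework-nucleic-acid limit).

## The demonstration library

`build_demo_library()` reproduces the demonstration's shape: six units on a
2×3 grid — unit 0 a catalog, units 1–5 pairing a concise bitmap with a
detailed file — holding 1,595 bytes of binary image data (`seal`) and
4 × 101 = 404 bytes of text (`name`, `motto`, `anthem`, `ethos`), 1,999
bytes in all, which the default layout encodes into 81 strands
(⌈(1999+2)/25⌉). The payload *contents* are seeded pseudo-random bytes and
printable characters: stand-ins at the authentic sizes, since the original
files are not redistributable; random content is also the honest stress case
for cluster separation. Per-unit primer pairs are rejection-sampled to pass
the composition constraints at pairwise edit distance ≥ 8 (cross-talk
guard). `random_access()` runs the entire read path — catalog bitmap through
the AFM channel, unit lookup, concise bitmap for the primers, simulated
sequencing, recovery — using only information recovered from the images, so
the test that its recovered primers drive a byte-exact file recovery
exercises the concise→detailed indirection end to end.

## Problem sizes and numerical choices

The shipped tests run the full 81-strand payload through the default channel
20 independent times (byte-exact recovery each time), read back 100 random
28×28 nanodot arrays with zero bit errors, exhaust all 33×255 single-byte
corruptions of a strand codeword, and verify clustering against an O(U²)
oracle up to 200 unique sequences — sizes chosen to exercise every code path
at full design parameters while keeping the suite in the low minutes.
Deterministic seeds are threaded through every stochastic step (`withr`),
and all randomness flows through R's RNG, including the C++ read-mutation
kernel, so runs are bit-reproducible.

Known limitations, collected: no homopolymer-aware error model; no consensus
about files with near-duplicate blocks at cluster radius 30; no tip
convolution or scan artifacts in the AFM model; bitmap-encoded empty files
cannot survive the physical AFM path; pooled-access efficiency is
sequence-independent by construction.
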