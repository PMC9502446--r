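---
title: "Methods: dual CUG decoding, physicochemical shift censuses and tRNA_CAG features"
author: "cugDecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual CUG decoding and shift censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cugDecode)
```

# The model

In CTG-Ser1 clade yeasts the CUG codon is decoded ambiguously, mostly as
serine and occasionally as leucine, by a single hybrid tRNA with a CAG
anticodon that both SerRS and LeuRS can aminoacylate. `cugDecode` models
the *restricted* consequences of that ambiguity: every CUG in a protein is
decoded consistently, giving exactly two proteome-wide decodings — the
all-serine and the all-leucine proteome — plus the *unrestricted*
combinatorial bound in which every CUG chooses independently.

All coordinates are 0-based half-open internally; every written report is
1-based inclusive. Nucleotide input is normalized to DNA letters (`U -> T`)
on read, with the original form remembered for round-trip writing.

## CUG censusing and translation

A CUG is exactly the codon `CTG` in the annotated reading frame after U/T
normalization. Codons containing `N` translate to `X` and are never counted
as CUG — a conservative censusing rule: an ambiguous base is never promoted
to evidence of ambiguity. A final stop codon is dropped from the protein;
the start codon is not required to be ATG because annotation exports vary.
CDS validation offers three policies (`strict`, `skip`, `coerce`); a
trailing incomplete codon can be trimmed under `coerce`, but an internal
stop always rejects the record, since a frame error upstream of it would
silently corrupt every downstream count.

## Isoform-count hypotheses

Two counts are reported. Unrestricted: $\sum_g 2^{n_g}$, with a CUG-free
gene contributing $2^0 = 1$, so the total is a proteome size directly
comparable to the restricted count. Restricted: one protein per CUG-free
gene and two per CUG-carrying gene. The phrase "two polypeptides per CUG
gene" admits a second, literal reading — two polypeptides per CUG *codon* —
and the package co-reports it as `restrictedLiteral`
($\text{genes}_{n=0} + 2\times\text{CUG codons}$), but the per-gene reading
is the default because it is the one consistent with the published gene
totals it accompanies (6272 genes, 4110 CUG-carrying, 10,382 polypeptides:
$2162 + 2 \times 4110$). Counts use double-precision arithmetic, which is
exact below $2^{53}$ — far beyond both the genome-scale totals involved
(~$10^9$–$10^{13}$) and every brute-force check in the test suite.

# Isoelectric points

The net charge of a protein at a given pH is the Henderson–Hasselbalch
balance

$$Q(\mathrm{pH}) = \sum_{\text{basic}} \frac{1}{1 + 10^{\mathrm{pH} - pK_a}}
                 - \sum_{\text{acidic}} \frac{1}{1 + 10^{pK_a - \mathrm{pH}}},$$

with the two termini counted once and the ionizable side chains (D, E, C,
Y acidic; H, K, R basic) once per residue; `X` contributes nothing. $Q$ is
strictly decreasing in pH (each term is), so the pI — the unique zero of
$Q$ on $[0, 14]$ — is found by bisection to $|\Delta \mathrm{pH}| <
10^{-4}$. Reports round pI to 2 decimals; all comparisons happen at full
precision first, so no protein can change its classification through
rounding.

The bundled default pKa table uses EMBOSS-tradition group pKas for
polypeptides and Lehninger α-carboxyl/α-amino/side-chain pKas for the
free-amino-acid mode. For a residue with a non-ionizable side chain the
free pI is the mean of its two α-pKas; the Lehninger values give
$\mathrm{pI}(\mathrm{Ser}) = (2.21 + 9.15)/2 = 5.68$ and
$\mathrm{pI}(\mathrm{Leu}) = (2.36 + 9.60)/2 = 5.98$, the anchors the rest
of the pI work is calibrated against. Alternative tables load from any TSV
with the same columns.

## Why three pI-shift rules

Neither serine nor leucine has an ionizable side chain, so the
charge-balance pI of a protein is *invariant* under the Ser/Leu decoding
swap: the solver-recomputed shift is identically zero up to bisection
tolerance, for every protein. A flat approximation — subtract the free
Ser/Leu pI difference ($5.98 - 5.68 = 0.3$) once per CUG-encoded residue —
would instead flag *every* CUG-carrying protein as shifted by at least 0.3.
Both behaviours are analytically forced and neither can reproduce a census
in which only a small minority of proteins shift by $\geq 0.1$ pH units.
The package therefore exposes all three rules — `recompute`, `paper_flat`
($-0.3\,n$), and the default `paper_length_weighted` ($-0.3\,n/L$, the
flat shift diluted by protein length, treating the approximation as a
per-residue perturbation) — and co-reports them in every profile table, so
any downstream census states its convention instead of hiding it. No rule
is claimed to reproduce any particular published count.

## Hydropathy

GRAVY hydropathy is computed under three bundled scales — Kyte–Doolittle
and the Eisenberg consensus and normalized-consensus scales — with `X`
excluded from numerator and denominator. The default mode is the GRAVY
*mean* rather than the raw sum: the conventional high-shift thresholds
(0.03 for Kyte–Doolittle, 0.3 for the Eisenberg scales) and the notion of
"slight changes of 0.1" only make sense on a per-residue-normalized score,
where one Ser→Leu substitution in a length-$L$ protein moves the score by
exactly $(h_{\mathrm{Leu}} - h_{\mathrm{Ser}})/L$ — a closed form the test
suite asserts against direct recomputation for every gene of a 500-gene
synthetic proteome under all three scales. Sum mode remains available by
flag. Because Leu is more hydrophobic than Ser in all three scales, every
shift is positive for CUG-carrying proteins; the census still takes
absolute values so that user-supplied scales with the opposite orientation
behave identically.

The shift census counts, per scale, proteins with any variation
($|\Delta| > 0$) and with a high shift ($|\Delta| \geq$ threshold), and
intersects the high-shift identifier sets across scales; the intersection
is reported in input order, and all counts are invariant to input order.
pI binning uses six closed pH ranges (valleys 5.3–5.9, 7–8.9, 10.1–13;
peaks 4.2–5.2, 6–6.9, 9–10.1). A value on the one shared boundary (10.1)
is counted once, in the range covering the lower pH values — the 9–10.1
peak — and custom range lists are rejected if they overlap anywhere other
than a shared endpoint.

# tRNA_CAG identity elements

Three sequence features let both SerRS and LeuRS recognize the hybrid
tRNA: (i) G at canonical position 33, immediately 5' of the CAG anticodon
(most tRNAs carry U there; G distorts the anticodon loop), (ii) GGG and
CCC motifs on the TψC arm, and (iii) a discriminator G at canonical
position 73, 5' of the terminal CCA.

The package deliberately does not implement full Sprinzl alignment-based
numbering; for three rule checks on standard-length (60–120 nt) tRNAs a
sequence-relative frame suffices and is far easier to audit. The anticodon
is located as the occurrence of the triplet closest to the sequence
midpoint (anticodons sit near the center of the cloverleaf); occurrences
within 15 bases of either end are discarded first, and if none survive the
call errors rather than guessing. Position 33 is the base 5' of the
anticodon; the discriminator is the final base, or the base 5' of a
terminal CCA when one is present; the TψC search window runs from 10 bases
past the anticodon to the discriminator. Feature calls are deterministic
and invariant to U/T representation. Raw 0-based indices are reported
alongside the canonical 1-based labels.

A bundled 76-nt template — a *constructed* cloverleaf-like sequence, not a
natural tRNA — carries all three elements; the tRNA simulator mutates it
minimally (pos33 G→U, the middle G of the TψC GGG→A, discriminator G→A) to
realize any requested feature vector, with optional background mutations
confined to the D-arm so diagnostic calls are never touched.

## Alignment and trees

Pairwise identity uses Needleman–Wunsch global alignment with linear gap
scoring (defaults +1/−1/−2) and a fixed traceback tie-break (diagonal,
then vertical, then horizontal), so aligned outputs are deterministic.
Identity is matched columns over *all* alignment columns — gapped columns
count against identity. For an externally supplied MSA the convention
differs in one respect: columns gapped in both members of a pair are
excluded (they carry no information about that pair), while single-gap
columns still count as mismatches. Both conventions are documented rather
than claimed to match any particular published identity figure. Distances
are $d = 1 - \text{identity}$.

Neighbor joining follows Saitou–Nei with the standard Q-criterion; on Q
ties the pair whose lexicographically sorted representative taxon ids
compare smallest is joined, making topologies reproducible. The 3-taxon
base case is solved in closed form
($a_A = (d_{AB} + d_{AC} - d_{BC})/2$, and rotations). Negative branch
lengths are preserved in memory and clamped to zero only at newick
serialization. On additive matrices NJ recovers the generating topology
exactly; the test suite checks this over random 4–8-taxon trees and
cross-checks topologies against an independent NJ implementation
(`ape::nj`), which is never used as the computation path.

# Expression fold changes

Replicate Cq values are averaged on the Cq scale (the standard Livak
workflow; averaging efficiencies on the linear scale would weight
replicates unevenly), then within each growth phase
$\Delta Cq(g,c) = \bar{Cq}(g,c) - \bar{Cq}(\mathrm{ref},c)$,
$\Delta\Delta Cq = \Delta Cq(g,c) - \Delta Cq(g,\mathrm{basal})$ and
$\log_2 FC = -\Delta\Delta Cq$, so one cycle earlier than expected means a
two-fold higher transcript. Two invariants follow and are enforced by the
class validity: the reference gene's row is identically zero and the basal
condition's column is identically zero; a third — invariance to adding a
constant to every Cq of one condition — is a property test. Replicate SDs
are retained for external significance testing, which is out of scope
here. Amplification-efficiency (Pfaffl) correction is not implemented.

# The synthetic-data generator

The generator exists so every stage runs, with known ground truth, without
any downloads. Its defaults emulate the published census shape of the
*D. hansenii* CUG distribution rather than fit it: a 34% CUG-free class, a
geometric carrier tail with mode 1 (success probability 0.34, so roughly a
third of carriers have exactly one CUG), truncated at a hard maximum of 31
CUG per gene; gene lengths uniform over 100–600 codons (a plausible yeast
CDS range bracketing the typical ~450-codon mean); background codons drawn
from the 60 non-CTG sense codons with a 0.36 GC bias matching the
organism's AT-rich genome. Each gene starts with ATG, ends with a uniform
stop, and carries exactly its planted CUG count at uniformly drawn
interior codon positions; the truth object records counts, positions and
the implied isoform totals. Counts drawn from the distribution are capped
by a short gene's available interior slots; explicitly planted counts that
do not fit are an error.

What the generator does *not* emulate: realistic codon usage beyond the GC
bias, amino-acid composition of real proteomes (so absolute pI
distributions of simulated proteins are not biological), phylogenetic
structure among simulated tRNAs, or qPCR efficiency artifacts. Passing
tests therefore demonstrate correctness of the *computations* under
planted truth, not biological calibration of any threshold.

The Cq simulator plants $Cq(g,c,r) = \mathrm{base}(g) - \mathrm{effect}(g,c)
+ \mathcal{N}(0, \sigma)$ with triplicates by default, so the ΔΔCq stage
recovers the planted effects exactly at $\sigma = 0$ and without bias under
noise. All simulators draw every random number from a single explicitly
seeded generator per call (`withr::with_seed`), leaving no hidden global
state: same seed, byte-identical outputs.

# Numerical and design choices

- Bisection tolerance $10^{-4}$ pH; pI reported to 2 decimals; threshold
  comparisons always at full precision.
- Deterministic tie-breaks everywhere randomness is not wanted: alignment
  traceback order, NJ join selection, pI bin boundary assignment.
- TSV outputs declare their float precision in a `#` header comment and
  are byte-identical across reruns; the run manifest records config,
  package version, input checksums and per-stage row counts.
- Test problem sizes are chosen to exercise the mathematics, not the
  genome scale: 200 random peptides for the pI fixed-point property, a
  500-gene proteome for the hydropathy closed form, 100 short pairs
  against the exhaustive alignment oracle, 50 additive matrices for NJ
  topology recovery, 1000 Monte-Carlo Cq tables for ΔΔCq bias
  ($\sigma = 0.2$, $n = 3$; the absolute bias per cell stays below 0.05,
  while any single table's error is expected near 0.2 — unbiasedness, not
  single-shot precision, is the estimator's guarantee).

# Known limitations

- The pI solver is a sequence-only charge balance: no structure-aware pKa
  shifts, no machine-learned corrections; absolute pIs carry the usual
  ±0.5 pH uncertainty of such models even though *shifts* between the two
  decodings are exact within the model.
- Cloverleaf annotation is rule-based and can mis-place the anticodon on
  tRNAs with unusual variable arms; all inspected indices are reported so
  calls can be audited.
- Multiple sequence alignment construction, bootstrap support, codon
  adaptation indices, GO annotation and qPCR efficiency correction are out
  of scope by design.
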