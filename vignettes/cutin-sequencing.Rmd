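---
title: "Reading the acyl-chain sequence of cutin from tandem MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading the acyl-chain sequence of cutin from tandem MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutinseq)
```

## The problem

Cutin, the structural polyester of the plant cuticle, is built from
hydroxylated and epoxidated C16/C18 fatty acids cross-linked by ester bonds.
Because the intact polymer is insoluble and amorphous, its *primary
structure* — which monomer is esterified to which — has to be read
indirectly: a cutinase partially hydrolyzes the polymer into soluble
oligomers (dimers to tetramers), and high-resolution negative-mode LC-MS/MS
of those oligomers reveals their composition and, through ester-cleavage
daughter ions, the order of their monomers. Group-specific derivatization of
the intact polymer (dansyl or benzyl on free hydroxyls, DmPA on free
carboxyls) adds end-group information: a monomer recovered *with* the tag
carried that group free in the polymer, a monomer recovered *without* it had
the group engaged in an ester bond.

`cutinseq` implements this whole inferential chain as testable code: exact
monoisotopic mass arithmetic, a monomer catalog, precursor decomposition
into monomer multisets, fragment prediction, ordering inference, overlap
assembly, label-ratio statistics, and a seeded simulator that generates
polymers, digests and noisy spectra so that every step can be validated
end-to-end without instrument data.

## Mass model

All arithmetic is performed on **neutral elemental formulas**; ions only
arise by applying an adduct (`[M-H]-`, `[M+H]+`, `[M+Li]+`, `[M+2Li-H]+`) to
a neutral species. This matters: adding deprotonated monomer m/z values
double-counts the lost proton, and only neutral-based bookkeeping reproduces
the printed oligomer ions exactly (e.g. the dimer of 16-hydroxypalmitate and
9,10,18-trihydroxystearate at m/z 585.47). Atomic masses are monoisotopic,
frozen in source at eight significant digits; isotope envelopes and multiply
charged species are out of scope because the workflow reads only singly
charged monoisotopic peaks.

A monomer is described positionally — chain length `n`, double bonds `d`,
hydroxyl positions (1-based from the carboxyl carbon, omega = `n`), epoxide
spans, carboxyl positions — and its formula is *derived*, never stored:
acids follow `C_n H_{2n-2d-2e-2(c-1)} O_{2c+h+e}` with `h` hydroxyls, `e`
epoxides and `c` carboxyls. Every catalog entry is checked against this
invariant in the tests, against an independently hand-built formula table.

```{r}
parse_shorthand("9,10,18-trihydroxy-18:0")[, c("id", "formula", "mz")]
```

## Tolerances

* Fragment matching: 10 ppm **or** 0.02 Da (either suffices). Printed Q-TOF
  values deviate from theory by up to ~0.02 Da.
* Precursor composition search (`precursor_tol_da`): 0.1 Da by default.
  Precursor isolation windows are physically far wider than fragment mass
  accuracy, and reported precursor values drift accordingly (one published
  tetramer precursor sits ~0.06 Da from self-consistent theory). Wrong
  compositions admitted by the wider window are down-ranked by their
  fragments, not excluded a priori.
* Chain-cleavage diagnostics: 0.03 Da, because these candidate ions carry
  hydrogen-transfer ambiguity.
* Comparison with printed values uses half-away-from-zero rounding to two
  decimals (`round_mz()`), the convention of instrument software.

## Fragment model

Ester-cleavage MS/MS fragments are modelled as **hydrolysis-form contiguous
sub-oligomers** — full acid and alcohol termini on both sides of every cut —
each with up to two additional neutral water losses (two is the most ever
seen in these spectra; the cap is the `max_water_loss` parameter and never
exceeds the fragment's free-hydroxyl count). This single rule reproduces the
printed trimer daughters (581.44, 563.43, 275.20) and tetramer daughter
(589.45) without modelling ketene-versus-acid chemistry. Internal fragments
(two cleavages) are generated for oligomers of length four and above but are
*excluded from scoring* by default: they require two backbone cleavages,
are weak in practice, and scoring them lets implausible orderings explain
terminal ions through internal mass coincidences.

Chain-cleavage (C–C) diagnostics for locating hydroxyl and epoxy groups are
generated as *candidates*, not assertions: homolytic cleavage of each bond
flanking an oxygen-bearing mid-chain carbon, hydrogen-transfer offsets of
−1/0/+1, an optional water loss, and both epoxide-oxygen assignments when
the cut runs through the epoxide span. Per-carbon hydrogens are counted on a
saturated backbone and double-bond hydrogens are debited from the omega side,
because double-bond positions are not encoded in the descriptors — a stated
approximation for unsaturated monomers. The candidate set covers all five
printed epoxide diagnostics (171.11, 157.12, 155.12, 141.12, 127.12) within
0.03 Da.

## Sequencing: score, ties and what mass cannot tell you

For a spectrum, `sequence_spectrum()`:

1. decomposes the precursor into monomer multisets by exhaustive enumeration
   over the catalog (complete by construction; verified against an
   independent brute force in the tests), with length bounds derived from
   the monomer m/z window 164–331 per unit;
2. enumerates the distinct orderings of each multiset (multinomial, capped
   at length six), discarding orderings whose non-terminal monomers have no
   hydroxyl to host the next ester bond;
3. scores each ordering as the **number of distinct observed peaks explained
   by at least one predicted fragment**. Counting explained observations
   rather than matched predictions prevents isobaric prediction pile-ups on
   a single ion from inflating a candidate. Intensities are recorded but
   unused by default, since the underlying deduction argues only from the
   presence or absence of daughter ions;
4. ranks by score; equal scores share a dense rank and are flagged
   ambiguous, never silently broken. Within a rank, orderings sort by the
   fewest water losses *invoked* (each explained peak attributed to the most
   parsimonious matching prediction), then by composition mass error, then
   by lexicographic symbolic serialization.

One limitation is intrinsic, not numerical: the masses of contiguous
sub-multisets are invariant under full reversal of the sequence, so a
reversal that is itself a valid oligomer always ties the true ordering.
The pair is reported together at rank 1 with `ambiguity = TRUE`; direction
beyond the free-carboxyl convention must come from end-group labeling (or
from a terminal monomer that lacks hydroxyls, which makes the reversal
structurally impossible and is detected). Likewise a mid-chain versus omega
linkage site changes no fragment mass, only free-hydroxyl counts, so ester
regiochemistry is annotated as undetermined.

For trimer candidates the central-monomer argument is made explicit: a
monomer appearing in both matched dimer daughters must occupy the central
position, and the evidence (both dimers, their observed m/z) is attached to
the result.

```{r}
sp <- spectrum(857.65, c(581.44, 563.43, 311.21, 287.22, 293.20, 275.20))
res <- sequence_spectrum(sp)
tidy(res)[1:3, c("rank", "sequence", "score", "water_losses_invoked")]
res$central_evidence$statement
```

Overlap assembly (`assemble_overlaps()`) merges fragment sequences whose
suffix/prefix monomer runs coincide; longer overlaps rank higher, mirroring
the greater confidence of a two-monomer overlap over a single shared
terminal monomer.

## Labeling statistics

Per monomer, abundances of tagged (free) and untagged (esterified)
populations are aggregated over replicates and summarised as
`log2(fr/es)` with the first-order delta-method standard error

```
se = 1/ln(2) * sqrt((se_fr/fr)^2 + (se_es/es)^2)
```

which the tests hold against a 10^5-draw Monte-Carlo standard deviation
(agreement within 15% at coefficients of variation up to 10%; the
first-order approximation degrades at larger CV, a known limitation).
Tag deltas are derived from the reagent chemistry — dansyl +C12H11NO2S,
benzyl +C7H6, DmPA +C10H11NO — and reproduce the printed derivatized ions
within 0.02 Da in positive mode. Benzyl tagging shifts mass identically
wherever the hydroxyl sits, so site localization is annotation, not mass
inference. GC-MS quantification against a heptadecanoic-acid internal
standard (default 10 µg) is single-point linear.

## The simulator and what passing tests mean

The generator is the package's study-condition definition, not a tuning
knob. `build_polymer()` samples monomers by the catalog's `sim_weight`
column, which encodes the qualitative abundance ranking of apple cutin —
six dominant monomers (9,10,18-trihydroxy-18:0/1/2/3, 10,16-dihydroxy-16:0,
18-hydroxy-18:2) carrying most of the weight, reflecting their ~80% share of
the monomer pool; exact proportions are configuration because the underlying
bar values are not published numerically. Terminal bias (default 5×)
up-weights 16-OH-16:0/18-OH-18:2 at the omega end and
16-OH-16:0/18-OH-18:3 at the carboxyl end, the enrichment seen in the
labeling experiments. Digestion cleaves each ester bond independently with
probability `p_cleave` — an explicit assumption, since no fragment-length
distribution for partial cutinase digestion has been measured — and
fragment counts obey the tree law `1 + p·edges`. Spectra perturb
theoretical peaks with Gaussian ppm error (5 ppm default, the Q-TOF class)
and add uniform noise peaks over the 100–1700 scan window; all randomness
flows from one explicit seed.

The headline end-to-end property — ≥90% rank-1 recovery of true orderings
over 200 simulated distinct-monomer trimers at 5 ppm and 5 noise peaks —
is computed on 200 spectra and an exhaustive-decomposition check on 500
random precursors (catalog of 28, lengths ≤4); these sizes keep the full
validation suite in minutes on one core while leaving the Monte-Carlo
standard errors of the reported rates well below the acceptance margins.
What passing does **not** show about real data: the simulator emulates
neither chimeric spectra, in-source fragmentation, isotope envelopes,
intensity structure, nor retention behaviour, and real cutin may contain
monomers outside the catalog; results on instrument data inherit those
caveats.

## Numerical and degenerate-input choices

* Subtraction that would drive an element count negative is an error naming
  the element — impossible neutrals fail fast rather than producing wrong
  masses.
* `decompose_precursor` with an empty result is a diagnosis, not an
  exception; an unparseable MGF block is skipped with its line number.
* Homodimers have exactly one distinct ordering and are reported
  unambiguous.
* Fatty alcohols are catalog entries but never enter oligomers or polymer
  simulation by default (no carboxyl; `include_alcohols`/`sim_weight`
  control them), matching their absence from observed oligomers.
* Branched simulated fragments are linearized along the longest
  carboxyl-to-omega path with a warning; the sequencer itself considers only
  linear candidates.
* Reports embed the full run configuration and an FNV-1a catalog checksum,
  so any ranking can be traced to the exact monomer library that produced
  it.
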