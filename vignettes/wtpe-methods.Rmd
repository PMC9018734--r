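---
title: "Models and methods behind wtpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wtpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtpe)
```

## The editing system being modelled

A prime editor built on nuclease wild-type Cas9 (WT-PE) behaves differently
from the familiar nickase-based editors. The nuclease introduces a blunt
double-strand break (DSB) 3 bp 5' of the PAM, and the slow product release
of SpCas9 leaves time for the pegRNA's primer binding site (PBS) to anneal
to the broken non-target strand (the strand carrying the protospacer
sequence), after which the reverse transcriptase extends that strand's 3'
end using the RT template. The result is a DSB whose PAM-distal end carries
a 3' single-stranded DNA flap encoding whatever the RT template was
designed to write: an intended edit, optionally followed by a homology arm
(HA) copied from genomic sequence.

Pairing two such pegRNAs that target opposite ends of a genomic segment —
with both PAMs pointing *into* the segment — produces two flap-bearing ends
whose flaps can anneal to each other. If the fragment between the cuts is
on one chromosome this heals as a large targeted deletion; if the two cuts
are on different chromosomes, as a translocation. Two design classes
exist:

* **C1**: each flap carries the edit plus an HA identical to the retained
  sequence adjacent to the *partner* cut, supporting a homology-mediated
  join;
* **C2**: each flap carries only the edit, and the two flaps are exact
  reverse complements of each other, annealing over their full length.

The accurate repair product in both cases is
`retained_a + edit + retained_b`, with each HA collapsed to a single copy.
The characteristic failure modes are end joining of the flap without HA
collapse (leaving the HA *duplicated* at the junction), direct fusion of
the break ends with no edit written, and resection-type deletions at the
junction.

## Coordinates and cut geometry

All coordinates are 0-based, half-open intervals on the plus strand of a
`locus`. A `spacer_site` is a 20-nt protospacer with an NGG PAM; the blunt
cut falls between protospacer positions 17 and 18 (3 nt 5' of the PAM),
which for a plus-strand protospacer at `[s, s+20)` is position `s + 17` and
for a minus-strand site `s + 3`. `N` bases in the reference never match a
protospacer or PAM position. Staggered (1-nt 5' overhang) SpCas9 cleavage
is not modelled; junction bookkeeping assumes blunt ends throughout.

The 17-nt protospacer portion retained on the PAM-distal side of the cut —
the *residue spacer* — survives in edited junctions and is annotated on
every predicted allele, since it is the natural landmark for confirming a
junction by sequencing.

## pegRNA construction

A pegRNA is `spacer + scaffold + RT template + PBS`, 5'→3', stored in DNA
alphabet (the T/U distinction is presentational). The PBS is the reverse
complement of the `pbs_len` nucleotides immediately 5' of the cut on the
non-target strand; the RT template is the reverse complement of the
intended flap. Defaults are `pbs_len = 13` and `ha_len = 13`, mid-range
values for flap designs of this kind; both are freely configurable
per design, and `validate_plan()` warns rather than errors outside the
practical ranges (PBS 8-17 nt; HA at least 8 nt, the shortest
microhomology known to support Rad51-assisted homology search). For
homology-independent designs an EcoRV site (`GATATC`) can be appended at
the flap 3' end — the 5' proximal portion of the RT template — so that
integration is detectable by restriction digestion; combining it with a
homology arm is rejected as a design error because the arm must occupy
exactly that end of the template.

Orientation of paired designs is enforced, not inferred: `site_a` must be
a plus-strand site and `site_b` a minus-strand site so that both PAMs fall
inside the removed or exchanged fragment and both retained fragments carry
flaps. For translocations the package always also emits the reciprocal
(balanced) derivative as a labelled prediction with a cautionary note;
experimentally only the unbalanced derivative is recovered, and keeping
prediction separate from expectation lets users test for both.

## Outcome classification

Merged amplicon reads are classified against the wild-type reference(s)
and the predicted accurate allele into `UNEDITED`, `ACCURATE_EDIT`,
`EDIT_WITH_INDEL`, `PURE_INDEL` or `DISCARDED`. "Prime edits" are accurate
edits plus edits containing indels; total editing activity additionally
counts pure indels.

Alignment is global with affine gap penalties (match +2, mismatch −4, gap
open −12, extend −2), computed with `Biostrings::pairwiseAlignment`. The
scoring scheme is a package choice — validated by the property that
classification of simulator output with zero sequencing error reproduces
the ground-truth labels exactly — since heavier gap opening than extension
keeps sequencing noise from fragmenting single biological indels.

Decision rules, in order:

1. reads outside the configured length bounds, or empty, are `DISCARDED`;
2. the better-scoring reference wins; exact ties are broken by presence of
   the exact edit string (with `junction_flank = 6` nt of context on each
   side) and otherwise discarded as ambiguous;
3. the edit is *detected* if that junction-spanning string occurs in the
   read, or the read aligns to the edited allele with no indel operation
   disrupting the edit interval (insertions exactly at the interval
   boundaries leave it intact);
4. only indel operations inside the quantification window — ±20 nt around
   each cut or around the edit junction — count toward the class;
   substitutions alone never change a class, which is what makes the
   classifier robust to sequencing error.

The ±20 nt window is standard amplicon practice: wide enough to catch
junction-proximal repair products (including a duplicated 13-nt HA), narrow
enough to ignore unrelated polymorphisms. Indel positions are reported in
0-based reference coordinates, derived from the aligner's indel ranges by
discounting insertion columns.

Activity thresholds follow the reporting convention of targeted
deep-sequencing screens: editing is called when total activity exceeds
0.2% of retained reads on target, with the bar lowered to 0.01% for
off-target comparisons where efficiencies are far lower.

## Efficiency quantification

Two independent physical readouts are implemented.

**Gel densitometry.** Band intensity is proportional to molar amount times
fragment length, so the deleted-allele fraction is the length-normalised
ratio

$$\mathrm{efficiency} = \frac{G_d / L_d}{G_d / L_d + G_u / L_u}
\times 100\%$$

with $G$ the background-corrected greyscale and $L$ the band length in bp.
The formula is scale-invariant in the greyscales and monotone in each
band, which the test suite checks over a large random grid. Background
subtraction is upstream; the package consumes corrected values.

**Absolute qPCR.** A standard curve $CT = a \log_{10}(\mathrm{copies}) + b$
is fitted by least squares to a serial tenfold dilution of a reference
plasmid (at least 3 points; the conventional series runs
$2\times10^1, 10^2, \dots, 10^9$ copies/µL). Amplification efficiency is
$10^{-1/a} - 1$; replicate CTs are arithmetic-averaged before conversion
(standard practice; averaging CTs rather than copies keeps the estimator
median-unbiased under symmetric CT noise). The deletion efficiency is the
ratio of absolute copies measured by a junction-specific assay and a
flanking assay:

$$\mathrm{efficiency} = \frac{\mathrm{copies\ (deleted)}}
{\mathrm{copies\ (flanking)}} \times 100\%.$$

The ratio is deliberately not clamped at 100%: it is a ratio of two
absolute measurements and can exceed 100% under noise, which is flagged
(`over_100_percent`), as is any CT outside the fitted dilution range
(`extrapolated`).

## The synthetic-data generator

`simulate_reads()` draws each read's class from the stated mixture
(multinomially by default, with a fixed-count mode for exact tests), picks
the matching allele — wild type, accurate edit, or an indel archetype —
and applies per-base substitution (default 0.001) and indel (default
1e-4) sequencing errors. Output is byte-identical for a fixed seed.

The indel archetypes mirror the repair structures described above:

* `ha_duplication_join` — the accurate junction with the homology arm
  present twice (flap copy followed by genomic copy);
* `blunt_join_indel` — direct fusion of the retained fragments with no
  edit, optionally with a junction resection;
* `random_small_indel` — a 1 + Geometric(0.35) length indel (capped at
  8 nt) near the junction.

Two placement rules keep the ground truth identifiable, which is what the
recovery tests rely on. Edit-with-indel reads receive their random indel
*near but never inside* the edit (offset 3-12 nt), because an indel that
destroys the edit is by definition no longer a prime edit. Pure-indel
junction lesions are modelled as resection-style deletions spanning the
break rather than insertions placed exactly at it: a blunt junction plus a
small junction insertion is genuinely ambiguous with an accurate edit
carrying substitutions (any classifier must absorb one as the other),
whereas resection deletions — also the dominant NHEJ signature at a DSB —
are always structurally distinct from a written edit.

What the simulator does *not* emulate: position-dependent Illumina quality
profiles, chimeric reads, PCR duplicates, or paired-end merging artefacts
(reads are assumed pre-merged). Passing recovery tests therefore
demonstrates correctness of the classification logic under idealised
noise, not performance on raw instrument data. Quality strings are a
constant Q30 placeholder; the classifier is quality-agnostic.

`simulate_gel()` and `simulate_qpcr()` are generative inverses of the two
efficiency equations: they construct greyscales/CT tables whose noise-free
evaluation returns exactly `100 * true_fraction`, enabling machine-checked
round-trips (to 1e-9 relative error for qPCR) and Monte-Carlo recovery
under noise.

## Problem sizes and numerical choices

The test suite and the acceptance script run the read pipeline at
n = 10,000 reads on ~260 bp synthetic loci with a 6-nt edit and 13-nt
homology arms — large enough for per-class binomial standard errors of
well under 1 percentage point, small enough to keep a full run in tens of
seconds. Designer and bookkeeping properties are checked over hundreds of
randomised plans; densitometry properties over a 1,000-point grid.
Score ties in classification are resolved as described above; the
degenerate deletion with coincident cuts and an empty edit correctly
returns the unmodified locus; an edit-free C2 design is flagged as an
error because flaps with no shared edit cannot anneal.

## Known limitations

* Thermodynamics are out of scope: no PBS/RT-template melting prediction,
  no on/off-target activity scoring — `validate_plan()` reports structural
  findings only.
* Off-target analysis implements only the comparison and threshold logic;
  nominating off-target sites is upstream.
* The relative real-world frequencies of the indel archetypes are only
  qualitatively known; the `indel_model()` weights are configurable
  defaults, not estimates.
* Classification reproduces the published outcome taxonomy; it is not a
  line-by-line reimplementation of any particular analysis script.
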