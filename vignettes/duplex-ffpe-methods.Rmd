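---
title: "Methods: coordinate-keyed duplex consensus calling for FFPE DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordinate-keyed duplex consensus calling for FFPE DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Duplex sequencing accepts a variant only when it is observed independently
on both strands of one DNA molecule, which suppresses the dominant error
modes of short-read sequencing — chemical base damage, PCR misincorporation
and sequencer miscalls — because all of them affect a single strand and its
copies.  In the bottleneck variant of the method the library is diluted to a
few tens of thousands of molecules before amplification, so the mapped
template coordinates `(reference, start, end)` of a read pair identify the
source molecule and no molecular barcode is needed.

DNA recovered from formalin-fixed paraffin-embedded (FFPE) tissue
complicates this picture in two ways.  First, it carries single-strand
lesions — chiefly cytosine deamination, read as C>T on the damaged strand —
at rates orders of magnitude above any real mutation load.  Second, it is
nicked and gapped, so one strand of many molecules cannot be amplified at
all, depressing the fraction of molecules that ever form a duplex.  Worst
of all, the standard library end-repair step uses a DNA polymerase to fill
in 5'-protruding ends: wherever the template strand of that fill-in carries
a lesion, the polymerase copies it into the newly synthesized strand,
converting a correctable single-strand artifact into an uncorrectable
double-strand "mutation" concentrated near fragment ends.  Replacing the
polymerase with a single-strand-specific nuclease, which simply removes the
overhangs, eliminates this artifact class at the cost of slightly shorter
templates.

This package implements both the analysis pipeline (filter → group by
coordinates → per-strand consensus → duplex merge → variant calls →
common-SNP removal → burden metrics) and a generative simulator of the
library chemistry, so the pipeline's claims are testable end-to-end against
a ground-truth ledger without patient data.

## The pipeline model

**Read filtering.**  Pairs are dropped, in fixed order, when improper, when
mapping quality falls below a threshold (default 30 — the operational
reading of "ambiguously mapped", a concept the protocol names but does not
quantify), when soft-clipped, or when a mate carries more than
`max(7, 10% of aligned length)` mismatches.  The mismatch cap is a design
choice: a legitimate hypermutator template at ~100 mutations/Mb contributes
far less than one mismatch per 150 bp read, so the rule only fires on
misaligned or chimeric reads.  Read ends are masked (default 5 bases per
read end) rather than re-clipped, because the outer template coordinates
*are* the molecule identifier and must not move.

**Consensus.**  Families are exact-coordinate groups split by read-pair
orientation.  A family is rejected outright below `min_copies` (default 5,
the five-PCR-copies rule), and independently each position needs
`min_copies` contributing copies with modal-base agreement of at least
`min_agreement` (default 0.8).  Support is counted per PCR copy, not per
read: where the two mates of a pair overlap they must agree, else that
copy abstains at the position.  Strict unanimity instead of 0.8 would
discard most families at realistic sequencing error rates; a majority floor
above 0.5 guarantees the modal call is unique.  Indels are represented as
deletion columns and anchored insertion events and go through exactly the
same depth/agreement arithmetic; this matters because microsatellite-
unstable tumors are indel-dominated.  Whether the five-copy rule is
per-family or per-position is genuinely ambiguous in the protocol; we
apply both, and both knobs are exposed in `consensus_config()`.

**Duplex merge.**  All sequences live in reference-strand space, so the
complement-aware concordance rule reduces to equality: a position is
duplex-called iff both strand consensuses call it identically, and the
duplex length of a template is its count of duplex-called positions — the
denominator of the burden unit (mutations per Mb of duplex sequence).

**Calling and SNP removal.**  Every duplex-called difference from the
reference emits one call per supporting template; deletion runs are merged
into single events and all indels are left-aligned.  Calls whose
allele-matched population AF exceeds 1% are removed (strictly greater, so
AF = 0.01 is retained); sites absent from the table are "unknown" and
retained, which is deliberately different from AF = 0.  Without germline
whole-genome data, rare germline variants are *not* separable from somatic
mutations; output is therefore labelled "mutations", and the caveat
applies to every downstream number.  The removed-common rate per Mb is
reported as a sanity metric — it should track planted (or population)
heterozygosity.

**Metrics.**  Burden CIs are exact Clopper–Pearson intervals
(`qbeta`-form), chosen over the normal approximation because duplex
footprints of 0.1–1 Mb put mutation counts in the tens.  The fragment-end
profile assigns each mutation `1 + min(distance to either template end)`
and normalizes per-distance event counts by per-distance duplex coverage so
short templates do not bias the tail; both raw counts and normalized rates
are emitted.  Single-strand corrected events (strand-consensus calls the
duplex does not confirm) are reported per Mb of called strand-consensus
sequence — a distinct denominator from the duplex length, and both are
stored so either convention is recomputable.

## The simulator's stated world

Defaults describe an FFPE specimen: fragments log-normal with median 146 bp
(dispersion sdlog 0.185, i.e. a spread of about ±27 bp, typical of archival material), reads 2×150,
a bottleneck of 20,000 molecules, shifted-Poisson PCR copies with mean 8
per strand, per-strand dropout 0.55 (so both strands survive with
0.45² ≈ 0.20, the duplex fraction typical of FFPE libraries), lesions at 1000 per Mb of
single-stranded sequence per strand (FFPE corrected-event loads span
roughly 200-2400/Mb), 90% of them C>T deaminations, and geometric 5'-overhangs with
mean 6 bases per end.  A `blood` preset lengthens fragments to 213 bp,
drops the lesion load and sets dropout to 0.31 (≈47% duplex-formable).
Germline SNPs are planted at 3000/Mb, 70% common (AF uniform on
0.01–0.5) and 30% rare, with genotypes drawn per Hardy–Weinberg; that
density reproduces a removed-common-SNP rate in the high hundreds per Mb,
the right order for a human genome against a population database.

Genuinely open design choices, decided once here:

* **Overhang distribution** — geometric, mean 6: memoryless end-resection
  intuition, and it produces the observed end-proximal artifact decay.
* **PCR copy number** — `1 + Poisson(mean − 1)`: the method only requires
  that five copies per strand be routinely attainable.
* **Clonality** — somatic variants are fully clonal (every overlapping
  molecule, both strands).  This makes the planted per-Mb rate equal the
  expected molecular detection rate, so rate-recovery tests are exact; a
  subclonal mixture would only rescale expected counts.
* **Indel placement** — an indel is applied to a molecule only when the
  whole event lies inside the fragment; a fragment boundary cutting through
  an indel leaves the reference allele.  This avoids boundary-truncated
  alleles that no caller could match to truth.
* **Lesion base-conditioning** — deamination targets are drawn among the
  damaged strand's cytosines; an event with no valid target base in its
  span is skipped and counted (`truth$skipped_lesions`), per the
  base-conditional contract.
* **Fragment cap** — fragment lengths are capped at 2× read length so
  mates always read through the whole template; longer molecules would
  merely add undetermined mid-template positions.

What the simulator does **not** model: sequence-context lesion hotspots,
quality-score structure beyond a flat Phred value, adapter chemistry,
alignment ambiguity in repetitive genomes (the reference is uniform
random), and subclonal tumor architecture.  A green test therefore
establishes the *pipeline arithmetic* — identification, consensus,
correction, filtering, estimation — not robustness to real-genome
alignment artifacts.

## Numerical and procedural notes

* Internal coordinates are 0-based half-open everywhere; 1-based conversion
  happens only at SAM/VCF boundaries.
* Ties in the modal-base tally can never be called because
  `min_agreement > 0.5` is enforced; the tie-break is therefore moot.
* Indel left-alignment shifts events through shared suffix bases to the
  leftmost representation; the same normalizer canonicalizes planted truth,
  so truth and calls compare on identical coordinates.
* Two distinct molecules can collide on identical coordinates; they are
  accepted as one template (a known, quantified error mode — the
  alternative, fuzzy coordinate merging, risks chimeric families).  At
  20,000 molecules on a megabase-scale reference the collision rate is
  far below 1%.
* Determinism: all randomness flows from one integer seed through a fixed
  RNG kind, and reports contain no timestamps, so identical config + seed
  reproduce byte-identical outputs.
* The acceptance-style tests run the full pipeline over 20 seeds per
  property.  They scale the world down (200 kb reference, 2,500–3,500
  molecules, PCR mean 6–7) to fit desk budgets; the scales come from
  pre-hoc power calculations, and the duplex-fraction closed-form check
  keeps the full 20,000-molecule bottleneck.  The end-profile experiment
  sets `end_trim = 0`: with read-through mates, a 5-base read-end mask
  makes template positions 1–5 unobservable and would censor the very
  signal the profile measures.

## Known limitations

Rare germline contamination of the "mutation" rate is inherent to the
no-matched-normal design; the tests subtract it through the truth ledger,
which real data cannot do.  The mismatch-filter and trim defaults are
package choices where the protocol is silent, and are surfaced in
`filter_config()`.  The SNP filter is allele-matched (stricter than
position-matched; a position-matched reading is conceivable).
CRAM, remote streaming, realignment and base-quality recalibration are out
of scope.
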