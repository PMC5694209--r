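---
title: "Identifying membrane-bound transcription factors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying membrane-bound transcription factors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfscan)
library(dplyr)
```

## The problem

Membrane-bound transcription factors (MTFs) are transcription factors held
dormant at a cellular membrane by one or more transmembrane (TM) helices.
Upon a stimulus they are released — by regulated proteolysis near the TM
span, or by expression of a splice isoform that never encodes the TM
segment — and translocate to the nucleus. Because this activation skips
transcription and translation, MTFs are fast responders, and cataloguing
them across plant proteomes is of broad interest.

`mtfscan` implements a genome-scale MTF identification workflow over
transcription-factor protein collections:

1. per-protein TM topology prediction (a built-in hydrophobicity-profile
   predictor, plus adapters for external predictor output);
2. an agreement-based consensus across predictors;
3. a separately handled, posterior-filtered TMHMM-style branch;
4. a union merge of the two branches into the final MTF call set;
5. TM-count and terminal-location classification;
6. family-by-species tabulation;
7. a screen of splice isoforms for TM loss with retention of the
   DNA-binding domain.

Everything is tabular: proteins, predictions and calls are tibbles, and the
scan result carries `tidy()`, `glance()` and `autoplot()` methods.

## The built-in hydrophobicity predictor

The classical hydrophobicity-profile method scores each residue by a
hydropathy scale and smooths with a trapezoid sliding window. The value at
position $p$ is

$$H_p = \frac{\sum_{k=-w}^{w} \omega_k\, h(s_{p+k})}{\sum_{k=-w}^{w} \omega_k},$$

where $h(\cdot)$ is the scale, $\omega_k = 1$ across an 11-residue core and
decays linearly to $1/6$ across 5-residue wedges on either side
($w = 10$), and windows truncated by a sequence end are renormalized by the
weights actually applied. Defaults use the GES transfer free-energy scale
(hydrophobic positive, kcal/mol); Kyte–Doolittle is bundled as an
alternative. The unknown residue X scores 0 on every scale; B/Z/U and stop
characters are rejected at input.

Candidate TM segments are the maximal runs of profile values at or above
the lower cutoff (0.6 GES units). Runs separated by fewer than
`min_loop_len = 2` residues are merged, then segments shorter than
`min_helix_len = 17` are discarded — a membrane-crossing helix needs
roughly 17–25 residues. A kept segment is *certain* when its peak reaches
the upper cutoff (1.0), otherwise *putative*. Run-based calling is simpler
than fixed-length peak expansion and equivalent for well-separated helices,
which is the regime TF proteins (mostly one or two spans) occupy.

Orientation follows the positive-inside rule: of the two alternating
inside/outside loop labellings, the one whose inside loops contain more
Lys/Arg wins. Only the `loop_charge_window = 15` residues adjacent to each
span are counted per loop, because charge bias is local to the membrane
interface; ties default to first-loop-inside, a fixed, documented
tie-break.

All parameters live in `hydro_params()` and are recorded alongside every
run.

## External predictors and the consensus

The package never executes third-party predictors; it parses their output.
TMHMM-style long reports and plp posterior tracks have dedicated parsers;
every other predictor enters through a one-line-per-protein
`id<TAB>topology-string` format. Topology strings over `{i, M, o}` with
non-alternating loops are accepted but flagged invalid.

Two predictions *agree* when they have the same span count, corresponding
spans overlap by at least `min_overlap = 5` residues, and the N-terminal
loop state matches. Agreement is reflexive and symmetric but not
transitive, so consensus uses greedy clustering in a fixed predictor
priority order: each prediction joins the first class whose *founder* it
agrees with, else founds a class. The winner is the largest class's
founder, ties resolving to the earliest-founded class. This makes the
consensus deterministic for any input order. A winning span-free topology
is a "soluble" consensus.

TMHMM-style predictions are kept out of the consensus and filtered
separately: a span survives when its mean per-residue membrane posterior
exceeds 0.90 strictly. The mean over the span was chosen over the minimum
as less brittle to single-residue dips; both are available
(`tmhmm_statistic`). The final MTF set is the *union* of consensus calls
and filtered TMHMM calls — the workflow's two branches — with consensus
spans preferred for doubly-called proteins (the merge records provenance,
so either choice can be audited).

## Location classes

The printed N-terminal / central / C-terminal proportions in the source
literature come with no numeric zone definition. `mtfscan` defines the
zones as length fractions (default thirds) and classifies each span by its
midpoint, with boundary ties resolving toward the terminal classes. Both
fractions are configurable (`classify_params()`) and recorded in reports,
so published-count comparisons can be tuned; exact reproduction of any
particular published split is not claimable without the original zone
definition. Percentages round half-up at one decimal (and zero decimals
for the ALS fraction), matching how the printed ratios behave.

## The alternative-splicing screen

A locus is ALS-activatable when some isoform loses every TM span yet
retains the DNA-binding domain. The comparison method behind the published
isoform analysis is unstated, so the package operationalizes it as:

* the reference isoform is the one with predicted TM spans (the longest
  such isoform if several);
* a variant qualifies iff the built-in predictor finds **zero** spans on it
  *and* at least 90% of the reference's domain interval aligns identically
  in a global alignment (match 2, mismatch −1, affine gaps: a gap of
  length $L$ scores $-5 - L$);
* the locus is flagged iff any variant qualifies.

Domain intervals are caller-supplied, not predicted. Every threshold is
configurable. Gaps and mismatches both count against coverage, so
“identical domain retained” is a strict criterion.

## The synthetic proteome generator

No external database is needed to exercise the pipeline: `genome_fixture()`
emits multi-species TF proteomes with known ground truth.

* Planted TM spans are contiguous blocks of 19–23 residues (centred on 21)
  drawn from Leu/Ile/Val/Phe/Ala/Met with frequencies favouring L/I/F/M
  (mean GES ≈ +3.0, typical of single-pass helices).
* The background emulates the Ser/Thr/Gly/Pro-rich disordered regions of
  transcription factors, drawn from the ten hydrophilic residues with mean
  GES ≈ −0.67 — below the 0.6 detection cutoff, as a soluble background
  must be.
* The twelve residues flanking each block come from a cooler Asn/Gln/Ser/Thr
  pool so the hydropathy run a block produces ends near the block edges on
  both sides and called spans stay centred on the plants.
* Decoys and planted-protein backgrounds are *adversarially resampled*:
  any window reaching the lower cutoff away from a block is redrawn, so the
  expected decoy false-positive count is exactly zero and spurious spans
  cannot arise by chance. The generator additionally verifies each plant —
  a draw whose blocks are not recovered as one well-centred span each is
  rejected and redrawn deterministically — so the fixture's truth file is a
  guarantee, not a probabilistic statement.
* Everything is seeded; per-protein seeds derive from the master seed and
  are recorded in FASTA headers, making fixtures byte-identical across
  re-runs.

What the fixtures deliberately do **not** model: real TF domain sequences
(no NAC/bZIP motifs), compositional drift along a protein, signal peptides
(which hydrophobicity methods famously confuse with TM helices),
marginally hydrophobic helices, or amphipathic ones. Passing the recovery
properties therefore demonstrates that the computation is correct under
its own model, not that the predictor matches laboratory topology on real
proteomes — that is what the multi-predictor consensus is for.

Default study conditions used by the validation suite: two species × 500
proteins with a 5% planted-MTF fraction for the recovery property (the
observed per-species MTF fraction in genome-wide surveys is roughly 3–16%);
a six-predictor panel with five correct predictors and span jitter ≤ 3 for
the consensus property; 50 loci for the ALS property. These sizes keep the
whole suite in the tens of seconds while leaving every assertion sharp.

## Numerical and degenerate-input choices

* Coordinates are 1-based and inclusive on both ends everywhere, the
  TMHMM report convention; every report header says so.
* Rounding is half-up (not banker's) at the printed precision, because
  printed percentages in this literature follow conventional rounding.
* Sorting of family/species names is case-insensitive and
  locale-independent (radix order on the lower-cased key), so tabulations
  are identical across platforms.
* Empty inputs are legal where a result is representable: an empty FASTA
  scans to an empty report (exit 0 at the CLI), an empty MTF set writes a
  header-only file; fractions over zero loci are errors.
* A single-residue protein has a profile (its own scale value) because
  truncated windows renormalize rather than pad.
* Co-optimal global alignments resolve by the alignment engine's
  deterministic traceback; coverage verdicts in the screen do not depend
  on the choice because qualifying variants are exact subsequence
  excisions.

## Worked example

```{r example, eval = FALSE}
fx <- genome_fixture(tempfile(), n_species = 3, n_tf_per_species = 100,
                     mtf_fraction = 0.05, seed = 42)
scan <- run_scan(fx$fasta, fx$annotation_file, out_dir = tempfile())
glance(scan)
#> # A tibble: 1 x 5
#>   n_proteins n_mtf pct_mtf n_species n_families
#>        <int> <int>   <dbl>     <int>      <int>
#> 1        300    15       5         3          8
```

All fifteen planted MTFs are recovered and none of the 285 decoys is
called; the summary tables, the TSV report, the resolved configuration and
the run log land in the output directory.

## Known limitations

* The hydrophobicity predictor is a single-sequence method; it will call
  strongly hydrophobic signal peptides as TM spans and can miss marginally
  hydrophobic helices. Use external predictor reports and the consensus
  when available.
* The ALS screen requires isoform protein sequences and a domain interval
  on the reference; it does not analyse transcript structure or verify
  nuclear localization signals.
* Published catalog counts from any particular survey depend on the exact
  predictor binaries, database versions and undocumented zone definitions
  used there; the package reproduces the arithmetic and the workflow, not
  the external software stack.
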