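---
title: "Methods: isomiR detection, nomenclature and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR detection, nomenclature and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirseq)
```

## The problem

Pre-miRNA hairpins almost never yield a single mature sequence. Deep
small-RNA sequencing reveals, alongside each miRBase-annotated canonical
miRNA, a population of sequence variants — isomiRs — that differ in their
5' start, their 3' end, internal bases, or carry non-templated 3' additions
(NTA). Studying them requires (i) an aligner that knows the exact 3' end of
each captured tag, (ii) a classification that assigns every tag to exactly
one variant class, (iii) a name that machine-readably identifies each
variant, and (iv) quantification that is robust to sequencing noise and
library-composition bias. `isomirseq` implements this stack end to end,
together with the downstream cohort analyses it enables (arm-switching
detection, screening for AGO2-cleaved pre-miRNA [ac-pre-miRNA] candidates,
and paired-condition ablation testing).

## Alignment model

Tags are placed on hairpin references by substitution-only (Hamming)
matching: up to `max_sub = 2` mismatches, no insertions or deletions, and a
minimum matched length of `min_len = 20` nt, below which short-tag matching
loses specificity. Restricting the search space to annotated hairpins
(rather than a whole genome) is what makes mismatch-tolerant matching of
20–24-nt tags feasible at all: most matures cannot be placed uniquely in a
genome.

Two strategies are provided:

* **Recursive trimming** (`recursive_map()`): the tag is tried at full
  length; while nothing places, `trim_step = 1` base is removed from the 3'
  end and the scan repeats, down to `min_len`. This is the sensitive mode —
  3' quality decay and adaptor remnants do not cost the tag — but the
  reported 3' end is a lower bound, not the captured end. Trimming is
  3'-only because that is where short-read quality decays; the step size
  and direction are this package's choices and are configurable.
* **Adaptor-trimmed exact-end alignment** (`adaptor_trim_map()`): the 3'
  sequencing adaptor is located (5'-most position where an adaptor prefix
  matches the read suffix with overlap ≥ 5 and ≤ 10% mismatches) and
  stripped, so the captured 3' end is known exactly; the tag is then placed
  at its full trimmed length after NTA peeling. This is the mode isomiR
  calls use — start/end deltas are only meaningful when the tag's ends are
  real.

**NTA peeling** (`extract_nta()`): every split of the trimmed tag into a
templated core and a 3' suffix of 0–`nta_max` (default 5) bases is
considered. A split is admissible when the core places within `max_sub`
mismatches and every suffix base is non-templated at that placement (beyond
the hairpin's 3' end, or differing from the hairpin base). Among admissible
splits the one with the fewest substitutions wins; ties go to the longer
templated core. The consequence is that a tag whose terminal base mismatches
the template is read as a 1-nt NTA (0 substitutions beat 1), while terminal
bases that match the template are read as templated extension, never as NTA.
The degenerate middle ground — a terminal mismatch that could be either —
is thereby resolved deterministically and conservatively toward NTA.

**Multi-mapping**: all equal-best placements (minimal substitutions at the
winning length) are retained and the tag's mass is split evenly (`1/k` per
placement), conserving total tag mass; ordering by `(hairpin_id, start)`
keeps outputs byte-reproducible. Duplicating or discarding multi-mapped tags
would inflate or deflate totals instead.

The placement scans are executed by `Biostrings` C-level mismatch counting
over a concatenated reference subject, with window starts restricted to lie
inside a single hairpin; unit tests compare every mode against brute-force
offset-enumeration oracles.

## Arm assignment and classification

Each hairpin carries at most one 5p and one 3p mature annotation (1-based,
inclusive, hairpin-relative coordinates; the pinned convention is a 21-nt
mature occupying positions 60–80). The annotation does not define the arm,
so the arm of an annotation is called from its span midpoint relative to the
hairpin midpoint (ties → 5p, logged); a placement is assigned to the arm it
overlaps most (absolute overlap, then overlap fraction, then 5p).
Placements overlapping neither mature — loop-only placements — are
*orphan-side*: their mass still counts toward the library, but they carry no
feature vector.

Relative to its arm's canonical mature, each tag reduces to a feature
vector `(Δstart, Δend, n_sub, nta_len)` where `Δend` refers to the
*templated* end. Classification is a total decision table over that vector:

| Δstart | Δend | subs | NTA | category |
|-------:|-----:|-----:|----:|----------|
| 0 | 0 | 0 | 0 | canonical |
| ≠0 | 0 | 0 | 0 | start_only |
| 0 | ≠0 | 0 | 0 | end_only |
| 0 | 0 | >0 | 0 | substitution_only |
| d≠0 | d | 0 | 0 | shifted |
| 0 | 0 | 0 | >0 | nta3 |
| — anything else — | | | | mixed |

Every vector maps to exactly one of the seven classes (property-tested by
exhaustive enumeration). Note the deliberate strictness of `nta3`: an NTA on
a shifted or substituted core is `mixed`, which preserves mutual
exclusivity.

## The isomiR name

Names follow `"<arm>|{<label>}|<start>_<end>|<modifiers>"`:
`hsa-miR-143-3p|{hsa-miR-143}|60_80|` is the canonical 3p mature of that
hairpin; `hsa-miR-143-3p|{isomiR}|62_80|sub.77.G>A` is a variant starting
two nucleotides downstream with a G→A substitution at hairpin position 77.
The label is the mature name exactly when the tag is canonical, the literal
`isomiR` otherwise; coordinates are the templated span; substitution
modifiers are sorted by position; NTA bases are rendered as
`add.<pos>.<nt>` with positions continuing hairpin numbering past the
templated end (the NTA modifier syntax is this package's extension, in the
same style as the substitution descriptor). `parse_name()` inverts
`render_name()` exactly and additionally accepts the spaced substitution
dialect (`sub.77.G > A`) seen in print. Round-tripping is property-tested on
10,000 random records.

## Quantification

Counts are `multiplicity × weight` sums per (feature, sample); per-sample
raw library size is the mapped tag mass, and
`tpm = 1e6 × count / effective_library_size`. Effective sizes are raw sizes
times TMM scaling factors (trimmed mean of M-values; 30% trim on log-ratios,
5% on abundances, inverse-variance precision weights, factors anchored to
geometric mean 1, reference sample chosen by the upper-quartile rule). The
TMM computation is delegated to `edgeR::calcNormFactors()`; the test suite
holds it against an independent transcription of the formula to 1e-10.
Corrections of this kind matter precisely when libraries with very different
compositions are compared — e.g. a wild-type versus a mutant in which a
whole class of products is ablated.

**Noise floor**: tags are also aligned (same parameters) to *decoy* matures
— sequences that cannot genuinely be present, such as non-conserved matures
from distant species. The floor is the worst decoy tpm over all samples,
rounded up; decoys within `max_sub` mismatches of any target mature are
dropped first (they could absorb genuine signal), and when no decoy draws
any alignment the configured default of 10 tpm applies. The max-decoy rule
is the most conservative reading of a decoy-calibrated threshold; a
quantile could be substituted via the exposed value.

**Robustness filters** (`apply_filters()`): a feature is kept iff (i) some
tissue shows it at ≥ `min_tpm` (default 10) in *every* sample of that
tissue, (ii) it is detected (tpm > 0) in samples spanning ≥ 2 distinct
library-prep kits, and (iii) it is not an orphan isomiR (an isomiR whose
arm's canonical is never detected in any sample — a signature of a
mis-annotated mature) when orphan dropping is enabled. "Present" (the tpm
threshold) and "detected" (any evidence) are deliberately distinct notions:
the tissue rule asks for reproducible expression, the kit rule only for
chemistry-independent existence.

## Cohort analyses

* **Arm dominance / switching**: per (hairpin, tissue), arm totals are the
  sum of feature tpm per arm averaged over the tissue's samples (the mean is
  this package's aggregation choice); `log2(5p/3p)` gives the dominant arm,
  and a pair is *eligible* when both arms reach the noise floor. A hairpin
  *switches* when ≥ 2 tissues are eligible and the dominant arm is not
  constant across them. Eligibility is evaluated per tissue rather than
  globally — a hairpin whose minor arm is silent in some tissue should not
  be judged there.
* **ac-pre-miRNA screening**: AGO2-cleaved pre-miRNAs mature by
  exonucleolytic 3' trimming rather than Dicer cleavage, leaving three
  fingerprints: a highly consistent mature 5' end, a silent opposite arm,
  and a trail of templated 3'-extension intermediates. The screen
  formalizes them as: modal 5'-start fraction ≥ 0.9; opposite-arm tpm below
  the noise floor in every sample of the tissue; and ≥ 10% of arm mass
  ending ≥ 2 nt past the canonical 3' end over ≥ 3 distinct end positions.
  These thresholds quantify qualitative hallmarks and are all exposed as
  arguments. Both arms are tested as the potential dominant arm, and only
  tissues whose samples span ≥ 2 prep kits are evaluated, so a single
  chemistry cannot fabricate a candidate. Which mature end is the
  "consistent" one is genuinely ambiguous for loop-spanning matures; this
  implementation keys on 5'-start consistency plus a 3' extension trail.
* **Ablation testing**: to compare conditions at very different depths, the
  deeper library is resampled without replacement to the shallower depth
  (seeded hypergeometric subsampling). The group-level test is a 2×2
  Pearson chi-square (no continuity correction) of candidate-derived vs
  other mass by condition; per candidate, classes are `complete_ablation`
  (mutant canonical mass 0), `strong_reduction` (canonical reduction
  > 80%), `isomiR_support` (isomiR mass down > 80%), else `unsupported`.
  The 2×2 construction (candidate vs non-candidate mass × condition) is
  this package's formalization of a group ablation test.

## The synthetic-data generator

`sim_spec()`/`simulate_cohort()` generate complete cohorts with per-read
ground truth so every claim above is testable without downloads. The
defaults define the simulated study conditions:

* 20 uniform-random hairpins (70–110 nt) with one 5p and one 3p mature of
  20–23 nt separated by a ≥ 8-nt loop, with enough flanking sequence that
  ±2-nt variants stay templated;
* eight libraries over four tissues × two prep kits at 3,000 reads each —
  the tissue × donor × kit structure of a multi-tissue survey at desk
  scale;
* a category mixture of 45% canonical, 20% 3'-end variants, 8% start
  variants, 7% substitutions, 5% shifts, 8% NTA, 7% mixed — canonical reads
  dominant and 3'-end variation the most common isomiR class, as in
  small-RNA data where the 3' end is the labile one;
* 0.5% per-base substitution error (no indels — short-read platforms'
  indel rates in this size range are negligible), full adaptor
  read-through (a 20–24-nt insert is always sequenced into the adaptor),
  and truth recorded before error injection;
* designed hairpins: arm-switch hairpins flip an 80/20 arm bias in one
  tissue; ac-pre hairpins emit a single 5' start with a 25% templated
  extension trail (2–8 nt) and a silent opposite arm; orphan hairpins emit
  a +1 end variant but never the canonical on one arm;
* decoy matures generated by rejection so that *every* prefix of alignable
  length is > `max_sub` mismatches from every hairpin window (verified by
  exhaustive scan) — decoy reads provably cannot map to targets;
* `decoy_fraction = 0` by default: at 3,000 reads per library a single
  decoy read already corresponds to hundreds of tpm, so any nonzero decoy
  contamination saturates a max-decoy floor at desk scale; default
  libraries are decoy-clean and the floor machinery falls back to its
  configured default, while the ceiling arithmetic itself is unit-tested
  on constructed masses.

Substitution variants are drawn at interior tag positions only: a variant
at the terminal base is *genuinely* ambiguous between a substitution and a
1-nt NTA reading (the aligner resolves it toward NTA, see above), and a
generator that wants unambiguous truth must not produce it. Similarly, NTA
bases are drawn to differ from the templated base at their position.

What the generator does **not** emulate: RNA secondary structure (hairpin
sequences are uniform-random — alignment and classification never consume
structure), ligation/chemistry biases between kits, position-dependent
error profiles, and color-space encoding. Passing tests therefore
demonstrate the correctness of the algorithms under the stated read model,
not robustness to every artifact of real libraries.

## Problem sizes and determinism

The shipped test suite runs cohorts of 8 × 1,500 reads for end-to-end truth
recovery, a 20,000-read single library for mixture recovery, a 65-hairpin
wild-type/mutant pair for the ablation design, 1,000 random tag/hairpin
pairs against the alignment oracle, and 10,000 records through the
nomenclature round trip — sizes chosen so the whole suite completes in
minutes on one CPU while every statistical check retains 3-sigma headroom.
All randomness flows from fixed seeds; identical inputs yield byte-identical
outputs everywhere in the pipeline.

## Known limitations

* Indel-bearing isomiRs are invisible by design (substitution-only
  placement).
* 5' additions are not modeled as NTA; they appear as start variation.
* The nomenclature grammar covers substitutions and 3' additions; further
  modifier families would need grammar extensions.
* The ac-pre screen reports candidates, not mechanism: only a paired
  functional comparison (e.g. catalytically dead AGO2) can support
  cleavage, which is what `ablation_report()` formalizes.
* At desk-scale depths the decoy floor is granularity-limited (one read ≫
  10 tpm); decoy calibration is only informative at production depths.
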