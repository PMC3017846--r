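---
title: "Homology-based miRNA precursor discovery and target prediction with mircane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based miRNA precursor discovery and target prediction with mircane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircane)
library(dplyr)
```

## The problem

Conserved plant microRNAs can be discovered without sequencing small-RNA
libraries: because mature miRNAs are strongly conserved across species, an
EST or GSS collection from an un-sequenced genome can be mined by looking
for near-exact matches to known mature miRNAs and then asking whether the
surrounding sequence folds into a pre-miRNA-like stem-loop. mircane
implements that protocol end to end for the desk: a mismatch-tolerant scan
of a FASTA database against a mature-miRNA catalog, extraction of flanked
candidate windows, secondary-structure prediction, validation against nine
structural criteria, redundancy collapse of near-identical loci, and a
complementarity-scored target predictor. A synthetic-data generator
produces databases with known ground truth so the whole pipeline can be
tested exactly.

The package ships a catalog of 19 published sugarcane miRNA precursors
(`mircane_catalog()`, `mircane_mature_path()`) which serve both as default
scan drivers and as the default embeds of the generator.

## The homology scan

ESTs have arbitrary orientation, so both strands of every record are
scanned against every mature query (19–24 nt). A hit is any substring
within `max_edits` unit-cost edits of the query — substitutions plus
single-nucleotide indels, a 2-nt gap costing 2 — with overlapping hits of
one query and strand merged to the lowest edit total. The default budget
of 3 edits reflects the divergence observed between conserved mature
miRNAs across grasses; the nominal word size of 7 is retained as an
interface parameter, but the implementation simply runs the full
semi-global dynamic programme against every record (it is cheap at EST
scale), so results are exhaustive by construction rather than
seed-dependent.

Around each hit a window of `flank` nucleotides per side (default 300,
about 620 nt total) is cut and strand-resolved so the mature sequence
always reads 5'→3'. An optional exclusion screen removes windows whose
mature-spanning region matches a user-supplied collection of non-miRNA
RNAs (tRNA/rRNA/snoRNA mimics) under the same edit semantics.

## The folding model

The built-in folder is a base-pair-weighted Nussinov-style dynamic
programme over pseudoknot-free structures: the structure minimising
`E = Σ w(pair)` with `w(G:C) = −3`, `w(A:U) = −2`, `w(G:U) = −1` kcal/mol,
hairpin loops of at least `min_loop = 3` nt (the steric minimum), lone
pairs permitted, and a deterministic tie-break (at equal energy the
leftmost position pairs, with the smallest partner index). `N` never
pairs.

This is deliberately *not* a nearest-neighbour thermodynamic model: its
energies are systematically more negative than mfold/RNAfold values
because every pair contributes independently of stacking context.
Consequently the MFEI acceptance threshold of 0.65, calibrated on
thermodynamic folders, is generous under the built-in model (typical
accepted candidates here have MFEI well above 1). Two escape hatches
exist: externally computed structures can be supplied in Vienna
dot-bracket or CT connect format (`parse_vienna()`, `parse_ct()`), in
which case the file's energy is used verbatim; and the threshold itself is
configuration (`mfei_min`). When a folding run emits several structures,
only the first (optimal) one is read, and the parser says so.

MFEI is defined as `AMFE / GC%` with `AMFE = |MFE| / length × 100`; both
are reported as positive numbers, and both — like GC% and the minimum
stem-loop length — are computed on the *trimmed* stem-loop (see below),
not the raw 620-nt window.

## The nine validation criteria

A candidate window plus structure is evaluated against nine criteria; all
nine must pass:

1. a stem-loop forms with the mature sequence in a duplex;
2. the mature sequence lies within one arm;
3. the mature sequence sits on the same arm (5'/3') as its homolog, when
   the catalog records one;
4. the mature/star duplex has between 1 and 6 mismatches;
5. no break in the star sequence;
6. MFEI above 0.65, negative energy, and 30–70% G+C (bounds inclusive);
7. at most 2 consecutive duplex mismatches;
8. at least 2 base pairs beyond the duplex;
9. a trimmed stem-loop of at least 60 nt.

Several of these required interpretation, resolved as follows and exposed
as configuration so users can disagree:

**The star region and "no break" (criterion 5).** The star is the span of
partners of all paired mature positions; no Dicer 2-nt 3'-overhang
adjustment is applied by default (`star_overhang = 0`), since the
protocol's criteria never mention overhangs. "No break" is formalised as
a single antiparallel register: every paired mature position has
`position + partner` constant. Symmetric mismatches (both sides unpaired)
preserve the register; any bulge shifts it and fails. This is the only
reading consistent with criterion 4's *requirement* of at least one
mismatch: a reading in which any mismatch "breaks" the star would make
criteria 4 and 5 jointly unsatisfiable.

**Criterion 8.** Read literally ("a minimum of two bases pairing" in the
duplex), this criterion could never fail on its own: criterion 4 already
caps mismatches at 6, forcing at least 13 of 19–24 mature positions to
pair. A criterion that is implied by another carries no information, so
the package adopts the reading suggested by "after the alignment": the
stem must *continue* for at least `min_closing_pairs = 2` base pairs
beyond the mature/star duplex, anchoring the duplex inside a larger stem.
This is also what every real pre-miRNA looks like.

**Vacuous criteria.** Criteria 4, 5, 7 and 8 presuppose a well-defined
one-arm duplex. When criterion 1 or 2 fails there is no such duplex, and
these criteria are recorded as (vacuous) passes so that the report
pinpoints the actual defect; the verdict is reject regardless. This
scoping is what makes single-criterion knockout candidates possible for
every criterion — a property the test suite exercises.

**Trimming.** Published precursor lengths (94–411 nt) are far below the
620-nt search window, so composition statistics are computed on the
minimal stem-loop: the interval spanning mature, star and the loop
between them, extended outward while the enclosing stem continues
(bulge-free walk). Without a duplex the whole window is used as a
fallback. The walk stops at the first interruption of the closing stem; a
large bulge low in a real stem would truncate the trimmed region early —
a known, documented approximation.

Verdicts are monotone in the thresholds: relaxing any bound never turns
an accept into a reject (property-tested).

## Redundancy collapse and loci

The published protocol collapses ESTs sharing more than 95% identity into
one precursor, and targets sharing at least 95% into one gene. Identity
is global Needleman–Wunsch (match +1, mismatch −1, linear gap −2;
`Biostrings::pairwiseAlignment`), with identity = matches over alignment
length, computed over the trimmed precursor region (the published
protocol does not state the comparison span; the trimmed precursor is
the comparable one). Clustering is
single-linkage; representatives are the longest member, ties to the
lexicographically smallest id. The strict (`>`) and non-strict (`>=`)
threshold readings are both used by the protocol and both supported.

The pipeline adds one step before identity clustering: accepted
candidates whose windows overlap on the same database record are merged
into one genomic locus first. This is necessary, not cosmetic: a true
precursor produces a plus-strand hit at the mature arm *and* a
minus-strand hit at the star arm (the star is a near-reverse-complement
of the mature), and near-identical catalog entries produce additional
hits at the same coordinates. All describe one stem-loop, but a window
and its reverse complement are not sequence-identical, so identity
clustering alone would double-count every precursor.

## Target prediction

Messages are scanned sense-only. A 21-nt miRNA is divided 5'→3' into
blocks of 8, 3 and 10 nt with per-block mismatch caps of 2, 0 and 3; the
zero-tolerance block (positions 9–11) covers the canonical cleavage site
opposite the tenth miRNA nucleotide, which is what pins the block
numbering to the 5' end — the reverse reading would put the strictest
block over the miRNA 3' tail, where plant duplexes are most tolerant.
Non-21-mers keep blocks 1–2 fixed and absorb the difference in block 3.
G:U wobbles count as mismatches in this pre-filter (configurable); they
are only rewarded later.

Windows passing the pre-filter are rescored by a bulge-aware dynamic
programme over site regions shifted/resized by up to `max_bulges = 2` nt:
Watson–Crick pair 0, G:U wobble pair 0.5, non-G:U mismatch 1, each bulged
nucleotide 1.5. Note the wobble penalty attaches to the *pair*, distinct
from the bulged-nucleotide penalty. Two bulges alone already cost 3.0,
so with the acceptance cutoff of 3.5 points a third bulge can never
co-occur with any other defect — hence the default bulge budget of 2.
Sites scoring at most 3.5 are kept, near-duplicate hits at one locus are
merged, and transcripts at ≥95% identity collapse to one reported gene
target per family.

## The synthetic-data generator

The generator is the package's ground-truth instrument: it builds EST
collections in which every positive and negative is constructed, so
recovery can be asserted exactly (the default study conditions are 20
embedded precursors with 3 duplex mismatches each among 200 decoys, and
planted target sites with 0–2 wobbles/mismatches/bulges in 250-nt hosts).

Constructed precursors are `poly-A flank + poly-C stem + mature + CC +
poly-N loop + GG + star + poly-G stem + poly-A flank` (arms swapped for
3'-arm precursors), where the star is the reverse complement of the
mature with engineered substitutions. The restricted alphabets are not an
aesthetic choice. Under a pairing-maximising folding model, any flank or
loop base whose complement is reachable can substitute into the stem at
*equal* energy, and the deterministic tie-break then prefers the
rearranged structure; unrestricted flanks get silently rewired into the
stem. Poly-A flanks cannot pair the all-C/all-G closing stem, the
ambiguity-base loop pairs nothing at all (resembling a low-quality EST
stretch), and the fixed C:G adapter bracketing the loop blocks
rearrangement chains routed through the loop ends. Mismatch positions and
substitute bases are chosen so that no equal-weight one-off re-pairing
exists (substitutes must not pair their own column or the Watson–Crick
complements of neighbouring mature bases; mismatch positions must differ
from their neighbours; run boundaries must not pair across the run), and
every candidate design is finally *verified*: the window is folded and
the pairing map compared to the designed one, retrying alternative
placements deterministically. Verification is structural, not
verdict-based, so the validator's criterion accounting remains
independently tested.

Two honest infeasibilities follow from the model and are raised as
errors rather than worked around: natural matures rarely admit 6 rigid
mismatches (too few positions differ from both neighbours), and miRNAs
whose 3' tail repeats (e.g. a UU end) cannot host a planted bulge because
the bulged nucleotide can always realign off the site end at lower cost.
Boundary tests use crafted matures (period-3 composition) where these
constructions are exact.

What passing the synthetic suite does *not* show: recovery from real
ESTs with sequencing errors, chimeras, vector contamination, AU-rich
flanks that partially pair, or thermodynamically marginal hairpins. The
generator's decoys (uniform-random, GC-extreme, short-hairpin and
MITE-like terminal inverted repeats) probe the criteria, not EST
messiness.

## Numerical and reproducibility notes

* All coordinates are 1-based inclusive, in tibble output and internally.
* All randomness flows through R's RNG: `set.seed()` plus a generator
  seed reproduces databases byte-for-byte.
* Ties are broken deterministically everywhere (fold traceback, duplex
  traceback, hit merging, cluster representatives), so pipeline reruns
  are identical; every result object carries a hash of its resolved
  configuration.
* Problem sizes in the test suite: oracle-equivalence checks run at 1000
  random duplexes, 500 random sequences of length ≤ 30 against full
  enumeration, and 100 scan instances on databases up to 5 kb; the
  end-to-end run uses 20 embeds and 200 decoys. These sizes make the
  enumeration oracles exact yet keep a full test run in minutes.

## Known limitations

* The built-in energy model over-pairs relative to thermodynamic folders;
  MFEI values are not comparable to published thermodynamic MFEIs unless
  external structures are supplied.
* The trimming walk does not cross bulges in the closing stem.
* Clustering is all-pairs Needleman–Wunsch — appropriate for hundreds of
  candidates, not for collapsing whole EST databases.
* Homology-based discovery cannot find lineage-specific miRNAs absent
  from the catalog, and EST coverage truncates real precursors (the
  bundled catalog itself contains one precursor annotated by homology
  alone after its EST failed structural validation; the pipeline flags
  such cases as near-misses instead of special-casing them).
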