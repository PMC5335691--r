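---
title: "mitocomp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitocomp: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

This vignette is the package's own account of its methods: what is being
modelled, which tunable parameters matter, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The objects of study

A metazoan mitogenome is modelled as a circular molecule with an ordered
feature table: 13 protein-coding genes, 2 rRNAs, 22 tRNAs (the two leucine
and two serine tRNAs are distinct tokens: `trnL1` reads CUN, `trnL2` UUR,
`trnS1` AGN, `trnS2` UCN) and the control region `CR`, a landmark rather
than a gene. Coordinates are 1-based inclusive (GenBank convention);
features spanning the origin are expressed as `join(a..L,1..b)` and kept,
not rejected. The comparison baseline is the pancrustacean ground pattern —
the ancestral arrangement shared by crustaceans and hexapods — stored as a
package constant of 37 genes plus `CR`, with the classical minus-strand
block (`trnQ`, `trnC`, `trnY`, `trnF`, `nad5`, `trnH`, `nad4`, `nad4l`,
`trnP`, `nad1`, `trnL1`, `rrnL`, `trnV`, `rrnS`).

## 2. Signed circular gene orders

An arrangement is a circular sequence of strand-signed tokens. Because
records are annotated from arbitrary origins and either strand, equality is
decided on a canonical form: if the `cox1` anchor carries a minus sign the
whole order is mirrored (reversed, all signs flipped), then rotated so
`cox1` comes first. Every record in scope carries a single-copy `cox1`;
supernumerary copies of other genes are disambiguated by an ordinal suffix
in genome order. `CR` participates as a positional marker by default — the
field's verbal descriptions of rearrangements use it as a landmark — and
can be excluded (`include_cr = FALSE`).

**Breakpoint distance.** The number of signed adjacencies \((x, y)\),
identified with \((-y, -x)\), present in one order and absent from the
other. It is symmetric, zero exactly on canonical equality, and satisfies
the triangle inequality on a fixed token multiset (property-tested).

**Scenario inference.** Minimal-event inference for mixed translocations /
inversions is NP-hard, and the source analyses describe events
qualitatively. `infer_events()` therefore trades optimality for determinism
and replayability:

1. token-multiset differences become loss events (emitted first) and
   duplication events (emitted last — a copy can only be inserted next to
   its observed neighbour once the shared genes are in place; among copies
   of a duplicated token, the copy whose flanks match the reference worst
   is treated as the new one);
2. maximal runs of the derived order found strand-reversed in the
   reference become in-place (block) inversions;
3. otherwise, the single gene whose relocation to its observed context
   most reduces the breakpoint distance is moved (sign change en route =
   translocation+inversion), ties broken by leftmost position;
4. at a strict local optimum of the breakpoint count, one zero-cost
   reversal into a not-yet-visited configuration is taken (the classical
   escape in breakpoint-greedy reversal sorting) and the loop continues.

For small orders (≤ 12 tokens) a bounded exact breadth-first search over
single events (depth 3 up to 6 tokens, else 2) is run first, so toy-scale
scenarios are minimal whenever a short one exists. The heuristic's
*contract* is replay soundness — applying the returned events to the
reference must reproduce the derived canonical order — and that is what the
acceptance suite asserts over seeded random scripts; recovering the exact
generating script is explicitly not promised. Non-convergence raises an
error carrying the partial event list.

**Patterns and phylogeny.** Records with identical canonical orders form a
pattern; the class equal to the ground pattern is labelled `Gr`, others take
the label supplied by the study manifest or `P1, P2, …` assigned by
smallest member id (so the partition and labels are invariant to input
order). The pattern label is then treated as one unordered multistate
character on a rooted tree: the Fitch parsimony step count equals its
minimum, (number of distinct labels − 1), exactly when every derived
pattern arose once — the operational meaning of "consistent with the
phylogeny". Per-pattern exact-clade (monophyly) flags accompany the count;
an ancestral pattern such as `Gr`, or a pattern ancestral to a nested one
(`Ax1` with `Ax2` inside it in the bundled study fixture), is expected to
be paraphyletic without breaking consistency.

## 3. Codon usage under translation table 5

Counting reads non-overlapping triplets from position 1 of each
strand-resolved coding sequence. The unspecified "minor adjustments" of
standard practice are fixed as: drop a trailing partial codon (the
truncated-stop case), exclude a terminal complete TAA/TAG, skip and tally
codons containing N, and count TGA / AGA / AGG as the sense codons they are
in the invertebrate mitochondrial code (Trp, Ser). Internal stops are
warned about and excluded. That leaves exactly 62 sense codons.

**Synonymous families.** Under table 5 an undivided serine family would
have eight codons (UCN + AGN). The package follows the convention of
mitogenome RSCU analyses — which plot Ser1 and Ser2 separately, one per
tRNA — and splits serine into two four-codon families while keeping leucine
as one six-codon family. This yields 21 families of 2–6 codons, matching
the "two to six codons per amino acid" framing of the field. RSCU is
count / (family total / family size); zero-total families are flagged and
set to 0 rather than `NA` so 62-long profiles stay comparable.

**Group comparison.** Pearson chi-square per family on the groups × codons
table of pooled counts, df = (r−1)(c−1), no continuity correction, groups
with zero family total dropped with a warning, never-observed codon columns
dropped. Significance is flagged at α = 0.001 — the conventional reporting
threshold for these comparisons — with no multiple-testing correction
(raw per-amino-acid p-values are what the field reports); both choices are
arguments. Calibration under a shared multinomial and power under the
generator's planted biases are asserted in the acceptance suite; the power
criterion is the *joint* comparison across the pooled groups, the design
the method is meant for, not every pairwise contrast (two groups whose
planted biases differ by 0.04 are not reliably separable pairwise at these
sample sizes, and that is a property of the stated world, not a defect).

**Ordination.** Classical (Torgerson) MDS on Euclidean distances between
per-record RSCU profiles (all 13 protein-coding genes concatenated per
record): double-centre −½D², eigendecompose, scale eigenvectors by the
root eigenvalues. It is deterministic and exact for Euclidean input —
the reason it was chosen over stress-minimizing variants whose output
depends on starting configurations. Each axis is oriented so its
largest-magnitude coordinate is positive; requesting more axes than there
are positive eigenvalues pads with zeros and warns.

## 4. The synthetic-data generator

The generator emits the *stated world* the pipeline is tested in, emulating
the study design the package is built around:

| parameter | default | rationale |
|---|---|---|
| groups (taxa) | Axiidea 8, Gebiidea 5, Caridea 20, outgroup 12 | the study's sampling design |
| third-position AT bias | 0.88 / 0.84 / 0.68 / 0.75 | stronger bias in the mud-shrimp groups, weaker in true shrimps; whole-molecule AT lands in the reported high-50s–low-70s % |
| amino-acid usage | uniform over the 21 families | no composition is stated; uniform is the neutral choice |
| PCG length | 300 codons mean (±10%) | ~3,900 codons per record, the scale of a real 13-PCG set |
| tRNA / rRNA lengths | 68 / 800 / 1,300 bp | typical metazoan values |
| control region | 800 bp at 80% AT | "< 1,000 bp for all but one taxon", AT-rich |
| spacers | uniform 0–20 bp | intergenic regions are usually minimal |
| patterns | Gr, Pa, Ap1, Ap2, Up, Ax1, Ax2 scripts | executable stand-ins built from the study's verbal descriptions (single tRNA move; extra trnQ between nad4l and trnT; several tRNA moves; PCG relocation + strand-switching tRNA moves; plus a 4-gene block inversion and a trnD translocation+inversion in Ax2) — the figure rows themselves are not machine-readable, so these are synthetic, not transcriptions |

Records are laid out gene by gene with seeded spacers; minus-strand genes
are reverse-complemented into the molecule, so extraction round-trips
exactly. Planted defects operate purely at the annotation level (the
sequence is untouched), mirroring how the real database errors arose.
Everything derives from one seed: identical configuration ⇒ byte-identical
GenBank files, manifest, and tree.

What the generator does **not** emulate — and therefore what a green test
does not establish: real sequence evolution along the tree (records are
i.i.d. draws from group profiles; no substitution model, no rate
variation), tRNA/rRNA secondary structure (composition-matched random
strings suffice because no stage inspects structure), strand-asymmetric
composition skew, codon-position-specific amino-acid composition, and
partially overlapping real-world gene boundaries beyond what spacer
sampling produces. Tests on this fixture validate the *pipeline machinery*,
not any biological claim about real accessions.

## 5. Numerical and degenerate-input choices

* Coordinates failing to parse (`?` locations) give `NA` positions and a
  `missing-coordinates` anomaly rather than an exception; features beyond
  the declared length attach an `out-of-range` anomaly at parse time.
* `start > end` flags `inverted-coordinates` only on non-wrap-around
  features; origin-spanning features are legitimate on circular records.
  A planned strand-contradiction heuristic for rRNAs was dropped: genuine
  rearrangements relocate rRNAs between strands, and the documented
  database cases are coordinate inversions, which the first rule catches.
* A second `trnQ` is documented biology in these taxa: reported with
  severity `info`, below the `defect` level that drives the QC exit code.
* Overlapping genes yield negative spacers (not clamped), which keeps the
  identity "feature spans + spacers = molecule length" exact on circular
  records.
* Chi-square families with fewer than two non-zero rows or columns are
  marked not-computable instead of erroring, so one absent family never
  aborts a batch.
* MDS eigenvalues are thresholded at a 1e-12 relative tolerance when
  deciding positivity; coincident records map to coincident points.
* All randomness flows through R's RNG from a single integer seed; no seed
  exceeds 2^31.

## 6. Known limitations

* The event heuristic is not a rearrangement-distance method: event counts
  are upper bounds (within +2 of the single-event optimum at toy scale, by
  the brute-force acceptance suite) and should not be used as a
  phylogenetic distance. DCJ/inversion-distance sorting is explicitly out
  of scope.
* Ambiguous `tRNA-Leu`/`tRNA-Ser` labels without an anticodon qualifier
  cannot be assigned to L1/L2/S1/S2 and surface as `unknown-name` —
  re-annotation, not guessing, is the intended remedy.
* QC detects annotation defect classes; it does not re-annotate.
* The Fitch computation treats the supplied topology as rooted and ignores
  branch lengths; support values are not consulted.
* Per-gene codon usage, ENc/CAI-style indices, amino-acid usage and
  strand-skew statistics are out of scope.
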