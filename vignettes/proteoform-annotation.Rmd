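---
title: "Annotating proteoforms on a 2DE coordinate system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating proteoforms on a 2DE coordinate system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteogel)
```

## The model

A *proteoform* is one concrete protein product of a gene: a splice backbone,
optionally carrying single amino acid polymorphisms (SAPs), insertions or
deletions, and post-translational modifications (PTMs). Bottom-up mass
spectrometry observes tryptic peptides, and most peptides map to several
proteoforms of the same gene family, so identification is an inference
problem, not a lookup.

`proteogel` models the analysis in four layers.

**1. The sequence library.** Transcript-level expression evidence decides
which backbones enter the search space: a transcript is retained when it is
a reviewed entry, its FPKM exceeds 0.1 in at least two runs, and the
coefficient of variation (sample SD over mean, all runs) is at most 30 %.
Retained backbones are expanded combinatorially with their compatible
variant events. The default policy applies **each event alone** per
backbone. The combinatorics of applying all event subsets grows
multiplicatively (a single gene with nine backbones and seventeen events
would already produce thousands of sequences under a pairing policy, and
full closure is exponential), which both inflates the search space and
dilutes peptide specificity; the single-event default bounds the library at
`backbones × (1 + events)` while still representing every event. An opt-in
`paired` policy additionally combines one SAP with one indel. Event
coordinates are 1-based positions on the backbone's protein sequence;
within a combination, events are applied from the highest position
downward, so upstream indels never invalidate downstream coordinates.
Records with identical sequences are collapsed into one, keeping all
provenance identifiers — otherwise a peptide could be called "shared"
between two entries that are in fact the same molecule.

**2. Digestion and the peptide index.** Trypsin cleaves after K or R but
not before proline (the classic specificity rule; it is configurable off
since some search engines ignore it), with at most one missed cleavage, and
peptides outside 9–25 residues are discarded. Isoleucine and leucine are
isobaric, so peptide identity is defined on an I/L-collapsed key; an I↔L
substitution therefore yields zero proteotypic peptides *by construction*.
A peptide is **proteotypic** when its key maps to exactly one library
record, **gene-specific** when it maps to several records of one gene, and
**multi-gene shared** otherwise.

**3. Inference.** Observations are filtered at q ≤ 0.01 and 9–25 aa;
peptides mapping only to contaminant entries are excluded. Replicates are
merged by per-cell union of distinct keys; the overlap statistic is the
Jaccard index by default (an `intersection/min` variant is selectable —
published overlap figures rarely state their definition, so both are
reported rather than guessed). Per gel cell, a proteoform is identified
when at least two distinct peptides map to it and at least one is
proteotypic (the "singleton" relaxation of the classic two-unique-peptides
rule: one unique plus one or more shared peptides suffices). Remaining
evidence is aggregated into protein groups as connected components of the
proteoform–peptide bipartite graph, after removing peptides explained
exclusively by identified proteoforms; components whose members share one
gene are single-gene groups, the rest multi-gene. Proteoforms supported
only by shared peptides are never promoted. The procedure is deterministic
and order-independent, and adding observations can only add
identifications.

**4. Gel-coordinate annotation.** Theoretical coordinates are the average
molecular mass and the isoelectric point computed from the Bjellqvist pKa
set (residue-specific N-terminal pKa values, side-chain adjustments for
C-terminal Asp/Glu). The pI solves net charge = 0 by bisection; the
Henderson–Hasselbalch charge is strictly decreasing in pH, so the zero is
unique. Modifications act on the group inventory: phosphorylation adds an
acidic group (effective pKa 6.5, the second phosphate ionization — the
first, near pH 1, is irrelevant in the gel range), acetylation removes the
modified amine, C-terminal amidation removes the terminal carboxyl,
deamidation adds a carboxyl (pKa 4.05), methylation leaves charges
unchanged, and carbamidomethylation removes the cysteine thiol (cysteine is
otherwise treated as ionizable).

Each identified proteoform's observed cells (any cell holding at least one
of its peptides) are tested for concordance: the unmodified theoretical
point must fall inside the cell expanded by the tolerances. Near-boundary
hits that properly locate to an adjacent cell are flagged as boundary
artifacts rather than shifts. Discordant cells enter the shift-taxonomy
cascade; every matching rule is returned, ranked by evidence strength, so
the output is an auditable list of hypotheses rather than a verdict:

* **lighter → proteolysis** when the observed peptides are confinable to
  one contiguous fragment whose mass is compatible with the cell's MW
  window. Only an upper bound is enforced (span mass ≤ cell maximum ×
  (1 + `frag_tol`)): two peptides clustered at one terminus are exactly the
  fingerprint of a fragment, so requiring the span itself to reach the
  cell's mass would reject the most convincing cases. Terminal clustering
  raises the rank.
* **heavier → complex/oligomer** when an interaction partner is
  co-identified in the same cell and the monomer-mass sum falls in the
  cell's window (± `complex_tol`). Integer monomer multiples
  (homo-oligomers) are only invoked for records with a self-interaction in
  the partner table: with a ±20 % window, some multiple of almost any mass
  fits almost any cell, so a bare mass coincidence is no evidence at all.
* **acidic → acidic PTM** when phospho/deamidation was observed on the
  record's peptides in that cell (strong evidence), or when some k ≤
  `k_max` phosphates reproduce the cell's pI window (hypothesis, reported
  with k). Charge is position-independent, so the k-phosphate scan does not
  need site assignments.
* **basic → basic PTM** when amidation/methylation was observed, or when
  C-terminal amidation reproduces the cell's pI window.
* **heavier with no partner evidence → proline retardation** when the
  proline fraction exceeds 10 % (proline-rich chains run visibly heavier
  than their true mass); otherwise incomplete denaturation is noted as an
  unranked possibility.

No rule can fire against the sign of the shift. Subjects with at least one
concordant cell are `concordant`; fragment cells never create new
proteoform calls. Protein groups are resolved per cell: exactly one member
with concordant coordinates resolves the group; groups whose members differ
only by point substitutions are declared unresolvable by coordinates (a
one-residue change moves the coordinates far less than a cell's width).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_fpkm` | 0.1 | FPKM | expression-evidence threshold |
| `max_cv` | 0.30 | — | run-to-run reproducibility bound |
| `min_runs` | 2 | runs | threshold must hold in ≥ 2 of the runs |
| `max_q` | 0.01 | q-value | peptide FDR < 1 % |
| peptide length | 9–25 | aa | reliable identification window |
| `max_missed` | 1 | sites | tryptic missed-cleavage cap |
| `tol_pi` | 0.15 | pH | cell-expansion tolerance on pI |
| `tol_mw` | 0.15 | fraction | cell-expansion tolerance on MW |
| `complex_tol` | 0.20 | fraction | window for complex mass sums |
| `frag_tol` | 0.25 | fraction | window for fragment compatibility |
| `k_max` | 5 | phosphates | acidic-hypothesis search depth |
| `proline_threshold` | 0.10 | fraction | proline-retardation trigger |

The pI tolerance deserves a note. Gel columns are 0.25–1.1 pH units wide on
the example calibration; a tolerance of 0.2 would swallow shifts of almost
a full column, silently reclassifying genuinely displaced proteoforms —
including the canonical textbook case of a ~23 kDa heat-shock protein at pI
5.98 observed one column more acidic (pI 5.11–5.80) — as concordant. At
0.15 the point just outside a column still registers as shifted while
calibration scatter inside a column does not. All tolerances are plain
config values; none is load-bearing for correctness, only for sensitivity.

## The gel calibration

The grid must come from a calibration file; no universal grid is
hard-coded, because published per-cell bounds from real gels are not
mutually consistent with a single monotone row/column layout (cut gels are
calibrated cell by cell). The packaged example grid is a self-consistent
reconstruction anchored on four published cell bounds (E5 = pI 6.30–6.88 ×
40–52 kDa; C8 = pI 5.11–5.80; H2 = pI 8.90–10.00; H12 = 6–15 kDa), with pI
decreasing along columns, MW decreasing from row A to H, and half-open
lower-inclusive intervals so every in-range point maps to exactly one cell.
MW midpoints are geometric (gel migration is roughly log-linear in mass)
and MW shifts are measured in log2 space.

## The synthetic generator

`make_variant_tables()` and `simulate_gel_experiment()` produce inputs in
exactly the TSV dialects the pipeline consumes, plus complete ground truth.
Sequences are drawn with human-like amino-acid frequencies (so the pI/MW
cloud qualitatively resembles a real proteome); splice backbones delete an
internal exon-like block; SAP/indel events are placed in the prefix shared
by all backbones of the gene, so reference residues always match and every
event is compatible with every backbone. Expression triplets deliberately
span the filter boundaries (below-threshold, high-CV, and unreviewed
fractions of 8 % each). Defaults: 60 genes, 100–1,000 residues,
Poisson(0.7) splice/SAP/indel events per gene, detection probability 0.95,
replicate-overlap target 0.89, no noise peptides; injected event fractions
are 10 % phosphorylation, 10 % proteolysis, 6 % complex formation, 6 %
basic PTMs of the identifiable records. These are desk-scale stand-ins
chosen once to exercise every code path, not estimates of any real sample.

Injection mechanics matter for honest recovery metrics. An event only
enters the ground truth when it actually displaces the proteoform beyond
the annotation tolerance (a phosphorylation that leaves the protein in its
native cell is a no-op, not a recoverable event); candidates that cannot be
displaced by one mechanism stay available to the others. Complexes are
placed at the summed mass of a partner pair, and both members must sit
heavier than the target cell beyond tolerance. Replicate structure: each
detected (cell, peptide) pair appears in both replicates with probability
equal to the overlap target t and in exactly one replicate otherwise, which
makes the expected Jaccard overlap equal t while the union — what inference
consumes — is always the full detected set.

What the generator does **not** emulate: spectral noise and chimeric
spectra, chromatography, abundance-dependent detection, real PTM site
preferences, partial digestion beyond the missed-cleavage model, or gel
warping. Passing recovery tests therefore demonstrates the internal
consistency of the pipeline's rules on data satisfying its assumptions —
not performance on real spectra.

## Numerical choices and degenerate inputs

* pI bisection runs on pH ∈ [0, 14] to |charge| < 1e-4 (at most 200
  halvings); an all-acidic or all-basic inventory returns the interval
  edge. A property test checks the bisection against an exhaustive
  grid scan.
* Boundary convention everywhere is half-open, lower-inclusive; a point on
  a shared cell boundary deterministically belongs to the interval whose
  lower edge it touches.
* Sequence validation rejects the ambiguity codes B, J, O, U, X, Z with the
  offending position; empty sequences and zero-run expression records are
  hard errors.
* Duplicate proteoform identifiers are a hard error at FASTA write time;
  overlapping events within one combination are skipped with a warning.
* A missing partner table downgrades the complex rule (skipped with a
  notice), never an error.
* Simulated proteoforms whose coordinates fall outside the grid are placed
  at the nearest edge cell and flagged in the ground truth; they are
  excluded from recovery denominators.

## Design decisions that were genuinely open

* **Concordance is decided on the unmodified coordinates.** PTM-adjusted
  hypotheses are computed and carried in the result, but they feed the
  acidic/basic rules instead of silently absorbing shifted cells into
  "concordant" — an observed phospho-shifted cell should be *explained*,
  not hidden.
* **Overlap statistic** defaults to Jaccard with `intersection/min`
  selectable (the definition behind published percentages is usually
  unstated).
* **Protein groups as connected components** after removing evidence
  exclusive to identified proteoforms: reproduces the single-gene versus
  related-genes dichotomy deterministically.
* **N-terminal methionine is not clipped** and no maturation is modeled;
  the library is annotated as supplied.
* **Peptide-coverage criteria** for proteolysis (the contiguity/upper-bound
  rule above) are configurable and reported in the output evidence; no
  claim is made that they match any particular published coverage
  criterion.

## Limitations

* pI prediction is sequence-only; structure, bound ligands and
  hydrophobicity/SDS-binding effects are out of scope.
* The shift classifier returns ranked hypotheses with evidence, mirroring a
  manually curated workflow; it does not compute posterior probabilities.
* Search-engine scoring, protein-level FDR and quantitation are upstream or
  downstream of this package and deliberately excluded.
* Worked examples that require canonical sequences not bundled with the
  package need UniProt access to reproduce.
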