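---
title: "Methods: globin identification, promoter scanning, phenetics and heme-pocket geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: globin identification, promoter scanning, phenetics and heme-pocket geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rhizoglob implements a desk-scale, fully reproducible version of the
bioinformatic workflow used to characterize globin (Glb) genes in rhizobial
genome assemblies: candidate detection and family classification, upstream
regulatory-element scanning, gene-neighborhood mapping, phenogram
construction, and heme-pocket geometry on predicted structures. This
vignette records the models behind each stage, the tunable parameters and
their defaults, the design decisions taken where the original workflow
relied on manual steps or third-party servers, and what the synthetic-data
closures do and do not demonstrate.

## The biological setting

Bacterial globins fall into three evolutionary families. The M family
contains flavohemoglobins (fHb: an N-terminal globin domain fused to a
FAD-binding reductase domain, ~400 aa in rhizobia) and single-domain
globins (SDgb, ~141 aa). The S family contains globin-coupled sensors
(GCS: globin domain fused to a signal-transmitter domain, ~510 aa),
protoglobins and sensor single-domain globins. The T family contains the
truncated 2/2-fold hemoglobins (tHb, ~149 aa), subdivided into classes
1–3. The classifier's reference set holds one query per type, and the
myoglobin-fold pocket positions — proximal F8 (His in canonical globins),
distal E7, B10 and CD1 — anchor both the acceptance rule and the
structural geometry stage.

## Candidate detection and classification

`extract_orfs()` reports all maximal ORFs on both strands (starts ATG/GTG/
TTG, stops TAA/TAG/TGA, translation table 11, alternative starts read as
Met). Coordinates are 1-based and include the stop codon. The ORF-calling
rules are a package choice: the source workflow searched pre-annotated
databases and never stated one.

Candidates are scored against each reference with a Gotoh affine-gap
global alignment (BLOSUM62; gap open 10, extend 0.5; a gap run of length
$k$ costs $\mathrm{open} + k\cdot\mathrm{extend}$). Traceback ties prefer
diagonal over up over left, making alignments deterministic. Significance
uses a permutation Z:

$$ z = \frac{s_{\mathrm{obs}} - \mu_{\mathrm{null}}}{\sigma_{\mathrm{null}}}, $$

where the null scores come from `n_shuffles` (default 100, floor 50)
uniform residue permutations of the query. This replaces the
structure-profile Z of the original workflow, which depended on a remote
threading server; the acceptance threshold $z > 6$ is retained as the
default but exposed in `globin_thresholds()` because the two Z scales are
not the same. A self-match scores far above 6 (empirically 50–130 on the
packaged references) and random 150-mers center on 0, so the threshold
separates cleanly at these conditions.

A call is accepted iff all three criteria hold: length $\ge$ 100 aa
(`min_len_aa`; the "approximately 100" in the source rule is implemented
as a hard 100, configurable), $z >$ `z_threshold`, and His at the query
position aligned to the reference F8. Two refinements:

* **Architecture.** A single-domain M-family best match of length
  $\ge$ `t_fhb` (default 300 aa) is promoted to fHb; a single-domain
  S-family best match of length $\ge$ `t_gcs` (default 350 aa) to GCS.
  The thresholds sit between the single-domain (~141/149 aa) and fused
  (~400/510 aa) length regimes and are deliberately loose.
* **Glu at F8.** Some GCSs align Glu rather than His at F8, possibly an
  alignment artifact. The default (`accept_gcs_glu_f8 = TRUE`) accepts
  such GCS calls but flags them (`f8_artifact`); setting it FALSE rejects
  them like any other F8 failure.

Molecular masses use average residue masses plus one water. tHb classes
are inherited from the best-matching class-1/2/3 reference; there is no
separate class model.

## The reference set

The eight canonical reference queries are identified in the literature by
GenBank accession; an offline build cannot fetch them, so the package
ships a synthetic stand-in set (`reference_globins()`, and
`inst/extdata/reference_globins_synthetic.faa` — labelled synthetic) and
accepts user references via `read_reference_set()`. The stand-ins are
constructed, deterministically, to preserve what the pipeline actually
uses: one sequence per type with the family's architecture and length
regime; a shared 3/3 globin-domain template behind the M/S references and
an unrelated 2/2 template behind the T references (so M/S and T form two
dissimilar lineages, as real bacterial globins do); His at F8, Gln at E7
(3/3), Tyr at B10 and Phe at CD1 at known indices. Conclusions about real
rhizobial sequences require real references; every classifier property
tested here (self-acceptance, mutation-robust recovery, the F8 gate,
lineage segregation) is a property of the algorithms, exercised on these
stand-ins.

## Upstream element scanning

`upstream_region()` takes the 130 coding-strand nucleotides 5' of the
start codon (reverse-complemented for minus-strand genes; truncated with a
flag at scaffold edges). Position $-k$ is the $k$-th nucleotide upstream of
the A of ATG; whether the original table counted from the start codon or a
transcription start is not recorded, so the start-codon convention is
adopted and documented. Hits are printed "near to far" (e.g. `-36 to
-41`), with case coding: uppercase where the observed base matches the
consensus, lowercase otherwise.

The canonical -10 (TATAAT) and -35 (TTGACA) boxes and the 14-nt Fnr box
(TTTAAGAGGCCAAT) are matched full-length under a Hamming budget (defaults:
1 mismatch for -10/-35; 5 for Fnr, i.e. at least 9/14 identities, which
brackets the published Fnr-like hits). The Shine-Dalgarno element
(AGGAGG) uses maximal exact substring matching with a 3-nt floor, because
reported SD hits are routinely shorter than the consensus. The original
study located elements by manual text search and pairwise alignment; the
published -35 hits of varying width (4–9 nt) cannot be reproduced exactly
by any fixed full-length rule, and the package does not try to guess the
unrecorded procedure. All hits are reported (overlaps unmerged); the
fewest-mismatch, nearest hit is flagged primary.

With i.i.d. backgrounds the expected number of exact full-length Fnr
matches per 130-nt window is $(130-14+1)\cdot 4^{-14} \approx 4\times
10^{-7}$, so a zero count over $10^4$ random windows is the expected
outcome and is verified in the acceptance suite; 6-mers under a 1-mismatch
budget do produce sporadic background hits, which is why planted-motif
tests check positions and mismatch counts, not hit uniqueness.

## Gene neighborhoods

`flanking_genes()` lists genes whose nearest edge lies within `span`
(default exactly 5000 nt, for the "~5 kb" of the source) of the focal
gene's nearest edge. Distance is the edge-to-edge gap (0 when
overlapping) — the "~5 kb" anchor (edge versus start) was unrecorded, and
edge-to-edge keeps the neighbor relation symmetric. Upstream/downstream
are defined relative to the focal gene's strand. `tandem_array_check()`
reports same-type adjacent pairs within the span with no intervening
annotated gene; an empty result asserts the copies are not tandemly
arrayed. Product labels are tagged by case-insensitive keyword lists
(nitrate/nitrite, chemotaxis, transport, nif/fix/nos, transcriptional
regulator, hypothetical; untagged products become "other").

## Phenetics

Pairwise distances are $d = 100 - \mathrm{identity}$, with identity
defined as identical aligned pairs over columns where both sequences are
non-gap. That denominator is stable for the strongly length-heterogeneous
globins involved (fusions and 100+ residue extensions); the convention
used by the original alignment program is unrecorded, so the
shorter-sequence denominator is available as an option. Because co-optimal
global alignments of `(a, b)` and `(b, a)` can differ under any fixed
traceback tie-break, `percent_identity()` computes on the
lexicographically ordered pair, making identity exactly symmetric. No
multiple-hit correction is applied: the output is a phenogram, not a
phylogeny.

`upgma()` is the classic size-weighted agglomeration (merge height =
half the merge distance), with a deterministic tie-break: among
minimum-distance pairs, the lexicographically smallest pair of smallest-
member labels merges first. This hand-rolled implementation exists
because the published tie-break of generic average-linkage routines is
unspecified; tests cross-check its heights against `hclust(method =
"average")` and its cophenetic closure against ape. The result is
ultrametric by construction (verified to $10^{-9}$).

`progressive_msa()` aligns profiles bottom-up along the UPGMA guide tree,
scoring column pairs as frequency-weighted mean substitution scores with
the same gap model; two sequences reduce exactly to the pairwise
alignment, and degapping any row returns its input sequence.
`domain_split_identity()` locates the globin-domain boundary of fHb/GCS
pairs by a fitting alignment (free query end gaps) of the single-domain
reference inside each multidomain query, then reports per-segment
identities; the globin segment of a pair built with planted asymmetric
divergence scores higher identity than the fused segment, mirroring the
greater conservation of globin domains.

## Heme-pocket geometry

`parse_structure()` reads fixed-column ATOM/HETATM records (rejecting
malformed records with their line number), requires a heme group
(HEM/HEC/HEB) with exactly one Fe, and `pocket_geometry()` reports, per
mapped role: the probe-atom distance to Fe and the side-chain
$\chi_1$ (N–CA–CB–first $\gamma$ atom, IUPAC sign, in $(-180, 180]$).
Default probe atoms are His NE2, Gln NE2, Asn ND2, Tyr OH, Phe CZ, else
the side-chain heavy atom nearest the Fe (the original measurement tool's
atom choice is unrecorded; the default is documented, not asserted as
theirs). Coordination: hexa if the distal probe is within
`coordination_cutoff` (default 3.0 Å — the source inferred coordination
qualitatively from distance ranges without stating a cutoff), penta if
only the proximal probe is, otherwise indeterminate.
`kabsch_superpose()` is the closed-form SVD solution with the
determinant correction, so the rotation is always proper.

The synthetic pocket generator plants exact geometry: probe atoms sit on
coordinate axes at the requested distances (so the 3-decimal PDB columns
preserve them exactly) and $\chi_1$ is built by internal-coordinate
construction; closure tests demand $10^{-3}$ Å and 0.1°, and rigid-motion
invariance to $10^{-9}$.

## The synthetic-data generator

`generate_genome()` emits i.i.d. background nucleotides at a requested GC
fraction, embeds each planted globin as ATG + back-translated (optionally
mutated) reference + TAA with an in-frame TAA guard immediately upstream
— so the maximal ORF starts exactly at the planted start codon, keeping
truth coordinates exact — plants upstream elements at stated offsets with
exactly the stated mismatch counts, places neighbor ORFs at signed
edge-to-edge distances, and writes a flat truth table alongside FASTA/
GFF3. Back-translation uses one fixed codon per residue (the most common
enterobacterial codon under table 11), so it is deterministic and
invertible. Mutation substitutes each position independently at the
stated rate (uniform over the other 19 residues), with F8 protected by
default so truth labels stay valid. Offsets $-1..-3$ are reserved for the
stop guard. Everything is a pure function of the spec and seed; the same
spec and seed yield byte-identical files.

What the generator does **not** emulate: realistic codon usage or GC
skew, operon structure, repeat families, phylogenetically correlated
divergence, insertions/deletions during mutation, or sequencing error.
Closed-loop passes therefore demonstrate algorithmic correctness
(coordinates, offsets, scores, trees, geometry) under controlled
conditions — not recovery performance on real assemblies.

## Problem sizes and numerical choices

The packaged study conditions are: classifier recovery on 8 references ×
50 replicates at 10% substitution; permutation nulls of 100 shuffles
(floor 50); motif closures on 200 planted windows plus $10^4$ background
windows; UPGMA closures on 100 random matrices of 4–8 taxa; lineage
segregation on 3 mutated copies of each reference; and an end-to-end
cohort of four genomes. These sizes give stable statistics (e.g. the
recovery proportion has a binomial standard error below 1.1 percentage
points at $n = 400$) while keeping a full run in minutes on one core.
Degenerate cases are handled explicitly: a zero-variance permutation null
reports $z = +\infty$ with a warning flag; collinear dihedrals return NA
with a warning; sub-consensus windows scan to an empty hit list; UPGMA
requires $n \ge 2$; Kabsch requires 3 non-collinear pairs. The pipeline
report omits timestamps so that identical configuration and seed yield
byte-identical output files.

## Known limitations

* The permutation Z is not the structure-profile Z it replaces; its
  `z_threshold` should be recalibrated if real references with weak
  homology are used.
* Full-length Hamming matching cannot reproduce published variable-width
  -35 hits; positions near those hits can be recovered but the exact
  printed ranges were produced by an unrecorded manual rule.
* The progressive MSA is a straightforward profile aligner without
  iterative refinement; it is adequate for position mapping and guide-tree
  construction, not a replacement for a production MSA tool.
* Classification requires the globin domain at the N-terminus for
  architecture refinement, which matches fHb/GCS but would mislabel
  C-terminal fusions.
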