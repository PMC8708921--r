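---
title: "Methods: discovering establishment-gene regulatory islands"
author: "egers authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering establishment-gene regulatory islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egers)
```

## The biological problem

After conjugative transfer, a plasmid arrives in the recipient cell as
single-stranded DNA and must immediately (i) be converted to duplex DNA and
(ii) neutralise host defences such as restriction–modification systems.
The genes doing this — establishment genes, including the anti-restriction
gene *ardC* — are expressed rapidly and transiently, and on the pLS20
family of *Bacillus* conjugative plasmids they sit in several operons
behind conserved upstream regions (EGeRS, establishment gene regulatory
sequences). Two regulatory architectures occur: a long GC-rich,
inverted-repeat-rich region with no constitutive promoter (type 1), and a
strong σ^A^ promoter flanked by dual-heptamer operators
(`TTATCCC-nn-TTATCCC`) bound by the Reg repressor (type 2). This package
implements the comparative pipeline that finds these regions, classifies
them, and assembles the regulons they control.

## Island discovery by self-comparison

The discovery stage is a dot plot made algorithmic. All exact k-mer
matches between distinct plasmid positions (default `k = 12`) are the
seeds; on a circular record the scan runs over the doubled sequence so
islands spanning the replication origin are found, and the duplicated
representations are collapsed afterwards. For every seeded dot-plot
diagonal the two sequences are compared position by position, scoring a
match `+1` and a mismatch `-q/(100-q)` where `q` is the identity floor
(default 60 %, the cross-plasmid similarity criterion used throughout);
with this penalty a segment has non-negative score exactly when its
identity is at least `q`, so the recursively maximal positive segments are
the maximal intervals sustaining the floor. This is the boundary rule:
islands are trimmed to the maximal run that still meets the identity
criterion. Verified fragments within `max(250, 2*gap_tol)` bp of each
other on both axes are chained into one locus pair, which is what keeps an
internally duplicated copy (the ~131 bp tandem duplication seen in one
pLS20-style island) in one piece even though the duplication shifts the
dot-plot diagonal. Locus pairs are merged into islands by reciprocal
overlap (≥ 0.5) and grouped by single linkage; a group needs at least two
loci. Inverted-orientation matches are detected with the same machinery
against the reverse complement but reported separately and never grouped —
the biological islands are co-oriented with their operons.

Sensitivity at the bottom of the 62–95 % identity band comes from the
verification step, not the seeds: a single 12-mer seed anywhere in a
600 bp pair is enough to trigger the full diagonal scan, and at 62 %
identity the expected seed count per partner pair is still above one for
island-length regions, with single linkage across five copies providing
further redundancy.

### Two identity statistics

The paper-facing identity (`alignment_result$identity`) counts matches
over all alignment columns after trimming terminal gaps; internal gap
columns count as mismatches. Grouping and the island identity matrix,
however, use matched-column identity (`identity_ungapped`): matches over
columns where both rows carry a base. The reason is the internal
duplication: under the gap-counting statistic a copy carrying a 140 bp
insertion drops ~20 identity points against its sisters and would fall
out of the very group that defines it, while the matched-column statistic
keeps it inside the printed 62–95 % band. Both numbers are reported.

## Island characterisation

* **GC anomaly.** The null is the sliding-window GC distribution of the
  host plasmid (500 bp windows, 100 bp step), with all candidate islands
  excluded from the background; the island's z-score is
  `(GC_island - mean)/sd` of that distribution. The windowed null is this
  package's construction — only the pooled contrast (51.4 % islands vs
  37.7 % backbone) is available as an external anchor.
* **Inverted repeats.** `find_inverted_repeats()` enumerates every
  maximal inverted repeat: arms reverse-complementary within a mismatch
  budget (default 1), loop up to 150 bp, arm at least 8 bp; maximal means
  the arms can be extended neither outward nor inward within the budget.
  The enumeration is exact (every candidate is anchored at its innermost
  arm pair, and greedy outward growth is optimal for contiguous arms) and
  is cross-checked against a brute-force oracle in the tests.
* **Stem score.** `stem_score()` is a Nussinov-style maximum count of
  nested Watson–Crick pairs with minimum loop 3. It is deliberately a
  base-pair count, not an energy: thermodynamic folding of the islands is
  out of scope, and this proxy only orders sequences by structure
  richness. The recursion is cubic, hence the 5 kb guard.
* **Motifs.** `scan_motif()` does mismatch-budgeted IUPAC matching; `N`
  in a pattern is free, `N` in the sequence never matches. σ^A^ promoters
  are called by pairing a −35 `TTGACA` match with a −10 `TATAAT` match at
  a 16–19 bp spacer with at most 3 total mismatches — a mismatch-count
  model, because no promoter training set exists for these plasmids. The
  ribosome-binding-site consensus is `AGGAGG` with ≤ 1 mismatch; the
  source material never states which RBS consensus it used, so this
  documented choice is the package's own.

## Classification and regulon assembly

Evidence is computed on the island ± 100 bp, oriented along the strand of
the nearest downstream gene. The rule, in order: **type 2** requires a
dual motif within 30 bp upstream of a promoter's −35 box (or downstream
of its −10); **type 1** requires GC z ≥ 2, at least 3 inverted repeats,
and no qualifying promoter; anything else is **unclassified**, never a
guess. A "qualifying" promoter — the one that disqualifies type 1 — is a
near-consensus call with at most 1 total mismatch. A looser bar (≤ 3
mismatches) was considered and rejected: in a GC-rich 700 bp window the
expected number of chance ≤ 3-mismatch promoter pairings is above one, so
it would disqualify most genuine type-1 islands by noise alone, while a
≤ 1-mismatch promoter arises by chance in well under 1 % of islands. The
promoter *scan* itself still reports calls up to 3 mismatches, because the
type-2 rule is protected by the additional operator-adjacency requirement.

Operons extend downstream from the anchor gene while genes stay
co-directional and intergenic gaps stay within 150 bp — a configurable
choice that reproduces the printed establishment operons on the toy
fixtures; islands pair only with operons transcribed away from them, and
a gene whose start lies up to 30 bp inside the discovered island 3' end
still counts as downstream, absorbing discovery-boundary fuzziness (the
shared RBS can extend a matched diagonal a few bases into the first
codon).

## Protein clustering

All-vs-all Smith–Waterman under BLOSUM62 (gap open 11, extend 1) through
Biostrings; bitscores and e-values from the Karlin–Altschul formula with
λ = 0.267, K = 0.041 and search space `m·n`. These e-values are documented
approximations of BLAST's — cluster membership, not e-value equality, is
the downstream quantity. An edge requires coverage ≥ 75 % **on both
sequences** (the stricter reading, which prevents domain-only chaining)
and e ≤ 1e-10; clusters are connected components (single linkage), the
common behaviour of the COG/OMCL-style tools these thresholds come from.

## Island phylogenetics

Islands are aligned progressively (shared k-mer guide distances,
profile–profile Needleman–Wunsch with +1/−1 expected-match scoring and a
linear gap penalty of 2; deterministic tie-breaks: diagonal, then up, then
left). Distances are Kimura two-parameter,
`d = -½ ln((1-2P-Q)√(1-2Q))`, with gap/N columns pairwise-deleted and
saturated pairs capped at 5 substitutions/site (flagged). Trees are
canonical neighbor joining (via ape, negative branch estimates clamped to
zero with a message), with nonparametric bootstrap (column resampling,
K2P + NJ per replicate, bipartition percentages as node labels) and
midpoint rooting. Maximum-likelihood inference with rate heterogeneity is
deliberately out of scope: the distance tree is validated structurally —
additive matrices are reproduced exactly, and synthetic two-clade panels
(5 % within, 30 % between divergence) give ≥ 95 % support for the central
split — not by matching a published likelihood. No alignment trimming is
applied before distance computation; columns are kept as aligned.

## The synthetic generator

`generate_plasmid()` emits the study conditions: a circular 60 kb backbone
drawn i.i.d. at GC 0.377; five copies of a 400–750 bp island ancestor
drawn at GC 0.514 with four planted inverted repeats (arms 10–25 bp);
per-copy divergence drawn so pairwise identities fall in the 62–95 % band
(substitutions only by default — an indel mode exists but is off, so
planted identities stay controllable within ±3 points); one copy carries
a 131 bp internal tandem duplication plus 9 extra bp; type-2 copies are
overwritten near their 3' end with a perfect dual-motif/promoter cassette;
every island is followed by an `AGGAGG` RBS and a co-directional operon of
2–6 ORFs (80–250 aa), plus a few unrelated decoy genes; placements are
non-overlapping with ≥ 400 bp margins. Codon choice in the ORFs is
weighted by the backbone base composition rather than uniform over sense
codons: uniform codons would put every coding region at ~50 % GC and wreck
the very GC contrast (37.7 vs 51.4 %) the generator exists to emulate.
The realized whole-plasmid GC therefore sits slightly above the backbone
value (≈ 38–39 %), since even weighted codons cannot be fully AT-matched.
`generate_family_panel()` builds the clade-style protein panels: every
plasmid carries one 70–90 %-identity member of each universal family (the
ardC/reg pattern), a draw from partially shared accessory families, and a
couple of unique proteins.

What the generator does **not** emulate: real codon bias and amino-acid
composition, insertion-sequence scars, gene overlap, multi-contig
assemblies, and indel-rich divergence between island copies. Passing the
recovery suites therefore demonstrates correctness of the algorithms under
the stated statistical structure, not performance on arbitrary real
plasmids; the published accessions remain the external check where those
records are available.

## Numerical choices and degenerate inputs

* Alignment scoring: match +2, mismatch −2, gap open 10, extend 0.5; `N`
  scores as a mismatch against everything including `N`.
* Records shorter than `2*min_len` return an empty island set with a
  warning, not an error; all-N sequences make `gc_content()` fail loudly.
* Ambiguity codes other than `N` are rejected at read time.
* Problem sizes in the tests and the acceptance script — 20 plasmids of
  60 kb for recovery, 100 random instances per oracle comparison, 200
  bootstrap replicates for the clan-separation check — are the package's
  chosen verification scales, large enough for the thresholds they feed
  (recall/precision/accuracy ≥ 0.95) to be stable across seeds.

## Known limitations

Multi-record assemblies and contig stitching are unsupported (annotations
or synthetic input are required); e-values are not BLAST-equal by design;
the progressive aligner is a simple profile merger, adequate for
island-scale homologous sequences but not a general MSA tool; and the
boundary definition behind any externally printed island sizes is
validated only to ~10 %, since the exact trimming convention behind such
figures is not recoverable.
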