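---
title: "Mapping disease-associated complement mutations onto protein structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disease-associated complement mutations onto protein structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrmap)
```

## The scientific problem

Defective regulation of the complement alternative pathway (AP) underlies
atypical haemolytic uraemic syndrome (aHUS), age-related macular degeneration
(AMD) and several deficiency states. Four proteins carry most of the known
disease-associated genetic alterations: the fluid-phase regulator factor H
(CFH, 1231 aa, twenty SCR domains), the protease factor I (CFI, 583 aa,
five domains), the membrane regulator MCP/CD46 (392 aa, four SCR domains
plus membrane regions) and the central component C3 (1663 aa, thirteen
domains). `scrmap` implements the analysis pipeline for such registries:

1. parse and validate curated mutation tables (HGVS protein-change tokens,
   Met-1 numbering);
2. assign every positioned mutation to a domain and tally by consequence,
   domain and disease;
3. project SCR-domain missense mutations onto a consensus SCR numbering and
   partition them into hypervariable-loop, cysteine-anchor and other
   positions;
4. superpose domain coordinate sets on their conserved anchors, compute
   side-chain solvent accessibility, and classify mutated residues as buried
   or exposed;
5. rank per-domain mutational frequencies (hotspots) and predict Type I/II
   phenotype classes heuristically.

## Numbering and counting conventions

All residue positions are 1-based from the initiator methionine, following
HGVS practice; the signal peptide is counted, never subtracted. A record is
*intronic* when its consequence is `intronic` or it is a splice change
without a residue-level protein annotation; everything else is non-intronic.
The *non-intronic mutational frequency* of a region is
`100 * count / length` where the count covers non-intronic records with a
position inside the region, and the length is the number of residues in the
region (for a set of domains, the union of their spans -- inter-domain
linkers are not counted). Printed integers round half away from zero; this
convention reproduces the published values (e.g. 161/1231 -> 13.08 -> 13 and
55/124 -> 44.35 -> 44 for CFH SCR-19/20).

Where the source counts disagree internally, both facts are preserved
rather than silently editing either: the CFI registry carries its stated 64
records, two of which are consequence-`unclassified` so that the eleven named
categories still sum to the printed 62; the MCP fixture follows the running
text (43 non-intronic) over the figure caption (41); CFH keeps 113 missense
of which 107 lie in SCR domains, one in an inter-SCR linker and five in the
signal peptide.

## The consensus SCR model

SCR (sushi/CCP) domains are ~61-residue beta-sandwich modules with four
invariant cysteines (disulphides C1-C3 and C2-C4) and a conserved
tryptophan. The packaged 124-member alignment fixes the canonical geometry:
Cys anchors at consensus positions 1, 26, 39 and 49, and the hypervariable
loop at positions 11-15. The consensus residue at a position is the
per-column majority (gaps ignored, ties broken by amino-acid alphabetical
order so the result is deterministic and member-order invariant). Columns
before the first cysteine and sparsely occupied insertion columns fall
outside the consensus; a residue in an insertion column maps to the nearest
preceding consensus position, so mapping is monotone and is the identity in
the absence of insertions. When a mutation falls on both a Cys anchor and
the loop interval (possible only in synthetic alignments), the anchor label
wins.

The exact membership of the published 124-sequence and 27-structure sets is
not enumerated in the source, so the packaged alignment is a synthetic
stand-in (flagged `_synthetic` in its filename): its 24 coordinate-bearing
members correspond to the 20 CFH and 4 MCP domains and carry true protein
spans, while 100 library members pin down the majority consensus.

## Structure, accessibility and burial

* **Superposition** is the closed-form least-squares (Kabsch) fit over
  anchor C-alpha atoms -- by default the four Cys plus the conserved Trp; a
  domain lacking the Trp simply uses the four Cys. A proper rotation
  (det +1) is enforced via the sign-corrected SVD, so reflections are never
  returned; fewer than three or collinear anchors raise a geometry error.
* **SASA** is rolling-probe Shrake-Rupley quadrature: each heavy atom is
  inflated by the probe radius (1.4 A) and sampled with a deterministic
  golden-spiral layout (960 points by default; results are seed-free). Van
  der Waals radii are C 1.70, N 1.55, O 1.52, S 1.80 A; hydrogens are
  ignored, as crystal structures lack them. On the analytic one- and
  two-sphere fixtures the default quadrature is accurate to well under 2%.
* **Relative side-chain accessibility** divides the side-chain SASA by the
  residue-type theoretical maximum (Tien et al. values, shipped as a code
  table), caps at 100%, and bins in deciles 0-9 (`floor(pct/10)`). Glycine
  uses its C-alpha as the side-chain proxy. *Buried* means bin <= 2 by
  default, matching the reported burial proportions; the stricter bin <= 1
  convention used in some figure captions is available via `threshold_bin`.
  The original analysis used DSSP accessibilities; this package computes
  SASA directly, so individual residues near a bin boundary may be assigned
  differently -- burial summaries should be read with roughly one residue's
  reclassification of slack.
* **Unresolved residues** (disordered in the crystal) carry no accessibility
  value; burial summaries exclude them from the denominator and report them
  in a separate `unresolved` count, mirroring quoted denominators such as
  "19 out of 48".

## Hotspots and phenotype classes

Hotspot identification is the descriptive ranking of domains by non-intronic
mutations per 100 residues, exactly as the registry analysis does; an exact
one-sided binomial enrichment p-value (`enrichment_p = TRUE`) is available
as an extension beyond that analysis. Type I (low plasma level; misfolding
or secretion defect) is predicted for mutations that remove a cysteine or
strike a buried side chain; Type II (normal level, functional defect) for
exposed side chains; mutations without structural coverage are `unknown`.
The prediction is a "-like" heuristic and never overrides a curated
phenotype annotation.

## Synthetic data and what tests do (and do not) show

The seeded generators emit, beside every dataset, its exact ground truth:

* `gen_mutation_table()` -- per-domain and per-consequence counts recorded
  as the rows are drawn (defaults: consequence mixture 0.7 missense / 0.1
  nonsense / 0.1 silent / 0.1 intronic; per-domain rates proportional to
  domain length, i.e. a uniform positional null);
* `gen_scr_decoys()` -- true rotation/translation per decoy (rotations
  uniform over SO(3), translations uniform in +/-20 A, Gaussian coordinate
  noise with configurable sigma);
* `gen_alignment_fixture()` -- true consensus and the exact
  residue-to-consensus map under random substitutions and insertions.

All randomness flows through R's seeded Mersenne-Twister stream; the
analysis path itself is fully deterministic, so identical inputs give
byte-identical JSON reports. The synthetic decoys use an idealised
serpentine SCR-like template (`scr_template()`): it has the right anchor
residues and realistic atom counts but is not a physical fold, so passing
structural tests demonstrates the correctness of the geometry and SASA
code, not agreement with experimental accessibility patterns. Likewise the
packaged registry is a reconstruction that reproduces every published
marginal while its individual synthetic rows (beyond the literature-named
mutations) are not real patient alleles. Burial proportions against the
experimental CFI, C3 and MCP crystal structures require the corresponding
PDB coordinate files, which are too large to package: place `2xrc.pdb`,
`2a73.pdb` and `3o8e.pdb` under `inst/extdata/pdb/` to activate that check.

Problem sizes used by the test-suite properties were chosen to give stable
statistics at interactive runtimes: 1000 seeded registries of 30 records for
the partition invariants, 200 runs of 50 mutations for planted-hotspot
recovery (a x3 enrichment must rank first in at least 95% of runs), and
100-150 decoys for the noise calibration of superposition RMSD, whose mean
is checked against the degrees-of-freedom expectation
`sigma * sqrt(3 - 6/N)` for `N` anchor pairs.

## Known limitations

* No de novo multiple sequence alignment, secondary-structure assignment or
  homology modelling: alignments, strand labels and coordinates are inputs.
* Nucleotide-level `c.` strings are carried but not validated against a
  reference transcript.
* The SASA normalisation differs in detail from DSSP; burial percentages are
  reproducible to about one residue's reclassification, not bit-exactly.
* Hotspot ranking is descriptive; the binomial p-value ignores the
  registry's ascertainment bias and should be treated as a screen.

## A worked example

```{r example, eval = FALSE}
defs <- complement_proteins()
reg <- complement_registry()

cfh <- reg[reg$protein == "CFH", ]
nonintronic_frequency(cfh, defs$CFH)$rounded           # 13 per 100 residues
nonintronic_frequency(cfh, defs$CFH$domains[c("SCR-19", "SCR-20")])$rounded
                                                       # 44: the C-terminal hotspot
aln <- complement_scr_alignment()
mapped <- map_mutations_to_consensus(reg, aln)
region_tally(mapped$consensus_pos[!is.na(mapped$consensus_pos)],
             anchors = aln$anchor_positions)
# 129 mapped: loop 25 (19%), Cys 23 (18%), other 81 (63%)
```
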