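---
title: "Methods: evolutionary-era analysis of coenzyme binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary-era analysis of coenzyme binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coenzera)
```

## The question and the model

About half of extant enzymes depend on cofactors, and many organic
coenzymes (ATP, NAD, FAD, SAM, CoA, heme, ...) are thought to predate the
full 20-letter amino acid alphabet: meta-analyses of prebiotic chemistry
converge on an "early" set of roughly ten residues (Ala, Asp, Glu, Gly,
Ile, Leu, Pro, Ser, Thr, Val), with the remaining ten attributed to later
biosynthesis. If peptides built from early residues could already bind
coenzymes, coenzyme-peptide functional hubs could precede ribosomal
protein synthesis. `coenzera` operationalises this question as a
statistical survey of residue-level coenzyme contacts across protein
structure databases:

1. **Registry.** Coenzyme classes carry a *temporality* — Ancient
   (prebiotically plausible, with a nucleotide-derived subcategory), LUCA
   (universal but without established prebiotic synthesis), Post-LUCA
   (restricted to some domains of life), or Unclassified (Thiamine
   diphosphate, Coenzyme M, Factor F430, Glutathione) — plus chemical
   flags (phosphate content) and member ligand codes. Amino acids carry
   an era (early/late) and a chronology rank used only for display
   ordering. These tables are *data*, shipped as an editable YAML file;
   the package curates no chemistry itself.
2. **Consensus sites.** Contacts are lifted to UniProt coordinates
   through SIFTS-style residue cross-references, so that structures with
   different author numbering agree on a common key. For each (protein,
   coenzyme class) pair the *interaction ratio* of a residue is the
   fraction of that protein's bound structures in which the residue
   contacts the class; residues at or above 50% form the consensus
   binding site.
3. **Statistics.** Early/late composition per temporality (raw,
   background-normalized, and excluding phosphate-containing classes),
   per-residue fractional differences, backbone/side-chain binding modes,
   nine-way grouped interaction types, metal-ion mediation,
   secondary-structure content, ECOD X-group fold diversity, and sites
   bound exclusively by one era with conservation summaries.

## Key definitions and conventions

* **Interaction ratio.** `ratio = k / n` where `n` is the number of
  distinct structures of the protein with at least one mapped residue
  contact to the class and `k` the number of those structures in which
  the residue participates (presence is the OR over ligand copies).  The
  threshold comparison is performed on exact rationals (the threshold is
  converted to a continued-fraction approximation and compared by integer
  cross-multiplication), so a tie such as 2/4 against 0.5 is never
  decided by floating-point noise.  The published description of the rule
  uses both "at least 50%" and "more than 50%"; the package defaults to
  the inclusive reading (`ratio_inclusive = TRUE`) and exposes the strict
  one as a flag.
* **Binding modes.** A residue's contacting atoms are aggregated across
  all of its structures; the mode is `backbone_only` if the union is a
  subset of {N, C, CA, O}, `sidechain_only` if disjoint from it, `both`
  otherwise. Modes classify residues, not structure-specific events.
* **Grouped interaction types.** Raw contact labels collapse into nine
  groups (covalent; electrostatic = ionic/hbond/weak_hbond/polar/
  weak_polar/xbond/carbonyl; amide; vdw; hydrophobic; aromatic incl.
  ring-geometry labels; atom-pi; metal; clashes). Records whose only
  group is clashes are excluded from all statistics, as they mostly
  reflect refinement artefacts. A residue's group set is the union over
  its contacts; in `type_distribution()` a residue contributes once to
  *each* group it exhibits (the single-count "dominant" unit is provided
  as an option, since the counting unit of the original figure is not
  stated).
* **Metal mediation.** The contact schema records, for every bound
  coenzyme molecule, its partner entities: protein residue atoms, waters
  (dropped on ingest), and metal ions. A site counts as metal-mediated
  when a metal-ion partner shares a (structure, ligand, copy) bound
  environment with the site's residue contacts. This environment rule is
  our resolution of an underdetermined association (nothing in the
  source data links a metal to one specific coenzyme when several are
  bound); it is set semantics per site, multiset per element tally.
* **Sequence redundancy.** Greedy longest-first clustering joins a
  sequence to the first representative at or above the identity
  threshold (default 0.90, the primary analysis setting; 0.30 is the
  common secondary setting). Identity is exact matches over the best
  ungapped, k-mer-seeded alignment divided by the length of the shorter
  sequence — a deliberate, documented approximation of the external
  clustering tool's global identity. The package requires agreement with
  a brute-force all-pairs oracle on small inputs, not bit-compatibility
  with the external tool.
* **Secondary structure.** Codes are collapsed to {h, b, c} (DSSP-style
  letters map H/G/I to h, E/B to b, the rest to c). Redundancy is
  removed per residue: the profile of a UniProt position is the *set* of
  codes observed across structures, and content statistics count
  (residue, code) pairs, so a residue seen as both helix and coil
  contributes to both bins. The dataset-wide background covers all
  mapped residues of the analysed proteins, not only site residues (the
  alternative — all of the source database — is not computable from the
  inputs).
* **Exclusive sites.** Sites with at least two residues, all of one era.
  The two-residue filter removes trivial single-contact cases.
* **Fractional difference (FD).** For residue *i* between temporalities
  A and B, `FD_i = p_i(A) − p_i(B)` in percentage points of the
  per-amino-acid site composition. The source analysis never prints its
  FD formula; the percentage-point reading is consistent with the
  magnitudes it reports and is flagged as an interpretation. FDs are
  antisymmetric and sum to zero across the 20 residues.
* **Background normalization.** Era proportions are divided by the
  background proportions of the clustered sequence set and rescaled to
  sum to 100; a composition equal to background maps to 50/50. The
  original figure caption's arithmetic is ambiguous; the unnormalized
  table is always produced alongside.
* **Chi-squared tests.** Pearson statistic without continuity
  correction, delegated to `stats::chisq.test()`. Both readings of the
  composition test are computed — goodness-of-fit of each temporality's
  early/late counts against the sequence background, and the temporality
  x era contingency test — since the original caption does not say
  which was used. p-values are reported raw; no multiple-testing
  correction is applied anywhere, matching the source analysis.

## The registry as data

The default registry stores 28 coenzyme classes: 27 derived from the
CoFactor classification plus ATP. Two of them (MIO, Orthoquinone) carry
an `excluded` flag — no structural interaction data are available for
them — leaving 26 analysed classes; they remain representable so the
count is auditable. Ligand-code membership per class is a curated
starting set in PDB chemical-component conventions; an analysis against
live data would refresh these lists from the public cofactor endpoint,
which is deliberately outside the tested code path (reproducibility
without network access). Temporality assignments follow the prose of the
origins-of-life literature where explicit (e.g. PQQ in LUCA, ascorbic
acid in Post-LUCA, the four Unclassified members, phosphate-free Ancient
classes SAM/tetrahydrofolate/biopterin/heme) and field-standard
placements elsewhere; edits require no code change. Chronology ranks
default to the consensus order of alphabet expansion arranged so that
every early residue precedes every late one (the literal consensus order
interleaves one late residue among the early ten; since ranks are only
used for report ordering, the era-consistent arrangement was preferred).

## The synthetic data generator

Real inputs are database-scale and network-derived, so the package ships
a first-class generator that emits the same file formats the ingest
stage reads (FASTA, SIFTS range TSV, one contacts JSON per structure,
secondary-structure/ECOD/conservation TSVs) plus a truth file restating
every planted parameter. Its defaults *are* the study conditions the
package is designed around: per-temporality early occupancies 0.61 /
0.53 / 0.47 (Ancient / LUCA / Post-LUCA), a 67%-early sequence
background, 200 proteins per temporality with mean site size 8 (2 +
Poisson(6)), 1 + Poisson(1.9) structures per protein, 90% per-structure
retention of true site contacts, backbone-only mode probabilities 0.24 /
0.15 / 0.11, metal mediation 0.24 / 0.13 / 0.11 with an Mg-dominated
element mix, an electrostatic-dominated interaction-type mix,
strand-richer Ancient versus helix-richer Post-LUCA site secondary
structure, and a 10% rate of near-duplicate twin accessions (2%
substitutions outside the site) to exercise redundancy removal.
Retention, the structure-count law, sequence lengths (150-250) and the
conservation grade model (60% of site residues at grade >= 7; 75% MAX-AA
identity) are not printed in the source analysis and were fixed once at
values a structural bioinformatician would call realistic for
multi-structure PDB proteins.

Design points worth knowing:

* Era and contact mode are drawn first; the residue identity is drawn
  uniformly within the era, with glycine eligible only when the mode is
  backbone-only. This both enforces the observed rule that no glycine
  mediates side-chain contacts and keeps the planted mode probabilities
  exact (forcing modes after drawing glycine would inflate backbone-only
  by several points). Glycine is correspondingly rarer among planted
  site residues than a uniform draw would make it.
* Contact atoms are always drawn from the residue's legal heavy-atom
  names; an invariant test enumerates every synthetic contact against
  the atom table.
* Each residue carries one grouped interaction type, constant across
  structures, so the planted type mix is recovered exactly up to
  multinomial noise; clash-only events replace a residue-structure
  observation at the configured clash rate and are dropped downstream,
  which slightly and era-independently lowers interaction ratios.
* What is *not* simulated: 3D geometry, phylogenetic structure in
  sequences (the background is i.i.d.), chimeric chains, insertion
  codes, and correlated conservation. Passing recovery tests therefore
  demonstrates correctness of the bookkeeping and estimators under the
  planted model, not robustness to every pathology of real structural
  data.

## Numerical and degenerate-input choices

Empty presence vectors, empty maps, sequence sets without canonical
residues, expected chi-squared counts of zero, and conservation tables
with no coverage are hard errors; unknown contact labels default to
warn-and-skip (configurable to reject); malformed contact records and
unmappable residues are skipped with counts. Sequences shorter than 10
residues become clustering singletons with a warning. Every record
dropped anywhere in the pipeline (water, metal partners, unmapped,
non-representative after clustering, clash-only, non-standard residues,
ligands outside the analysed classes) is tallied in the run manifest,
and `run_full()` verifies that input = used + sum(dropped-by-reason)
exactly. Output tables are written with fixed formatting and no
timestamps, so a rerun with the same configuration and seed is
byte-identical.

## Problem sizes used by the tests

The shipped test-suite exercises the oracle equivalences on 200 random
small datasets (up to 10 proteins x 5 structures x 20 residues), the
chi-squared oracle on 1,000 random tables, parameter recovery on bundles
of 200 sites per temporality (ordering stability over 100 seeded
replicates) and 500 sites for the mode/type/metal recovery, and
clustering agreement on 50-sequence families — sizes at which the
brute-force oracles are exact and fast. The acceptance script runs the
full pipeline once at the default study conditions.

## Limitations

The temporality labels themselves are contested for several coenzymes
(glutathione most prominently), and the analysis inherits whatever bias
the structural databases carry toward heavily studied proteins and
ligand classes. The identity approximation is ungapped, so insertions
between near-identical sequences depress identity more than the external
tool would; at the 90% threshold on realistic inputs this is rarely
decisive, and the oracle-agreement property bounds the algorithmic
behaviour. Interaction records are taken at face value from the contact
calculation: no geometric re-validation, distance cutoffs, or
quality-based structure filtering is applied, mirroring the source
methodology.
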