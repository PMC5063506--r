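---
title: "Methods: phenotype-separating residues, structural context, and docking workup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-separating residues, structural context, and docking workup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specmap)
```

## The problem

Some receptor agonists activate cells from one set of species and not
another. When the phenotype tracks an accessory protein rather than the
receptor itself (as with TLR4, whose small hydrophobic-pocket partner MD2
actually binds the ligand), the species difference must be written somewhere
in the accessory protein's sequence. `specmap` implements the computational
chain that turns that observation into a structural hypothesis:

1. pick one ortholog per species and align them (alignment construction
   itself is upstream; we consume an aligned FASTA);
2. find **phenotype-separating positions** — alignment columns where the set
   of amino-acid identities in responder species is disjoint from the set in
   non-responder species;
3. place those residues in **structural context** on a receptor complex:
   ligand pocket, dimerization interface, or distal surface, by explicit
   distance rules;
4. build the **docking inputs** (search box, flexible-residue shell, engine
   configuration) used to probe where a small-molecule agonist could sit;
5. analyse **scored docking poses**: cluster them into binding modes,
   map ligand-residue contacts, and quantify inter-mode score gaps and
   overlap with a reference ligand;
6. summarise the supporting **pharmacology**: dose-response AUC (trapezoid
   and cubic spline), pEC50 from a four-parameter logistic, and percent
   difference from a reference agonist with a 90% confidence interval.

Every stage consumes and produces plain tables (tibbles) or small S3
wrappers around them, so stages chain with the pipe, and every stage has a
synthetic-data generator that plants known ground truth.

## Separating positions

A column separates the phenotypes when
`identities(responders) ∩ identities(non-responders) = ∅`. The canonical
pattern this finds is a triplet like positions 130-132 of MD2: one column
conserved in responders (Lys) but variable in non-responders, its neighbour
conserved in non-responders (Arg) but variable in responders, and between
them a near-universally conserved Tyr with a single-species exception —
shared identities make that column *not* separating, which is exactly the
behaviour `find_separating_positions()` must reproduce.

Design choices:

* **Gaps.** By default, columns containing a gap in any sequence are
  excluded from the separating test and reported separately
  (`gap_policy = "exclude"`). Indel columns reflect alignment artefacts as
  often as biology, and the disjointness semantics are only unambiguous over
  residue identities. `gap_policy = "identity"` treats `-` as a 21st
  identity for sensitivity analyses.
* **Ambiguity codes.** `X`, `B`, `Z` are dropped from the identity sets
  before the disjointness test (they match nothing) and the column is
  flagged `ambiguous`. This prevents low-quality sequence from manufacturing
  separations.
* **Pattern labels.** Separating columns are labelled
  `conserved-in-responders`, `conserved-in-nonresponders`, `both-variable`,
  or `both-conserved` (the double-singleton case, which the three-way
  labelling would otherwise misstate).
* **Numbering.** All columns and residues are 1-based. Reference numbering
  is relative to the supplied reference sequence; any signal-peptide offset
  is the caller's responsibility via the `reference` choice.

Ortholog selection (`select_orthologs()`) picks, per species, the candidate
with maximal **coverage** — the fraction of reference positions aligned to a
candidate residue under an end-to-end global alignment with affine gaps and
BLOSUM62 (gap opening 10, extension 4). "Coverage" is not a standardised
quantity; the end-to-end reading is the conservative one for isoform
selection because truncated isoforms cannot win on local similarity alone.
Ties go to RefSeq entries, then to the lexicographically smallest source id,
so selection is a deterministic function of its inputs. With several
reference representatives, a candidate's coverage is the maximum over them
(recorded per representative).

## Structural context

Structures are tidy atom tables (`structure_model`) with one row per atom
and a chain-role tag: `receptor-A`, `accessory-C`, `partner-B` (the second
receptor chain of the active dimer), `ligand`, or `other`. Roles are
assigned explicitly by configuration, never inferred, because biounit files
disagree on chain naming.

Classification rules (`classify_residue_context()`):

* **pocket** — any atom within 3.4 Å of any ligand atom;
* **interface** — not pocket, and any atom within 4.0 Å of the partner
  chain;
* **surface-distal** — neither.

A residue inside both cutoffs is classed pocket: ligand proximity is the
stronger structural statement, and no real case in the motivating data
presents the conflict. "Any atom" includes hydrogens when the file has them
(`heavy_only = TRUE` restricts both sides to heavy atoms). Distances are
reported even when above the cutoffs, so the caller can audit marginal
calls. Solvent accessibility is deliberately out of scope: "surface" is
operationalised as distal-from-pocket-and-interface, which is what the
distance rules can actually certify.

Superposition (`kabsch_superpose()`) is the SVD form of the least-squares
rigid fit with the determinant correction, so reflections are never
returned. Collinear point sets leave the rotation underdetermined; they are
flagged and a best-effort fit returned. `superpose_by_selection()` pairs
atoms by chain, residue number, insertion code and atom name within a
selection, fits on the pairs, and transforms the whole moving model —
the primitive behind bound/unbound comparisons and
`build_chimeric_receptor()`, which grafts chains from a donor complex onto
an acceptor after fitting on a shared selection (e.g. adding the receptor
chain from a dimerized entry to an accessory-protein-only entry).

`conformational_rmsd()` exposes the atom set as a parameter (all atoms by
default, `atoms = "CA"` for backbone-style comparisons) because published
"< X Å" claims rarely state which atoms they cover; the choice is recorded
with the result.

Altloc conflicts keep the highest-occupancy conformer, ties resolved toward
altloc `A`. PDB input/output goes through `bio3d` at the PDB's fixed
3-decimal coordinate precision.

## Docking inputs

The search region is the axis-aligned bounding box of the reference ligand
expanded by 6 Å on every face (`compute_search_box()`); padding applies to
the bounding box, not per-atom van der Waals extents, which is the plainer
reading and errs toward a slightly smaller region. The flexible shell
(`select_flexible_shell()`) contains every residue with any atom within its
chain role's cutoff — 3.4 Å for receptor and accessory chains, 4.0 Å for
the partner chain — of any atom of any reference ligand; multiple reference
ligands (e.g. the native agonist from each species, brought into one frame
by accessory-chain superposition) contribute as a union. Shell membership
is monotone in the cutoff by construction.

`emit_docking_config()` writes a Vina/Smina-dialect config with
`exhaustiveness = 48` (independent search trajectories) and
`num_modes = 9` (saved pose clusters) as defaults, with 96 and 144 as
convergence-check presets; `parse_docking_config()` round-trips it
bit-exactly. Running the engine is out of scope — the package builds inputs
and analyses outputs.

## Pose analysis

Scored poses arrive as multi-model PDB with a `REMARK SCORE` per model or
as Vina/Smina PDBQT (`REMARK VINA RESULT`). Pose RMSD is plain coordinate
RMSD without refitting (poses share the receptor frame) and without
symmetry correction — a documented limitation for symmetric ligands.

Clustering (`cluster_poses()`) is greedy best-score-first: the best-scored
unassigned pose seeds a mode and absorbs all unassigned poses within the
RMSD threshold (default 2.0 Å); modes are ordered by best score and score
ties break by input order. This mirrors the mode-separation spirit of the
docking engines themselves; the threshold is a parameter because no
published value pins it down. The inter-mode **score gap** per run is the
absolute difference of the best scores of the top two modes; across runs
the median and maximum are reported. Against a force field whose known
standard deviation is ~2.5 kcal/mol, a median gap of ~0.2 kcal/mol means
the two modes are energetically indistinguishable — the package reports the
numbers and leaves that judgement explicit.

Overlap with a reference ligand (`reference_overlap()`) reports two
deliberately different metrics — the fraction of pose atoms within 2 Å of
any reference atom, and the Jaccard index of pose vs reference
contact-residue sets — because "substantial overlap" has no canonical
measure; neither metric is privileged.

## Assay metrics

All curves live on `x = log10(molar concentration)`.

* `trapezoid_auc()` — composite trapezoid over (x, response).
* `spline_auc()` — integral of the interpolating cubic spline; the default
  boundary condition is **natural** (zero second derivative), with `"fmm"`
  as the alternative, and the choice travels with the result. For collinear
  data the spline is the line, so the two AUCs agree exactly — a useful
  self-check. With replicates, the default is AUC per replicate then mean
  (`collapse = "mean"` splines the per-concentration means instead).
* `fit_pec50()` — least-squares 4PL,
  `response = floor + (ceiling − floor) / (1 + 10^((log10(EC50) − x)·hill))`,
  by Levenberg-Marquardt with the span bounded below by zero, initialised
  from data quantiles. `pEC50 = −log10(EC50 [M])`, so 1 µM gives 6 and 1 nM
  gives 9. Non-convergence and an EC50 outside the tested range are flagged,
  never silently patched.
* `percent_diff_ci()` — the estimate is
  `100·(mean(cmp) − mean(ref))/mean(ref)`; the default 90% CI comes from
  Fieller's theorem on the ratio of means with pooled variance and
  `n₁+n₂−2` degrees of freedom (exact under normal errors with equal
  variances, which is the natural null here), and a seeded percentile
  bootstrap (10,000 resamples) is the robustness alternative. A comparison
  is **significant** when the CI lower bound exceeds 0% — the one-sided 5%
  rule embedded in a two-sided 90% interval. When the denominator CI spans
  zero the Fieller interval is unbounded and flagged rather than truncated.

## The synthetic-data generators

The generators are first-class, tested code; they define the study
conditions under which every downstream claim is checked.

* `gen_labeled_alignment()` — 3 responders, 4 non-responders, 160 columns
  by default, mirroring a seven-species accessory-protein alignment. The
  default planted truth reproduces the canonical triplet: column 130
  conserved-in-responders (K vs {H,H,R,Q}), column 131 conserved (Y) with a
  single non-responder exception (H), column 132
  conserved-in-nonresponders ({K,K,Y} vs R). Every non-planted column is
  guaranteed at least one identity shared between the groups (each
  background column plants its shared identity in at least one member of
  each group), so the planted columns are exactly the separating ones and
  recovery can be asserted with zero tolerance. Gaps are never planted in
  truth columns.
* `gen_toy_complex()` — single-atom-per-residue chains (5 Å spacing, ±0.1 Å
  jitter) with a multi-atom ligand 2.5 Å under the planted pocket residues
  and a partner chain 3.0 Å from the planted interface residues. The
  geometry guarantees ≥1 Å margins on both sides of the 3.4/4.0 Å cutoffs,
  and the generator asserts those margins at build time. The unbound copy
  drops the partner and ligand, applies a stored rigid transform, and
  displaces a planted loop by a stored vector (3 Å by default) — enough
  geometry to exercise every distance and superposition rule, with no
  pretence of protein realism.
* `gen_pose_set()` — rigid template ligand translated to one of two mode
  centers (20 Å apart by default) plus an isotropic Gaussian displacement
  whose norm is clamped at `spread` (0.5 Å default). The clamp makes
  `spread` the maximum displacement, so within-mode pose RMSD never exceeds
  `2·spread` and greedy clustering at any threshold in
  `[2·spread, separation/2]` recovers the planted modes deterministically —
  the recovery claim is then a theorem about the generator, not a
  probabilistic hope. Scores are Gaussian (sd 0.05 kcal/mol) around
  per-mode means of −7.0 and −6.8 kcal/mol, so the recovered best-score gap
  concentrates near 0.2 kcal/mol.
* `gen_dose_response()` / `gen_group_assay()` — 4PL responses with Gaussian
  noise (plate OD noise is approximately additive), and lognormal
  replicates at a stated CV (multiplex cytokine data are strictly positive
  and right-skewed). The true percent difference is recorded with the
  table.

Every generator is a pure function of its parameters and seed (no hidden
global RNG state; `withr::with_seed` scopes the stream), and written files
round-trip through the package's own readers.

What the synthetic data does **not** emulate: phylogenetic correlation
between species (each background column is drawn independently), real
side-chain geometry and packing, docking-score landscapes with more than
two basins, or plate-position and batch effects in assays. Passing the
recovery tests therefore demonstrates that the *operations* are correct
under their stated assumptions, not that the biological conclusions of any
particular study are right.

## Numerical choices and degenerate inputs

* Distances are computed by vectorised all-pairs expansion
  (`|a−b|² = |a|² + |b|² − 2a·b`, clamped at zero before the square root);
  the test suite checks it against naive double loops, so any future
  spatial-index acceleration inherits an exact oracle.
* Superposition requires ≥3 paired non-collinear atoms; collinear sets
  warn. Determinant correction forbids reflections even when a mirror fit
  would score better.
* 4PL fits bound `hill ∈ [0.05, 20]` and `span ≥ 0`; a fit that converges
  to the boundary is visible in `tidy()` output.
* Zero-variance groups give degenerate (point) confidence intervals rather
  than errors; zero-width boxes are legal (a single-atom ligand plus
  padding).
* Cluster score ties break by input order; this is the one documented
  order dependence in the package.

## Problem sizes in the test suite

The suite asserts exact recovery over 100 seeded alignments (7 × 160),
brute-force agreement over ~2,000 aggregated geometry queries on 60 random
structures, grid-oracle agreement for superposition on 5-point sets (10°
rotation grid with closed-form translation), 100 seeded two-mode pose sets,
and 2,000-replicate Monte-Carlo calibration of the significance rule
(observed one-sided error ≈ 5%, CI coverage ≈ 90-91%). These sizes keep the
default test run under a minute while leaving the statistical assertions
with comfortable margins; `scripts/acceptance.R` re-runs the same
computations from scratch at the same sizes.

## Known limitations

* No mmCIF input; no SASA; no symmetry-corrected pose RMSD; no engine
  invocation.
* Fieller intervals assume approximately normal group means — fine at the
  CVs typical of cytokine panels, but the seeded bootstrap is there for
  heavier tails.
* Spline AUC depends mildly on the boundary condition at the ends of the
  tested range; the condition used is recorded with every result.
* Phenotype-separating analysis does not correct for shared ancestry: a
  column can separate the groups because of phylogeny rather than function.
  The structural-context stage is the intended filter for such hits.
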