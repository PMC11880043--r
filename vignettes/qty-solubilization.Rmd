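---
title: "Designing and characterizing water-soluble QTY analogs of membrane proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and characterizing water-soluble QTY analogs of membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtykit)
library(ggplot2)
```

## The problem

Integral membrane proteins — receptors, transporters, membrane-embedded
enzymes — expose large hydrophobic surfaces to the lipid bilayer, which
makes them notoriously hard to express, purify and study in aqueous
solution. The QTY code is a deterministic protein-engineering recipe for
this problem: inside the transmembrane (TM) helices, replace the four most
lipid-facing hydrophobic residues with hydrophilic residues of nearly the
same size and shape,

| native | analog | rationale |
|--------|--------|-----------|
| Leu (L) | Gln (Q) | similar side-chain volume, amide replaces isobutyl |
| Ile (I) | Thr (T) | beta-branched for beta-branched |
| Val (V) | Thr (T) | beta-branched for beta-branched |
| Phe (F) | Tyr (Y) | aromatic for aromatic, adds one hydroxyl |

and leave everything outside the TM segments untouched. Because Q, T and Y
are uncharged, the substitution adds no acidic or basic groups, so the
analog's isoelectric point barely moves; each replacement adds only
14–16 Da, so the molecular weight is nearly unchanged; and because the
replacements are shape-conservative, the analog is expected to keep the
native fold while losing its hydrophobic surface patches.

`qtykit` implements the design step and the full characterization pipeline
used to validate such designs: sequence-variation statistics, molecular
weight and isoelectric point, hydropathy profiles, rigid-body superposition
RMSD between native and analog structures, solvent-accessible surface area
(SASA) with hydrophobic-surface fractions, and binding-site contact and
conservation analysis.

## The design step

A protein is a record (a tibble row) carrying its sequence and its TM
segments in 1-based inclusive UniProt TRANSMEM convention. TM annotations
are an *input*: helix assignments come from UniProt or prior structural
work, and no TM-prediction algorithm is shipped — predicting helices and
designing within them are separate concerns, and conflating them would make
the variation statistics depend on a predictor's idiosyncrasies.

```{r design}
rec <- protein_record("toy", "MKLLIVFAGW", tibble::tibble(start = 3, end = 8))
q <- qty_apply(rec)
q
cat(render_alignment(q$native, q$analog, q$segments[[1]]))
```

Two percentages summarize a design: the TM variation (substitutions over
summed TM length) and the overall variation (substitutions over the full
sequence length). Substitution is applied only inside annotated segments,
which is what keeps the soluble domains — and with them pI and MW —
essentially invariant, and what forces TM variation ≥ overall variation.
The percentages are carried at full precision and printed to two decimals.

The map is a fixed point: Q, T and Y are not themselves substituted, so
applying the code to an analog is a no-op. This idempotence, the locality
of edits to TM segments, and conservation of all charged-residue counts are
the invariants the test suite exercises on randomized designs.

## Physicochemical characterization

Molecular weight is the sum of average residue masses plus one water
(Expasy Compute-pI/MW convention; average rather than monoisotopic masses
because whole-protein values are reported to two decimals). The net charge
at a given pH is the Henderson–Hasselbalch sum over ionizable groups —
positive: N-terminus, K, R, H; negative: C-terminus, D, E, C, Y — and the
pI is its unique root, found by bisection on (0, 14) to 1e-4 pH (the curve
is strictly decreasing, so bisection cannot miss). The default pKa set is
the Bjellqvist/Expasy one, including Expasy's residue-specific N-terminal
pKa values; the simpler EMBOSS set ships as an alternative
(`pka_table("emboss")`). The two sets differ by up to a few tenths of a pH
unit on ordinary peptides, which is why the set is named in every report.

```{r characterize}
qty_characterize(q)
```

Hydropathy profiles use the Kyte–Doolittle scale with a 19-residue default
window (the conventional choice for TM detection). Every QTY target scores
lower than its source on this scale, so an analog's profile is pointwise at
or below the native one — a quick sanity check that a design actually
removed its membrane signature:

```{r hydropathy, fig.width = 6, fig.height = 3}
fx <- synthetic_tm_protein(n_helices = 4, helix_len = 24, loop_len = 6,
                           hydrophobic_bias = 0.8, seed = 7)
qfx <- qty_apply(fx$record)
autoplot(hydropathy_profile(qfx$native), segments = qfx$segments[[1]])
```

## Structures, pairing and superposition

Structures (PDB or mmCIF) are parsed into a flat heavy-atom tibble: first
model only, alternate locations resolved to the highest-occupancy conformer
(ties fall back to altloc A), hydrogens dropped, hetero residues kept and
flagged. All of this is deterministic so repeated runs are bit-identical.
Residue numbers are author numbering, which for the experimental entries of
interest follows UniProt numbering, while predicted models typically number
from 1; `pair_residues()` therefore offers a constant per-model offset and,
as the robust fallback, a global sequence alignment in which the four QTY
pairs score as matches, so a native leucine aligns onto its analog
glutamine rather than opening a gap.

Pairing is also where loop trimming happens: residues present in only one
model — unresolved loops in an experimental structure, extra termini in a
prediction — simply have no partner and drop out of the comparison. When a
structure is multimeric, `extract_protomer()` cuts out one chain together
with the hetero residues whose nearest polymer atom belongs to it.

Superposition is the closed-form Kabsch solution: SVD of the covariance of
the centered paired CA coordinates, with the reflection corrected by
flipping the smallest singular vector whenever the candidate rotation has
negative determinant — a mirror image is never matched by an improper
transform. Optional outlier-rejection cycles (`cycles`, `cutoff`) re-fit
after discarding pairs whose post-fit distance exceeds the cutoff,
emulating the refinement of PyMOL-style `align`; because published RMSDs
rarely state their refinement settings, both the all-pair RMSD and the
refined RMSD are always reported so a published value can be bracketed.
CA-only superposition is the default (an `atoms = "all"` option exists):
with no published atom-selection convention to follow, CA is the defensible
common denominator.

```{r superpose}
noisy <- perturb_structure(fx$model, sigma = 0.5, seed = 11)
sp <- superpose_structures(fx$model, noisy, pair_residues(fx$model, noisy))
glance(sp)
```

For i.i.d. Gaussian coordinate noise of s.d. sigma per axis, the
post-superposition RMSD concentrates slightly below `sqrt(3) * sigma`
(the fitted transform absorbs six degrees of freedom), which is how the
generator plants structure pairs of known expected RMSD for testing.

## Solvent-accessible surface and hydrophobic patches

SASA is computed with the Shrake–Rupley construction: each atom's
accessible sphere (van der Waals radius + 1.4 Å probe) is sampled at 960
points and a point counts as accessible if it lies outside every neighbor's
accessible sphere. Two numerical choices matter:

* **Deterministic, frame-covariant sampling.** The sample points are a
  golden-section spiral — no random numbers, so areas are bit-reproducible —
  oriented in a canonical frame built from the principal axes of the
  molecule itself (with a covariant sign convention). Orienting the spiral
  in the molecule frame rather than the lab frame makes areas invariant
  under rigid motion of the input to numerical precision, not merely to
  sampling error. Exact point-group symmetries (equal covariance
  eigenvalues) could still reorder the axes; real molecules are generic.
* **`n_points` is the accuracy knob.** At 960 points an isolated sphere is
  within 0.5 % of its analytic area and a two-sphere overlap within 1 % of
  the closed-form spherical-cap result; doubling the points changes totals
  by well under 0.5 %.

Hydrophobicity is assigned at the residue level: the hydrophobic surface is
the SASA of residues in {L, I, V, F, M, W, A}, and the hydrophobic fraction
is that area over the total. Proline is excluded from the default set (it
is the set used when describing lipid-facing TM surfaces); the set is an
argument everywhere it matters. The radii are a Bondi-style heavy-atom set
(`vdw_radii()`); hydrogens are never modeled.

```{r surface}
nat <- shrake_rupley(fx$model)
ana <- shrake_rupley(thread_analog(fx$model, qfx))
compare_surfaces(nat, ana)
```

`thread_analog()` renames residues along the analog sequence on *identical*
coordinates, the idealized setting in which any change in hydrophobic
fraction is attributable purely to the substitution chemistry. On such
matched coordinates the analog's hydrophobic fraction strictly decreases
whenever at least one exposed residue was substituted.

## Binding sites

Pocket analysis uses the minimum heavy-atom distance convention throughout:
a contact residue is a polymer residue with any heavy atom within the
cutoff (default 4.0 Å, the conventional pocket radius) of any ligand atom.
Inter-cofactor separations are reported under both the minimum-heavy-atom
and the centroid convention, because published single-number separations
often leave the convention unstated; every report names the one used.
Pocket conservation between a native and an analog model maps the analog's
contact residues through the residue pairing and reports the Jaccard index
of the two contact sets plus a kept/lost/gained table (an invented but
clearly labeled summary statistic); analog contacts absent from the pairing
are listed as `unpaired`, never dropped silently.

## The synthetic generator, and what passing tests do not show

`synthetic_tm_protein()` emulates the two features of real membrane enzymes
that the pipeline's statistics depend on: TM segments enriched in
hydrophobic residues (default bias 0.8 — real TM helices are strongly but
not purely hydrophobic) connected by polar loops, and a helical-bundle
geometry (ideal helices, 1.5 Å rise and 100° twist, packed antiparallel on
a 10 Å grid). Defaults of 4 helices × 24 residues with 6-residue loops give
a bundle in the size range of small multi-pass membrane enzymes while
keeping every test and the acceptance run fast. The generator does not
attempt side-chain placement, Ramachandran-valid loop backbones, lipids or
realistic packing density; consequently, passing tests demonstrate the
correctness of the *computations* (substitution logic, mass/pI arithmetic,
superposition optimality, area sampling, contact geometry) on controlled
inputs, not the biological success of any particular solubilized design.
Judgments about a real protein still require its real structures.

## Degenerate inputs and tie-breaks

Collinear point sets give a non-unique optimal rotation; the SVD solution
is still a minimizer and is returned (documented, not warned). Equal-occupancy
altlocs fall back to conformer A, then file order. Records without TM
segments are a design error, not a silent no-op. Differences outside TM
segments in `variation_stats()` are counted but warned about, since QTY
output cannot produce them. Sequences with non-standard letters are
rejected outright in strict mode; in lenient mode they are carried verbatim,
excluded from substitution, and make mass/pI computations fail loudly
rather than guess.

## Reproducing published-scale numbers

The package's own tests run entirely offline on synthetic fixtures. A
separate, clearly optional script (`inst/validation/validate_published_study.R`)
reproduces the published six-enzyme characterization — TM variation range
37.50–54.69 %, overall range up to 27.63 %, native-vs-analog RMSD range
0.273–0.875 Å, and the FAD–heme–F359 relay geometry in the STEAP4
oxidoreductase — but requires downloading the six UniProt entries, the six
experimental structures and the deposited analog models, and so is not part
of any automated run. Note that published RMSDs for these pairs appear with
two slightly different sets of values depending on where they are quoted;
the script prints both the raw and the outlier-refined RMSD for exactly
this reason.
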