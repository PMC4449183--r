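---
title: "Domain architecture and active-site completion in GH20 hexosaminidases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain architecture and active-site completion in GH20 hexosaminidases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gh20arch)
```

## The scientific question

Family GH20 glycoside hydrolases (beta-N-acetylhexosaminidases and
lacto-N-biosidases) hydrolyze terminal N-acetylhexosaminyl residues by
substrate-assisted catalysis in a (beta/alpha)8-barrel (TIM-barrel) catalytic
domain, here called GH20. The enzymes of known structure carry widely
different accompanying domains, which raises a practical engineering
question: what is the minimal domain combination that still gives a folded,
active enzyme?

Two observations organize the family. First, architectures split into two
classes: **Model A**, where a non-catalytic accessory domain (GH20b) sits
immediately N-terminal to the catalytic domain, which is followed by an extra
alpha-helix (GH20b-GH20-alpha, possibly with further domains); and
**Model B**, a catalytic GH20 domain with no GH20b. Second, in every Model A
structure the subsite -1 substrate-binding cavity is *completed by a remote
element*: a segment far away in sequence that folds back onto the active site
and contacts the two conserved subsite -1 residues, an arginine and an
aspartate/glutamate. The remote element comes from one of three places:

* the catalytic domain's own **loop 2** (the loop after barrel strand
  beta-2), when that loop is long;
* an **accompanying domain** (the lectin-like domain in the
  *B. bifidum* lacto-N-biosidase, LnbB), when loop 2 is short;
* the **dimer partner's C-terminus** (human HexA/HexB, the insect OfHex1,
  the streptococcal GcnA), likewise when loop 2 is short.

Truncation constructs that remove the remote element's source are inactive
even when they express and fold, so the classification has direct
consequences for construct design. This package implements the full
computational side of that survey: consensus domain-architecture
classification, hydrogen-bond-based secondary structure and barrel/loop
detection, conserved-pair anchoring, typed contact analysis and
remote-element provenance calls, plus the sequence-level bookkeeping
(truncation constructs, expression tags, theoretical masses) needed to plan
and interpret the constructs.

## Pipeline and module map

1. **Structure I/O** (`parse_structure()`, `select_chains()`,
   `write_structure()`, `fetch_structure()`): PDB/mmCIF through *bio3d*,
   first model only, highest-occupancy alternate conformers, hydrogens
   dropped, waters kept but flagged, author residue numbering throughout
   (every residue index in the survey literature is author numbering).
2. **Secondary structure** (`assign_backbone_hbonds()`,
   `assign_secondary_structure()`, `detect_barrel()`, `extract_loop()`):
   Kabsch-Sander electrostatic hydrogen-bond model, bridge-rule strand
   ladders, barrel = eight strands whose hydrogen-bond adjacency graph forms
   a single cycle.
3. **Superposition and annotation transfer** (`kabsch_superpose()`,
   `align_domains()`, `transfer_annotations()`): CA-only Kabsch superposition
   over sequence-aligned domain spans; conserved-pair labels move between
   structures only through explicit mappings, never by inference.
4. **Architecture** (`load_annotations()`, `consensus_architecture()`,
   `classify_architecture()`, `detect_extra_helix()`,
   `interface_residues()`).
5. **Active site and remote element** (`anchor_active_site()`,
   `classify_loop2()`, `detect_contacts()`, `find_remote_element()`,
   `second_shell_membership()`, `build_report()`).
6. **Sequence tools** (`global_align()`, `build_construct()`,
   `theoretical_mw()`).
7. **Synthetic fixtures** (`make_ideal_helix()`, `make_hairpin()`,
   `make_mini_barrel()`, `plant_contact_pair()`, `make_remote_demo()`,
   `make_toy_annotations()`).
8. **Orchestration** (`gh20_config()`, `run_scan()`, `render_report()`).

## Models and conventions

### Hydrogen bonds and secondary structure

The survey literature assigned secondary structure by visual inspection in a
molecular viewer, which is not reproducible. We use the standard
Kabsch-Sander electrostatic model instead: the amide hydrogen is placed 1.0 A
from N along the previous residue's C=O direction, and

E = 27.888 (1/d(ON) + 1/d(CH) - 1/d(OH) - 1/d(CN)) kcal/mol,

with a bond recorded when E < -0.5 kcal/mol. Prolines and chain-leading
residues cannot donate; same-chain pairs closer than two sequence positions
are excluded. Helices come from i -> i-4 turns, with one guard beyond the
textbook rule: a 4-turn is accepted as helical only when the three spanned
residues stay within 7 A CA distance of both turn ends. An i,i+4 hydrogen
bond can also arise between two strand ends joined by a three-residue
excursive loop; in an ideal helix the largest such distance is about 6.4 A,
while in the excursive case it exceeds 7.5 A, so the guard separates the two
cleanly. Strands come from the standard parallel/antiparallel bridge rules;
bridge runs shorter than 3 residues are demoted to coil.

### Barrel topology and loop numbering

`detect_barrel()` collects the strands inside the candidate catalytic span,
links two strands when at least two hydrogen bonds join their residues, and
accepts the topology when the adjacency graph on eight strands is a single
cycle (one missing ladder edge - a bulge - is tolerated with a warning).
Strands are numbered beta-1..beta-8 *in sequence order from the N-terminus*,
and loop k is the stretch strictly between strand k and the next
secondary-structure element. The numbering convention is a package decision
(the survey literature uses "loop 2" without defining it); this choice
reproduces the published loop-2 spans.

Loop 2 is called **Long** at >= 12 residues. The published spans are
bimodal - short loops are 6-11 residues, long ones 15-30 - so any boundary in
12-14 separates them; 12 is stored as a config default
(`loop2_threshold`).

### Contact chemistry

The published interaction tables come from visual analysis with no stated
distance criteria, so all cutoffs here are package decisions, kept as
explicit config keys:

| parameter | default | meaning |
|---|---|---|
| `polar_cutoff` | 3.5 A | max heavy-atom distance for a polar contact (both atoms polar) |
| `nonpolar_cutoff` | 4.5 A | max distance for a non-polar contact (both atoms apolar) |
| ligand first shell | 4.0 A | a residue this close to the ligand is first shell, not second |
| neighbour exclusion | +/-5 | sequence window around the conserved pair ignored in the remote search |
| `loop2_threshold` | 12 res | Long/Short boundary for loop 2 |
| `interface_cutoff` | 4.5 A | heavy-atom cutoff for domain-interface residue pairs |
| transfer radius | 5 A | max CA-CA distance for annotation transfer after superposition |

Atom polarity is a pure function of (residue name, atom name): N and O are
polar; Cys SG is polar and Met SD apolar (the common hydrophobicity
convention); a carbon is polar only when its residue template bonds it to at
least two N/O atoms (backbone carbonyl, amide, carboxylate and guanidinium
carbons). Waters are excluded from all distance searches unless
`water_mode = TRUE`, in which case a water oxygen within 3.5 A of polar atoms
of both residues records a water-mediated bridge (this is how the
lacto-N-biosidase's Gln190-Leu574 style bridges appear).

### The remote-element search

`find_remote_element()` considers every residue contacting the conserved
arginine or aspartate/glutamate except (i) residues within the +/-5 window of
either anchor and (ii) the catalytic domain's own residues outside loop 2
(its first shell is local structure, not a remote element). The
best-contacting surviving residue assigns the provenance class: `loop2`,
`partner_chain`, or `accompanying_domain`; ties in distance break to the
smaller author number. Key residues are selected purely by distance -
chemistry is reported but never used for selection, because at least one
published remote key residue is polar (a glutamine), so a hydrophobicity
filter would miss it. An empty search is a valid result (`source = "none"`):
it is the computational mirror of deleting the element's source domain, which
inactivates the enzyme in vitro.

Heterodimers are analyzed per subunit (two report rows), matching how the
published survey lists the two human HexA sites; homodimers report one
representative site.

### Constructs and masses

`build_construct()` models the expression constructs used to dissect LnbB:
`n_his6` prepends the pET28a thrombin-site leader
(`MGSSHHHHHHSSGLVPRGSHM`), `c_his6` appends the pET24b XhoI junction
(`LEHHHHHH`), and an initiator Met is added when the construct's own
N-terminus is not the tag and does not already start with Met. The vectors'
exact junction sequences are not printed in the survey literature; these
defaults are the standard vector products, and the +/-2 kDa acceptance band
on the four construct masses (112, 57, 83 and 28 kDa) absorbs the residual
ambiguity. `theoretical_mw()` sums average residue masses plus one water
(18.015 Da). Percent identity from `global_align()` (Needleman-Wunsch,
BLOSUM62, gap open 10 / extend 0.5) counts identical columns over aligned
columns after discarding terminal-gap columns, so length differences do not
masquerade as divergence.

## What the synthetic generators emulate - and what they do not

Everything above is testable without downloads because the fixture module
generates structures with exactly known ground truth:

* `make_ideal_helix()` builds backbone geometry from ideal internal
  coordinates (phi -57, psi -47), which guarantees the i -> i-4 bond ladder.
* `make_mini_barrel()` builds a closed **antiparallel meander** barrel:
  strands on a cylinder at 4.8 A spacing, each residue's C=O and N-H aimed at
  its partner strand with exact mutual hydrogen-bond geometry, loops placed
  as displaced coil stacks that form no bonds. We use an antiparallel meander
  rather than the parallel register of real TIM barrels because a rigid
  per-residue template cannot satisfy both hydrogen-bond ladders of a
  parallel sheet simultaneously, while the antiparallel register is exact at
  every level - and the barrel detector keys on bridge adjacency, which is
  direction-blind. Loops of length 0 or 1 erode the detected strand ends by
  one residue (the turn-adjacent bonds fall inside the sequence-separation
  exclusions), so exact-recovery tests use loops of length >= 2.
* `plant_contact_pair()` places a probe residue whose designated atom sits at
  an exact distance from a chosen target atom, approaching perpendicular to
  the target's bond direction so the designated pair is the contact minimum.
* `make_remote_demo()` assembles the three remote-element scenarios (long
  loop 2 folded onto the site; a probe in a C-terminal accompanying span; a
  probe on a second chain) around a labeled conserved pair.

The fixtures are idealized: backbone plus CB only, no side-chain rotamers, no
barrel twist or shear, no crystallographic noise, B-factors or alternate
conformations beyond what the I/O layer handles. Passing the fixture suite
therefore demonstrates that the *algorithms* recover designed ground truth
exactly; it does not demonstrate robustness of the secondary-structure
boundaries on real, distorted barrels. For that reason the loop-2 boundary
checks against deposited entries carry a +/-2 residue tolerance (no
secondary-structure criteria were published to match against), while all
fixture checks are exact.

## Worked example

```{r survey}
ann <- load_annotations(make_toy_annotations())
calls <- classify_survey(ann)
enzyme_models(calls)
```

```{r demo}
demo <- make_remote_demo("accompanying_domain")
s <- demo$structure
hb <- assign_backbone_hbonds(s)
ss <- assign_secondary_structure(s, hb)
bar <- detect_barrel(s, ss, hb, chain = "A")
site <- anchor_active_site(s, demo$annotations)[[1]]
find_remote_element(s, site, classify_loop2(bar), demo$gh20_span,
                    domains = demo$domains)
```

## Numerical and degenerate-input choices

* Multi-model files: first model only; alternate locations: highest
  occupancy, first on ties.
* Unknown residue templates default every atom to polar with a warning, so
  exotic chemistry is never silently dropped from polar searches.
* `kabsch_superpose()` refuses fewer than three pairs or collinear sets; the
  determinant correction excludes reflections.
* Annotation consensus resolves overlaps by source priority (cazy > pfam >
  superfamily > scop > psiblast > manual); same-priority disagreements keep
  both spans and flag a conflict rather than guessing. The consensus is
  invariant under row permutation of the input table.
* The Model A call keys on GH20b immediately N-terminal to GH20; the extra
  alpha-helix is recorded when found but not required (one surveyed entry
  prints a truncated architecture string, and requiring the helix would
  misclassify it).
* Oligomeric state is carried as `"unknown"` where it has not been measured
  in solution; it is never inferred from crystal contacts.
* Problem sizes in the test-suite and acceptance script: 8-strand barrels of
  8-residue strands (plus loops), 15-point superposition sets, toy sequences
  up to ~70 residues. These sizes make every fixture property checkable
  exactly while the whole suite runs in well under a minute.

## Known limitations

* Conserved-pair labels are only shipped (for the thirteen surveyed entries)
  or transferred through an explicit superposition mapping; the package never
  infers an active site from sequence motifs. In particular the LnbB
  glutamine that substitutes the conserved arginine's role from subsite -2 is
  handled correctly only because its label is shipped.
* For the human heterodimer entry the deposited chain identities of the two
  subunits are resolved at analysis time from the labeled residue identities,
  not stored.
* Assembly generation from crystal symmetry is out of scope; analyses use the
  deposited chains, which suffice for every surveyed entry.
* `detect_barrel()` tolerates one missing ladder edge; heavily distorted or
  decorated barrels (large insertions between strands) may still need a
  narrowed `search_span`.
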