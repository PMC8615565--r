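---
title: "Logical modeling of germinal-center B-cell signaling for patient-specific DLBCL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical modeling of germinal-center B-cell signaling for patient-specific DLBCL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gclogic)
```

## The biological question and the modeling formalism

Diffuse large B-cell lymphoma (DLBCL) arises from B cells passing through
the germinal center (GC), where the cell's fate is decided by a small set of
marker genes — BCL6 (dark-zone program and tolerance of genotoxic stress),
MYC (proliferation), BLIMP1 (plasma-cell commitment) and BCL2 (survival) —
downstream of three receptor systems: the B-cell receptor (BCR), CD40, and
the interleukin-21/4 receptors (summarized as one input, `IL21_4`).

`gclogic` represents this circuitry as a multi-valued logical network. Each
component carries an integer activity level; most are Boolean (0/1), while
`IKKc`, `NFkB` and `IRF4` are ternary (0/1/2), distinguishing the low,
transient NF-kB/IRF4 activity triggered by BCR signaling (level 1) from the
high, sustained activity triggered by CD40 (level 2). That distinction is
load-bearing: transient IRF4 permits BCL6 expression, sustained IRF4
switches the cell to BLIMP1 and plasma-cell exit. Rules are propositional
formulas over thresholded atoms (`X` = "level of X is at least 1", `X:2` =
"at least 2"); a component adopts the **highest** target level whose
condition holds. This highest-wins convention is required for the states in
which both the BCR and CD40 branches are active: the CD40/TRAF6 branch must
then drive IKKc — and with it NF-kB — to level 2 even though the CBM-complex
condition for level 1 also holds.

Attractor analysis uses fixpoints only. Fixpoints are invariant across
update schedules (synchronous, asynchronous, or otherwise), so nothing in
the package's conclusions depends on a scheduling choice; trajectories and
cyclic attractors are deliberately out of scope. Inputs are environment,
not dynamics: they are held constant and every analysis conditions on an
input assignment.

## The GC model and its reconstruction status

The multi-regulator rules of `gc_network()` are the published logical
functions of the system:

| component | rule |
|---|---|
| PI3K | `SYK & BTK` |
| MYC | `PI3K & NFkB & !BLIMP1 & !BCL6` |
| ERK | `RAF & !STAT` |
| IKKc | `1 <- CBM ; 2 <- TRAF6` |
| BCL6 | `IRF4 & !IRF4:2 & !(ERK | BLIMP1)` |
| BLIMP1 | `IRF4:2 & STAT & !BCL6` |
| AID | `NFkB & STAT & !BLIMP1` |
| BCL2 | `(PI3K | NFkB) & !BCL6` |

The single-regulator rules (`SYK = BCR`, `BTK = BCR`, `RAF = BTK`,
`CBM = BTK`, `TRAF6 = CD40`, `STAT = IL21_4`, and the level-preserving
chain `NFkB = IKKc`, `IRF4 = NFkB`) are a *reconstruction* from the
described pathway wiring, not a transcription of a published rule table;
they are the simplest rules consistent with the interaction graph and they
reproduce the full published attractor table, which the test suite asserts
stage by stage. Two reconstruction choices deserve note:

* **IkB is not an explicit node.** NF-kB activation is modeled as a direct
  level copy from IKKc; the physiological double inhibition
  (IKKc ⊣ IkB ⊣ NF-kB) is collapsed into one activation. The gene-level
  mapping still honors it: an *amplification* of the inhibitor gene NFKBIE
  maps to a *loss* of the NFkB component.
* **IRF4 has no NF-kB-independent regulators.** Its level mirrors NFkB,
  which is what gives the dual-sign IRF4→BCL6 behaviour (activating at
  level 1, inhibiting at level 2) its stage specificity.

Stages are identified with input combinations via
`stage_id = 1 + 4·BCR + 2·CD40 + IL21_4`. Combinations with T-cell-derived
signals but no BCR engagement (ids 2–4) cannot occur physiologically —
T-cell help presupposes antigen presentation — and are excluded from all
patient-level comparisons, which run over the five physiological stages
LZ1, Pre-GC, DZ, LZ2, PC. Marker patterns use BCL6, BLIMP1, MYC, BCL2 only;
AID is computed and reported (it marks somatic-hypermutation competence,
active exactly in the wild-type DZ attractor) but never enters pattern
equality, stage colors, or the "no marker" treatment criterion.

## From genotypes to patient models

Lesion tables use Oncoprint-style categories. Only strong effects are kept:
non-synonymous mutations, structural variants, and high-grade copy-number
gains/losses; synonymous mutations and low-grade/neutral copy-number
records are filtered out, as are genes absent from the mapping table.
Interpretation is mechanical and sign-aware:

* copy-number loss → loss of function (LOF), gain → gain of function (GOF);
* mutations and SVs: GOF for oncogenes, LOF for tumor suppressors;
* an inhibiting gene→component edge inverts the direction (TNFAIP3/A20 LOF
  becomes IKKc GOF; NFKBIE amplification becomes NFkB LOF);
* LOF clamps the component to 0, GOF to its maximal level — so GOF of a
  ternary component is always level 2, which is why NF-kB-pathway lesions
  tend to produce plasma-cell-like attractors.

When one component collects both GOF and LOF clamps, the LOF wins and the
conflict is recorded and surfaced in every report. The underlying sources
are silent on this case; we chose LOF because loss of the protein is
epistatic to activating point mutations for essentially all modeled genes,
and a deterministic rule matters more here than the particular choice.

TLR2/MYD88 map to TRAF6 rather than directly to NF-kB. This reproduces the
documented "constantly strong (level 2) NF-kB" phenotype of TLR2-perturbed
models through the IKKc level-2 branch while keeping the NF-kB node free,
so that an NF-kB inhibitor still acts on such models.

The shipped mapping table contains exactly the 29 gene→component rules
documented in the narrative text (27 genes map via families and regulators
onto 13 components). The full curated gene list behind the original
cohort-scale counts was never published, so cohort-level tallies that
depend on it are out of scope by design; the synthetic-cohort module plus
the worked-example genotypes substitute property-level checks for them.

## Oncogenicity and NF-kB dependency

Four independent flags, each recomputable from a profile, define
oncogenicity: an abnormal marker combination (BCL6 together with MYC and/or
BCL2 — the double/triple-hit-like state); a marker in the wrong stage (BCL6
outside DZ, MYC outside Pre-GC/LZ2); loss of the plasma-cell exit (PC stage
lost *or* its attractor lacking BLIMP1); and loss of the LZ1 resting state
(stage lost *or* any marker active without input — escape from selection).
A model is oncogenic if any flag fires. Note the PC-loss flag deliberately
covers the "stage exists but BLIMP1 is gone" case, which is how a
STAT/EZH2-perturbed genotype loses plasma-cell exit without touching the
inputs.

NF-kB dependency uses a fixed decision cascade, evaluated in this order:

1. **independent** — the genotype clamps MYC or BCL6 active; marker output
   is then driven by the lesion, not by NF-kB signaling;
2. **inactive** — the genotype clamps NFkB (or IKKc, its only regulator)
   to 0;
3. **level2 / level1** — the genotype's *internal* clamps alone give NFkB a
   constitutive level 2/1 in the signal-free condition (all inputs 0);
4. **unperturbed** otherwise.

The cascade order is a design choice: precedence of *independent* keeps
BCL6-driven genotypes that also carry NF-kB-pathway lesions (e.g.
MEF2B+TLR2) in the BCL6 group, matching the documented grouping, and it
keeps the claim that the NF-kB+BCL2 inhibitor combination clears all
attractors of the three perturbed/unperturbed NF-kB-dependent classes true
by construction of the class, not by accident. Step 3 sets input clamps
aside: a receptor-level lesion such as CD79B (constitutive BCR) changes
which stages exist but does not by itself create constitutive NF-kB in the
signal-free diagnostic, so a CD79B-only model stays *unperturbed*. The
original analysis does not state a class for that case; this is our
resolution, chosen so that "constitutive NF-kB" always means an
input-independent activation.

Step 3 is computed by synchronous iteration from the clamped all-zero
state. The NFkB ancestor subgraph (receptors → SYK/BTK → CBM/TRAF6 → IKKc →
NFkB) is acyclic, so the iteration stabilizes within network depth; if a
modified network ever failed to converge, the implementation falls back to
conditioned fixpoint enumeration and takes the maximal NFkB level. Tests
assert the iteration agrees with enumeration on genotype models.

## Drug simulation

Each inhibitor clamps its target to 0: Ibrutinib → BTK, Copanlisib → PI3K,
Bortezomib → NFkB, Venetoclax → BCL2. Drug clamps are applied *after*
genotype clamps and therefore override them on the same component — without
this precedence a BCL2 inhibitor could not act on a BCL2-amplified model,
contradicting the documented behaviour. Drugs act on the named component
only; lesions downstream of the target escape, which is exactly how an
IRF4-GOF model keeps BLIMP1 under NF-kB inhibition.

Response is scored by the "no marker" surrogate: the count (and fraction)
of reachable physiological stages whose attractors have all four markers
off, standing in for loss of pro-survival signaling in a model without an
explicit apoptosis module. Stages lost to input clamps leave the
denominator. Regimen ranking orders by descending no-marker count, then
fewer total active markers, then smaller regimens, then label — the last
two steps only break exact ties, keeping the ranking deterministic.

The default candidate set is the seven blocks used throughout the original
comparison: none, the four single agents, PI3Ki+BCL2i and NFKBi+BCL2i.

## The synthetic cohort

No per-gene lesion-frequency table was ever published, so the generator's
defaults are explicit synthetic choices, not estimates: every mapped gene
has weight 1 with BCL2 at 4 (making BCL2 the most frequent lesion by
construction, as described for the real cohort); patients carry 1–10
distinct-gene lesions with a geometrically decaying count distribution
(decay 0.3, mean ≈ 3, chosen so most patients have few lesions, as in real
exome data); cell-of-origin labels are drawn ABC 0.35 / GCB 0.50 /
unclassified 0.15, near reported DLBCL proportions; BCL2 alteration classes
are COO-conditioned (ABC amplification-biased, GCB mutation/SV-biased,
mirroring the documented ontogeny difference). A `noise_fraction` adds
records the filter must drop, to exercise the filtering path.

What the generator emulates: marginal lesion-frequency ranking, the
lesions-per-patient range, COO-biased BCL2 alteration classes, and
mappability of every default record. What it does not emulate: gene–gene
co-occurrence and mutual exclusivity, mutational signatures, subclonality,
purity, and any survival structure. Tests passing on synthetic cohorts
therefore validate the pipeline's mechanics and the classifier's totality —
not epidemiological claims about real DLBCL.

The nine worked-example genotypes (models 131, 73, 29, 47, 34, 60, 85, 27,
92) ship as an exact fixture table. Where the narrative omits the
alteration class of a lesion, the fixture records `sv` — mutation and SV
map identically under the role-based rule, so the clamp set is unaffected.
The STAT lesion of model 29 is mapped as GOF; the source lists the gene
without a direction, and only an active STAT (suppressing ERK) reproduces
the documented BCL6+BCL2 co-activity in Pre-GC and DZ.

## Numerical choices and problem sizes

Fixpoint enumeration is an exhaustive, vectorized scan of all states
consistent with the inputs and clamps — at most 2^13·3^3 = 221,184 states
per GC stage, 2^16·3^3 = 1,769,472 for the whole space — processed in
chunks of 2^18 states to bound memory. No SAT/BDD machinery is used: at
this scale the scan runs in fractions of a second and stays fully
cross-checkable against independent oracles, which the test suite does with
R's own parser/evaluator as a second semantics and with a literal per-state
loop on small random networks. Fixpoints are reported in lexicographic
order of the state vector, networks are immutable values, and clamps are
stored in component order so that model files round-trip byte-stably. The
test suite sizes its stochastic checks at 50 random clamp sets for oracle
equivalence, 12 random small networks for the literal oracle, 1,000 random
genotypes for classifier totality, and 500 patients for cohort-shape
checks; these sizes are the package's chosen verification depth.

## Known limitations

* The single-regulator rules and the IRF4 chain are reconstructions; a
  published full rule table could differ in ways the attractor table does
  not expose.
* Fixpoints only: transient dynamics (e.g. the MYC pulse timing the
  dark-zone stay) are outside the formalism used here.
* All clamps are complete: no partial inhibition, no dose–response, no
  haploinsufficiency.
* The p53 axis, non-canonical NF-kB, and apoptosis (BIM) are not modeled;
  "no marker" is a surrogate, not a death read-out.
* The NF-kB class of receptor-only genotypes and the oncogenicity of
  models whose attractors are abnormal without any flagged marker (e.g. an
  NF-kB-dead, IRF4-driven model) follow this package's documented
  conventions, not a published rule.
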