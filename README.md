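# gclogic

Patient-specific logical modeling of germinal-center (GC) B-cell signaling
for diffuse large B-cell lymphoma (DLBCL).

DLBCL genomes are heterogeneous: each patient carries an individual
combination of mutations, copy-number alterations and structural variants in
the signaling pathways that keep a GC B cell alive. `gclogic` turns such a
genotype into a mechanistic prediction. It implements a multi-valued logical
network of GC B-cell signaling — BCR, CD40 and IL21/4 receptor inputs; PI3K,
MAPK, NF-κB and JAK/STAT signaling; and the stage markers BCL6, BLIMP1, MYC,
BCL2 (plus AID as an auxiliary read-out) — perturbs it with each patient's
lesions, and asks how the attractors of the GC reaction change and which
inhibitors restore a marker-free state.

## The model in brief

The network is a directed graph over 19 components. Each component `v`
carries a discrete activity level `s(v)`; most are Boolean, while IKKc,
NF-κB and IRF4 are ternary (`{0,1,2}`, level 1 = low/transient, level 2 =
high/sustained activity). Rules are formulas over thresholded atoms
(`X` ≡ `s(X) ≥ 1`, `X:2` ≡ `s(X) ≥ 2`) with `&`, `|`, `!`; a component
adopts the highest target level whose condition holds, e.g.

```
IKKc : 2 : 1 <- CBM ; 2 <- TRAF6
BCL6 : 1 : 1 <- IRF4 & !IRF4:2 & !(ERK | BLIMP1)
```

Attractors are fixpoints `f(s) = s` of the synchronous update, which are
invariant across update schemes; they are found by exhaustive scan of all
states consistent with an input assignment (≤ 221,184 states per stage,
1,769,472 for the whole space). The eight input combinations of
(BCR, CD40, IL21/4) map one-to-one onto GC stages; five are physiological:
LZ1 (no signal), Pre-GC, DZ, LZ2, PC.

Genetic lesions and drugs enter as *clamps* (components fixed at a level):
high-grade copy-number losses/gains map to loss/gain of function, mutations
and structural variants follow the gene's role (oncogene → GOF, tumor
suppressor → LOF), inhibiting gene→component edges invert the direction, and
GOF always clamps to the component's maximal level. Patient models are
profiled across the physiological stages, compared to wild type, flagged for
oncogenic behaviour (abnormal marker combinations, markers in the wrong
stage, loss of the PC exit or of the LZ1 resting state) and assigned one of
five NF-κB dependency classes (unperturbed, level 1, level 2, inactive,
independent). Four inhibitors — Ibrutinib (BTK), Copanlisib (PI3K),
Bortezomib (NF-κB), Venetoclax (BCL2) — and their combinations are simulated
as zero-clamps that override genotype clamps, scored by the number of stages
driven to the "no marker" state.

See the methods vignette (`vignettes/gc-logical-modeling.Rmd`) for the full
model description, design decisions and limitations.

## Worked example

Patient model 73 carries a single MCL1 alteration, mapped as a gain of
function onto BCL2:

```r
library(gclogic)

wt <- wild_type_profile()
wt
#> Attractor profile [model WT]
#>    1 LZ1       (BCR=0 CD40=0 IL21/4=0): none
#>    2 n.phys.2  (BCR=0 CD40=0 IL21/4=1) n.phys.: none
#>    3 n.phys.3  (BCR=0 CD40=1 IL21/4=0) n.phys.: BCL2
#>    4 n.phys.4  (BCR=0 CD40=1 IL21/4=1) n.phys.: BLIMP1+BCL2
#>    5 Pre-GC    (BCR=1 CD40=0 IL21/4=0): MYC+BCL2
#>    6 DZ        (BCR=1 CD40=0 IL21/4=1): BCL6 [AID]
#>    7 LZ2       (BCR=1 CD40=1 IL21/4=0): MYC+BCL2
#>    8 PC        (BCR=1 CD40=1 IL21/4=1): BLIMP1+BCL2

pm <- patient_model(genotype_to_perturbations(fixture_patients(),
                                              patient_id = "73"))
prof <- attractor_profile(pm)
prof
#> Attractor profile [model 73]
#>    1 LZ1       (BCR=0 CD40=0 IL21/4=0): BCL2
#>    5 Pre-GC    (BCR=1 CD40=0 IL21/4=0): MYC+BCL2
#>    6 DZ        (BCR=1 CD40=0 IL21/4=1): BCL6+BCL2 [AID]
#>    7 LZ2       (BCR=1 CD40=1 IL21/4=0): MYC+BCL2
#>    8 PC        (BCR=1 CD40=1 IL21/4=1): BLIMP1+BCL2

compare_to_wild_type(wt, prof)
#> 2 of the compared stages differ from wild type
#>   LZ1: aberrantly active BCL2
#>   DZ: aberrantly active BCL2

classify_oncogenic(prof)
#> Oncogenicity: ONCOGENIC
#>   abnormal marker combination: TRUE
#>   marker in wrong stage: FALSE
#>   PC loss: FALSE
#>   LZ1 loss: TRUE

classify_nfkb(pm)
#> [1] "unperturbed"
```

Two stages shift: the resting LZ1 state aberrantly expresses BCL2 (escape
from selection), and in the DZ the lesion breaks the BCL6→BCL2 repression so
both are active together — an abnormal combination, hence the oncogenic
flags. Ranking the seven default regimens shows that only treatments
containing the BCL2 inhibitor touch the clamped BCL2, and the
Bortezomib+Venetoclax combination clears every stage:

```r
rank_regimens(pm)[, 1:3]
#>     regimen no_marker_stage_count reachable_stage_count
#> 1 bcl2+nfkb                     5                     5
#> 2 bcl2+pi3k                     3                     5
#> 3      bcl2                     1                     5
#> 4      nfkb                     0                     5
#> 5       btk                     0                     5
#> 6      pi3k                     0                     5
#> 7      none                     0                     5
```

Cohort-scale runs work the same way from a lesion table
(`run_cohort()`, `run_drugs()`), and `generate_cohort()` produces synthetic
genotype tables with the documented statistical shape (BCL2 the most
frequent lesion, 1–10 mapped lesions per patient, COO-biased BCL2
alteration classes).

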