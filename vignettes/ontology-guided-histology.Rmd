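---
title: "Ontology-guided classification of cardiovascular histology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-guided classification of cardiovascular histology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonto)
```

## Overview

`histonto` classifies 10× histological images of the human cardiovascular
system block by block and then *corrects* that classification with domain
knowledge. The package has three scientific layers — texture description,
cascade classification, and knowledge-base refinement — plus a synthetic
fixture generator that makes every layer testable in isolation. This
vignette explains the model behind each layer, the tunable parameters and
their defaults, the numerical choices, and what the synthetic fixtures do
and do not demonstrate about real tissue.

## Texture description: LBP and its rotation-invariant form

Every 100×100 px block is converted to 8-bit grayscale (ITU-R BT.601
luminance, rounded; the choice of luminance weights is a plumbing decision —
any fixed grayscale projection works, but BT.601 is the common convention
for 8-bit RGB microscopy captures). Each interior pixel is encoded as

$$\mathrm{LBP}_{P,R} = \sum_{p=0}^{P-1} s(g_p - g_c)\,2^p,
\qquad s(x) = \begin{cases}1 & x \ge 0\\ 0 & x < 0\end{cases}$$

with $P = 8$ neighbors at radius $R = 1$, $g_c$ the center gray value and
$g_p$ the $p$-th neighbor. Two conventions had to be fixed:

* **Center vs neighbor.** We follow the standard LBP literature: the center
  is thresholded against, the neighbors contribute bits. (Some descriptions
  swap the two symbols in prose; the standard convention is the one under
  which the descriptor has its documented properties.)
* **Neighbor ordering.** Bit $p = 0$ sits at the east neighbor and the ring
  proceeds counter-clockwise. Raw LBP histograms depend on this convention
  (tests pin it down); the rotation-invariant histogram does not.

The rotation-invariant variant canonicalizes each 8-bit code to the minimum
over its 8 cyclic rotations. The 256 codes fall into exactly 36 rotation
orbits, so the LBPri histogram has 36 bins. A 90° image rotation shifts the
8-neighbor ring cyclically by two positions, which canonicalization absorbs;
the test suite asserts `lbpri_histogram(rot90(b)) == lbpri_histogram(b)`
exactly on random blocks.

The block descriptor concatenates both histograms: 256 + 36 = 292 values.

Numerical choices:

* **Border handling.** Pixels without a complete 8-neighborhood (the
  block's 1-px border) are skipped rather than padded: padding would
  fabricate intensities and bias the histogram toward artificial codes. A
  100×100 block therefore contributes $98 \times 98 = 9604$ codes, and the
  histogram total always equals the interior pixel count (a conservation
  law the tests check).
* **Normalization.** Each sub-histogram is L1-normalized before
  concatenation, so descriptors are comparable across block sizes and the
  SVM sees inputs on a stable scale. Raw-count mode is available
  (`describe_block(..., normalize = FALSE)`).

## Cascade classification

Blocks are labeled with one of six classes: smooth muscle of the elastic
artery (EA), of the large vein (LV), of the muscular artery (MA); cardiac
muscle of the heart (HE); loose connective tissue (LC); and light regions
(LR). EA and LV are the two most texture-similar classes, so classification
is a two-stage cascade:

1. a **linear five-class SVM** over {HE, MA, LC, LR, C1}, where C1 merges
   EA and LV;
2. a **binary polynomial-kernel SVM** (degree 3) consulted exactly when
   stage 1 answers C1, separating EA from LV.

The merged class never escapes: the final label set is always the six
classes above. Multi-class handling is libsvm's one-vs-one voting; vote
ties resolve by the fixed class order HE, MA, LC, LR, C1, which makes
predictions deterministic.

Parameters (all in `cascade_config()`):

| parameter | default | why |
|---|---|---|
| `cost1`, `cost2` | 100 | L1-normalized descriptors have per-feature magnitude ≈ 1/256; at cost 1 the linear stage underfits drastically (it collapses classes), while costs in the 10–1000 range separate the fixture classes perfectly. 100 sits in the flat middle of that range. |
| `degree` | 3 | the customary low-order polynomial for a binary split on histogram features. |
| `gamma` | 1/292 | libsvm's 1/dim scaling. |
| `coef0` | 1 | lets low-order polynomial terms contribute. |

Feature scaling inside libsvm is disabled (`scale = FALSE`): the
descriptors are already normalized, and per-feature rescaling of sparse
histogram bins would amplify empty-bin noise.

## The knowledge base

The refinement stage only ever needs one kind of answer from the domain
knowledge: *is this configuration possible?* — operationalized as whether a
`(subject, predicate, object)` fact exists. `histonto` therefore implements
the knowledge layer as a closed-world triple store over a fixed vocabulary
(four organs, four tissue terms, one epithelium type, two predicates)
rather than a full OWL ontology with a DL reasoner: emptiness vs
non-emptiness of a membership query reproduces the required behaviour
exactly, and closed vocabulary validation keeps "unknown term" errors
distinct from legitimately empty answers. Facts serialize to a restricted
Turtle subset (one triple per line, single namespace prefix) so knowledge
bases are plain, diffable text.

The default knowledge base contains:

* **no cross-organ `hasPresenceOf` facts.** Cardiovascular samples are
  prepared per organ, so a heart slide does not contain elastic-artery
  wall, etc. Every cross-organ presence query answers empty, which is what
  licenses the correction. Users modelling genuine co-presence (e.g. vasa
  vasorum in a large vessel's adventitia) can assert facts to suppress it.
* **`hasEpithelium` facts** linking each organ to `FlatSimpleEpithelium` —
  the endothelium/endocardium that lines vessel and heart lumina. A single
  epithelium type suffices at 10×; distinguishing flat/cubic/cylindrical
  epithelium by cell shape requires 40× magnification and is out of scope.

## Refinement

### Organ correction

Occurrences of the four discriminant labels are counted and the organs
present are ranked by count. For every ordered pair (higher rank A, lower
rank B) the rule *(A, hasPresenceOf, B)* is queried; an empty answer
reclassifies all blocks labeled with B's tissue to **loose connective
tissue**. LC is the right replacement because organ false positives arise
overwhelmingly on connective tissue: stain and texture variation in LC is
what gets mistaken for foreign muscle, so returning those blocks to LC
undoes the error rather than relocating it.

Design choices made where the procedure was genuinely open:

* **Rule generation is pairwise by rank** (k organs ⇒ k(k−1)/2 rules), which
  reproduces the worked rule lists for both the two-organ and four-organ
  cases, including rules whose subject is not the single top-ranked organ.
* **Ties** in occurrence counts are broken by the fixed priority
  HE > MA > EA > LV (cardiac muscle is the least confusable texture, the
  EA/LV pair the most), with a warning, since tied evidence cannot order
  organs on its own.
* **Single pass.** Occurrence counts are not recomputed between rules; the
  correction is one deterministic sweep in rule order. Iterating would let
  early corrections change later rankings with no principled stopping rule.

### Epithelium recognition

Flat simple epithelium cannot be seen directly at 10×, but it must line any
real lumen. The detector looks for that geometry:

1. **Size.** 4-connected components of LR blocks with at least
   `min_size = 10` members. "Ten or more consecutive blocks" could also be
   read as a linear run; components are the robust reading (a lumen is a
   blob, not a line) and contain runs as a special case.
2. **Neighbourhood.** At least one block 4-adjacent to the component must
   be muscle. This kills false positives from light areas between loose
   connective tissue or near the tunica adventitia. The qualifying set
   defaults to all four muscle classes {EA, LV, MA, HE}: descriptions of
   the restriction sometimes list only the three smooth-muscle classes, but
   epithelium is detected in heart images too, so cardiac muscle must
   qualify in practice. The set is a parameter
   (`qualifying_classes`) for sensitivity analysis.
3. **Knowledge.** The KB is asked which epithelium lines the dominant
   organ. An empty answer means "probably no epithelial tissue here" and
   changes nothing.
4. **Placement.** The component's cells that touch muscle — the LR side of
   the lumen/muscle limit — become EP. The lumen side is relabeled (not the
   muscle side) because epithelium lines the lumen; interior LR cells stay
   LR.

`refine()` applies organ correction first, then epithelium detection, and
is idempotent: corrected matrices contain a single organ (so no further
rules fire), and after boundary cells become EP the remaining interior LR
cells no longer touch muscle.

Label conservation holds by construction: refinement only ever makes the
transitions {EA, LV, MA, HE} → LC and LR → EP.

### Threshold calibration

The lumen-size threshold is calibrated by exhaustive search over integer
candidates, minimising the total annotation error

$$\mathrm{Ae}(t) = \sum_i \lvert \rho_g - \rho_i(t) \rvert$$

where $\rho_i(t)$ is the refined matrix at threshold $t$ and $\rho_g$ the
ground truth. For categorical matrices the absolute difference is realised
as the **Hamming distance** (number of disagreeing cells) — the natural
metric-space reading of $|\cdot|$ for label grids. Ties go to the smallest
threshold (prefer the more sensitive detector when the data cannot
distinguish). On synthetic calibration problems whose ground truth was
built with threshold 10 — and which always contain runs of exactly 9 and 10
blocks, so neighbouring thresholds are distinguishable — the sweep recovers
t\* = 10.

## The synthetic fixture generator

The generator emulates exactly the statistical structure the pipeline
relies on, and nothing more:

* **Per-class textures** are oriented sinusoidal gratings plus Gaussian
  noise on a stain-palette base color (pink/violet muscle tones, pale blue
  connective tissue, near-white light regions). Orientation/frequency pairs
  are pairwise distinct across the six classes so LBP histograms separate
  by construction; LR has the lowest pixel variance of all classes, as
  lumina do. Blocks are bit-reproducible from `(class, seed)`.
* **Organ layouts** are concentric: an LR lumen disk, a muscle annulus of
  the organ's class, an LC surround (the geometry of a vessel cross
  section). The ground-truth matrix marks lumen cells adjacent to muscle as
  EP — what a perfect annotator would draw. At the reference geometry
  (2048×1536 px) the grid is 15×20 = 300 blocks; 20 images give 6000
  blocks. Lumen/annulus radii scale with the grid and are validated to fit.
* **Corruption** swaps the *texture* of randomly chosen LC cells to a
  foreign organ's class while leaving the truth label LC. A classifier
  trained on clean textures then mislabels exactly those blocks — genuine
  classifier errors of the kind the organ correction removes. Corrupting
  connective tissue (rather than the muscle annulus) is deliberate: it is
  the error mode for which LC is the correct replacement label, matching
  the false-positive analysis that motivates the correction; corrupting
  muscle cells would create errors the correction *cannot* fix (their truth
  is the organ, not LC) and would make the post-correction connective
  F-score fall, contradicting the improvement the procedure is designed to
  deliver.
* **Dataset splits** are at the image level, 70/30 by default, assigned
  before tiling — block-level splitting would leak near-identical texture
  between train and validation.

What passing tests on these fixtures *show*: the descriptor algebra, the
cascade contract, the rule engine, the epithelium geometry and the
calibration recovery are implemented correctly, and refinement strictly
improves per-class F-scores under the corruption model. What they *do not
show*: performance on stained tissue. Real H&E/trichrome blocks are not
gratings; inter-class texture overlap, staining variability and mixed-tissue
blocks make real F-scores substantially lower than the near-perfect fixture
scores, and the headline fixture numbers must not be quoted as expected
clinical performance.

## Problem sizes and determinism

The test suite and the acceptance checks run at deliberately modest sizes
chosen to exercise the study conditions: the full 20-image, 6000-block
dataset for the end-to-end cascade check; 100 seeded calibration problems
for threshold recovery; 3 seeds × 4 corruption rates × 4 organs for the
monotone-improvement property. Every stochastic step derives its stream
from an explicit integer seed (`with_seed` preserves the caller's RNG
state), so datasets, models and reports are bit-reproducible.

## Known limitations

* The four-organ vocabulary is closed; adding organs (or positive
  co-presence facts) means editing the vocabulary and the default KB, not
  just data files.
* Blocks receive exactly one label even when they straddle tissues;
  mixed-content blocks are a known error source at region boundaries.
* The classifier offers no confidence scores, so refinement treats all
  classifier labels as equally trustworthy evidence for ranking.
* `min_size = 10` is calibrated for 100×100 blocks at 10×; other
  magnifications or block sizes require re-calibration
  (`calibrate_threshold()`).
* The Turtle reader accepts only the package's restricted subset — it is a
  persistence format for this vocabulary, not a general RDF parser.
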