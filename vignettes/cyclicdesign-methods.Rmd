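---
title: "Designing sequences for head-to-tail cyclic peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sequences for head-to-tail cyclic peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Head-to-tail cyclic peptides — macrocycles whose C-terminal carbonyl is
amide-bonded back to the N-terminal nitrogen — are attractive
therapeutics, but designing amino-acid sequences that actually fold into
a given macrocyclic backbone is hard: general-purpose inverse-folding
models are trained almost exclusively on linear proteins, where small
rings are essentially absent. `cyclicdesign` implements the full
in-silico loop for attacking this: generate ring-closed backbone
ensembles, design sequences onto them with a backbone-graph
message-passing network that understands ring topology, filter the
designs by how well predicted structures match their targets, and
fine-tune the network on the survivors with redundancy-aware clustering
and perplexity-based checkpoint selection.

This vignette explains the models, their assumptions, the tunable
parameters, and the design choices made where the problem left the
design genuinely open. Everything quantitative below is computed by the
package's test-suite or by `scripts/acceptance.R`; the vignette itself
states no number the code does not reproduce.

## Backbone representation and geometry

A backbone is the per-residue N, CA, C, O coordinate set plus a flag for
head-to-tail cyclisation. Internal coordinates (phi, psi, omega in
degrees, wrapped to (-180, 180]) convert to Cartesian coordinates by
sequential NeRF placement under ideal covalent geometry (N-CA 1.458 Å,
CA-C 1.525 Å, C-N 1.329 Å, C=O 1.231 Å; angles N-CA-C 111.2°, CA-C-N
116.2°, C-N-CA 121.7°, CA-C=O 120.1° — standard polymer values, all
configurable). Residue 1 sits in a canonical frame (N at the origin, CA
on +x, C in the xy-plane).

Two conventions worth knowing:

* **Round trips.** Building coordinates from a cyclic torsion set yields
  an *open* chain; the wrap dihedrals (phi of residue 1, psi/omega of
  residue L) are measured against the actual residue-1 atoms and
  therefore only match the inputs once the ring is closed. The
  torsion-to-Cartesian round trip is exact (to 1e-4°) at every
  sequentially placed position; wrap positions agree to within the
  closure tolerance on closed rings.
* **RMSD.** Backbone RMSD is computed after optimal (Kabsch)
  superposition over the selected atoms — predicted and reference
  structures generally arrive in arbitrary frames. No cyclic-permutation
  search is performed: residue numbering is taken as given. The SVD
  implementation is cross-checked against an independent
  quaternion-eigenvalue oracle in the test-suite.

## The Ramachandran model and the conformational sampler

Sampling is residue-type-agnostic (poly-alanine semantics), so one
dihedral-preference model serves all positions. The density is a
four-basin wrapped-normal mixture over (phi, psi): alphaR (-63, -41),
beta (-120, 130), polyproline II (-75, 150) and alphaL (60, 45), with
weights 0.35 / 0.30 / 0.25 / 0.10. The pseudo-energy is the
max-normalised negative log density, so the most probable conformation
has energy 0 and the sampler's rejection rule "any residue above energy
2" mirrors the usual lookup-table cutoff semantics.

**Basin spread.** The basin spread defaults to 25°. This was chosen so
that the energy-below-2 region covers roughly a sixth of the
Ramachandran plane, comparable to a real alanine dihedral map. With a
much tighter spread (for example 15°) the allowed region shrinks to
about 7% of the plane, and closed rings whose every residue is allowed
become so rare that ensemble generation at practical scale is
impossible: we measured iid basin-assignment feasibility of only 6–18%
for 6–10-mers *even with an oracle-quality per-assignment optimiser*,
versus 27–73% at 25°. The spread (like every basin parameter) is
user-configurable, and users with access to a real Ramachandran lookup
table can substitute their own basin table.

**Ring closure.** Sampled torsions are independent draws, and
independent draws essentially never lie on the closed-ring manifold, so
closure must deform them. Plain cyclic coordinate descent (CCD, the
classic loop-closure iteration; provided as `close_ring()` with both a
compiled and a pure-R engine) closes reliably but distorts torsions by
>150° — the closed ring it finds has nothing to do with the sampled
basins, and the energy filter then rejects ~99.98% of its outputs. Two
structural facts drive the final algorithm:

1. A trans peptide unit with strictly ideal bond angles can only "turn"
   by roughly 53–74° per residue, so many basin assignments admit *no*
   ideal-geometry closed ring at all. Real macrocycles flex their
   backbone bond angles by a few degrees; the sampler therefore treats
   the three backbone bond angles per residue as tightly tethered
   degrees of freedom (spread 2.5°, `angle_flex_sigma`).
2. Demanding that every residue reach a *pre-assigned* basin is stricter
   than the actual filter (any basin with energy <= 2 is fine), but a
   barrier-free objective per assignment turns optimiser failure into a
   clean verdict on that assignment's feasibility.

`close_ring_rama()` therefore runs a projected Gauss-Newton descent on
the closure manifold: torsions are tethered to the sampled
maximum-posterior basin centers, bond angles to ideal geometry; the
closure constraint (the virtual end triad meeting the real residue-1
triad) is maintained by Newton restoration after every tangent step,
with all steps taken in the metric defined by the tether variances so
stiff angle DOFs absorb almost none of the closure correction. The
sampled start plus up to three jittered restarts around the assigned
centers are tried; a failure means the sampled basin assignment admits
no closed allowed ring and the attempt is rejected — exactly the
rejection-sampling semantics of kinematic-closure pipelines, where an
analytic solver plays the role our optimiser plays here.

`generate_ensemble()` chains sample → restrained closure → Ramachandran
filter (re-measured on the *closed* conformation, including the wrap
phi) → backbone hydrogen-bond filter, until the requested count or an
attempt cap (50x by default) is reached. Everything is deterministic
given the seed. Acceptance rates are an emergent property of this
sampler and are not comparable to those of other closure engines.

## Hydrogen bonds

The dataset filter requires at least 1, 2 and 3 backbone-backbone
hydrogen bonds for 6-, 8- and 10-mers (other lengths extrapolate as
`ceiling((L-4)/2)`, floored at 1). Since backbone PDBs carry no
hydrogens, amide H positions are constructed at 1.01 Å from N on the
external bisector in the C(prev)-N-CA plane. A bond requires H...O <=
2.5 Å, N-H...O angle >= 120° and cyclic sequence separation >= 2; every
donor reports at most its closest qualifying acceptor (so bifurcated
geometries are not double-counted), while acceptors may serve several
donors. A DSSP-style electrostatic criterion is deliberately not
implemented; the geometric criterion is simple, configurable and
testable against a brute-force scan, which the suite asserts on every
fixture and on sampled backbones.

## The sequence-design model

The inverse-folding network is a residue-graph message-passing
encoder-decoder in the style of fixed-backbone design models, written
directly in R matrix algebra with hand-derived backpropagation
(verified against finite differences in the test-suite).

* **Features.** k nearest neighbours by CA distance (default
  `min(L-1, 32)`); each directed edge carries 16-center radial basis
  encodings (2–22 Å) of the 25 ordered inter-atom distances over
  {N, CA, C, O, virtual CB} of the two residues, plus a one-hot relative
  position. The virtual CB is placed by the standard chiral tetrahedral
  construction, which is what lets distance-only features distinguish
  phi from -phi. For macrocycles the relative position is the *cyclic*
  offset — the signed minimal distance around the ring,
  `((j - i + floor(L/2)) mod L) - floor(L/2)`, antipodal ties to -L/2 —
  so the network respects the ring's rotational topology; the test-suite
  verifies full rotational equivariance of the conditional
  distributions. The offset flavour is a config switch (`cyclic`),
  default on.
* **Architecture.** Edge embedding, then 3 encoder and 3 decoder layers
  of width 128 by default (tests and toy runs use 64 and 2+2): messages
  are three-layer MLPs over concatenated endpoint states and edge
  embeddings, mean-aggregated, with residual + layer-norm node updates
  and a position-wise feed-forward block. The decoder sees the sequence
  embedding of a neighbour only if that neighbour is earlier in the
  decoding order, and sees the *encoder* state of later neighbours, so
  the autoregressive factorisation is exact. Edge embeddings are not
  updated across layers (a simplification relative to the largest
  published models; adequate at peptide scale).
* **Scoring and sampling.** The model score of a sequence is its mean
  per-residue negative log-likelihood in nats under teacher forcing
  (fixed left-to-right order by default; perplexity = exp(score)).
  `decode_sample()` draws a uniformly random decoding order and samples
  positions sequentially from temperature-scaled categoricals;
  `design()` draws n = 5 samples and keeps the best-scoring one — the
  standard best-of-five workflow. A zeroed output head scores every
  letter at exactly -log(1/20), which the tests use as a calibration
  anchor.

## Training

`finetune()` optimises smoothed cross-entropy (label smoothing 0.1) with
Adam under an inverse-sqrt warmup schedule and global gradient clipping
at 1.0; backbone coordinates are perturbed with 0.1 Å Gaussian noise at
every visit, and decoding orders are resampled per example. Sequences
are clustered by greedy 30%-identity clustering (descending length then
lexicographic visiting order, ungapped best-offset identity), splits are
made at cluster granularity, and each epoch draws one member per
training cluster from an epoch-specific RNG stream derived from the
master seed (`seed + epoch`), so runs are bit-reproducible. For
deliberately redundant datasets (such as the three-letter rule dataset
below, which collapses into a handful of clusters) `cluster_sampling =
FALSE` visits every training record each epoch. Validation perplexity is
evaluated and a checkpoint stored every `eval_every` epochs;
`select_checkpoint()` returns the lowest-validation-perplexity
checkpoint, ties to the earliest epoch — the standard
stop-before-overtraining selection rule. Default epochs: 200.

Because reproducing published benchmark numbers would require external
trained folding models, training acceptance is *parameter recovery*: the
fixture module emits datasets whose sequence is a deterministic function
of local backbone geometry (`basin-letter`: G for positive phi, A for
the alpha band (phi <= 0, psi in [-100, 10)), V otherwise) which a sound
implementation must be able to learn essentially perfectly. The
acceptance suite trains a 64-wide 2+2-layer model from random
initialisation on 200 noisy (0.02 Å) 8-mers and requires >= 90%
teacher-forced recovery on 50 held-out examples; it also requires a toy
model to memorise 20 random structure-sequence pairs to perplexity
< 1.3. Both pass with large margins (recovery is typically 100% within
a few dozen epochs). Passing these says the pipeline can extract a
geometry-to-sequence mapping that is actually present; it does not say
anything about performance on real, statistically ambiguous data.

## Evaluation statistics

* `p_near()`: the folding-funnel statistic
  `P_Near = sum_i exp(-r_i^2/lambda^2) exp(-E_i/kT) / sum_i exp(-E_i/kT)`
  over an ensemble of (RMSD-to-native, energy) samples, computed with
  the log-sum-exp trick; invariant to energy offsets and sample order,
  monotone in the quality of low-energy samples. Defaults lambda =
  1.5 Å, kT = 0.62 follow common macrocycle practice; both are
  mandatory-explicit in configuration files because the literature
  rarely prints them. A "stable peptide" call is a user-chosen P_Near
  cutoff — no default is shipped, since published funnel criteria are
  under-specified.
* `sequence_recovery()`, `uniqueness_counts()`: exact positional match
  fraction and exact multiset accounting.
* `best_prediction_rmsd()`: lowest-RMSD selection among several
  predicted structures, ties to the earliest — the standard
  best-of-five post-folding rule.
* `summarize_designs()`: per-length medians/means with the midpoint
  convention for even sample counts.

## The pipeline and its folding hook

`run_pipeline()` wires the stages together: sample → design → fold →
filter → optional fine-tune → evaluate, writing every artifact
(backbone PDBs, versioned TSV tables, config snapshot) with
deterministic bytes. A single master seed fans out to fixed per-stage
offsets, so changing it changes every stage and fixing it fixes
everything.

Structure prediction itself is out of scope: the folding stage is a
pluggable hook. `method = "command"` invokes a user command template
(producing predicted PDBs) per design; `method = "perturb"` — the
default, and what all tests use — stands in for a predictor by
perturbing the design's own backbone with Gaussian noise (sigma 0.3 Å, 5
predictions, best-of-N by RMSD). The perturbation oracle produces
RMSD distributions with realistic bookkeeping but *no dependence on
sequence quality*; pipeline-level results under it exercise plumbing,
determinism and filter logic, not design skill.

## Numerical choices and degenerate inputs

* Closure tolerances: 0.05 Å on the C(L)-N(1) bond deviation, 5° on the
  flanking bond angles; the restrained closure drives energies to 90% of
  the cutoff so accepted conformations sit strictly inside the filter.
* The relax loop abandons an attempt after 25 iterations without
  improvement of the worst residue; with three restarts this gives the
  best throughput per accepted conformation of the settings we measured.
* Ties: best-of-n design and best-prediction selection take the earliest
  of equal scores; checkpoint selection takes the earliest epoch of
  equal perplexities; greedy clustering joins the first qualifying
  centroid.
* Degenerate inputs fail loudly: too-short backbones, missing atoms
  (named by residue), unknown configuration keys (named by path),
  non-finite coordinates, empty P_Near ensembles.
* Problem sizes in the shipped tests are chosen for a laptop-class
  single core: ensembles of 200 per length for the sampler contract,
  training runs of 20-250 examples at hidden width 64. All scale up by
  configuration.

## Known limitations

* The Ramachandran mixture is a four-basin cartoon of a real
  residue-specific dihedral map; substitute a table for serious work.
* The closure search is a local optimiser with restarts: per-assignment
  feasibility verdicts are sound in practice but not certificates, and
  acceptance rates will differ from analytic kinematic solvers.
* Sampler outputs carry a few degrees of bond-angle strain (bounded by
  the tether spread), like real structures but unlike strictly ideal
  chains.
* The model is small and trained from scratch; nothing here loads
  published pretrained weights, and no claim is made about matching
  published design benchmarks, which depend on external folding models.
* D-amino acids, non-canonical residues, side-chain-aware design and
  multi-chain complexes are out of scope.
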