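---
title: "protocode: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protocode: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Classic explanations of the genetic code's error robustness lean on natural
selection over replicating lineages — yet high-fidelity replication itself
presupposes a decent code. `protocode` implements the alternative scenario in
which a community of protocells, none of which reproduces or is selected,
exchanges fragments of their translation machinery horizontally, and each
receiver adjusts its own code to be more like its donors'. The question the
simulator addresses is whether regularity, error robustness and (near)
universality can emerge from that interaction loop alone.

## The model

**Translation black box.** Each protocell's translation system is a 3–6–11
multilayer perceptron. Inputs are the three codon base positions with
U = 0, C = 0.3, A = 0.7, G = 1 — pyrimidines and purines deliberately occupy
opposite halves of the input range, with a 0.3 within-class and 0.4
between-class gap. Hidden and output nodes use the logistic
$y(v) = (1+e^{-v})^{-1}$ and each receives a bias weight. All 101 weights are
initialised i.i.d. uniform on $[-0.1\sqrt3, +0.1\sqrt3]$ — the unique
zero-mean uniform with standard deviation 0.1 (a Gaussian alternative sits
behind `init = "gaussian"`).

**Chemical space.** The 11 output dimensions are: min–max-normalised van der
Waals volume, side-chain pKa, logP and molecular weight, plus seven 0/1
flags — side-chain C, N, O, S and benzene ring, and two backbone types
(primary α-amine vs proline's cyclic secondary amine). Min–max over the 20
encoded amino acids is the only normalisation that achieves the stated
$[0,1]$ range exactly, and it pins each property's extremes to 0 and 1 (this
is asserted in the test suite). All 20 amino acids are pairwise distinct in
the space; the closest pair is Ile/Leu at Euclidean distance 0.057, which
matters below.

**Decoding and the obverter.** A codon decodes to the amino acid nearest its
output point (Euclidean; ties broken by alphabetical three-letter code, which
makes decoding deterministic). To *signal* an amino acid, a donor uses the
obverter rule: scan all 64 codons and pick the one whose own decoded output
lies closest to the target's chemical-space vector, ties broken by canonical
codon order (lexicographic over U, C, A, G). Because the chosen codon need
not be assigned to that amino acid in the donor's own table, transmission
carries an emergent, unparameterised error rate — the model's only source of
novel assignments. We implement no additional explicit noise (an ambiguity in
the source material; the emergent mechanism alone suffices for the observed
diversification).

**Horizontal transfer.** Per transfer: draw an ordered (donor, receiver)
pair uniformly from the $N(N-1)$ possibilities; sample 10 *distinct* amino
acids without replacement, each draw proportional to cellular relative
amino-acid abundance (cRAAA) over all 20 amino acids (not just those the
donor encodes — restricting the pool removes the novelty channel and, in our
experiments, freezes the population at expressivity 1); pair each with the
donor's obverter codon; train the receiver on the 10 (codon encoding, target
amino-acid vector) pairs for 500 shuffled online passes at η = 0.1.

**Training target: idealised vector, not donor output.** The source text can
be read as comparing the receiver's output either to the donor network's raw
output or to the target amino acid's canonical vector. We transmit the
canonical vector. The donor-output reading was implemented and rejected on
the evidence: copying reachable (interior) outputs makes the population
collapse immediately onto a constant consensus function with expressivity 1
and universality 0, eliminating the error mechanism the model depends on.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `population` | 16 | community size N |
| `transfers` | 100,000 | transfers per run (desk experiments use 2,000–8,000) |
| `pairs_per_transfer` | 10 | fragment size; more pairs homogenise faster |
| `epochs` | 500 | training passes over the fragment per transfer |
| `learning_rate` | 0.1 | backpropagation η |
| `interval` | 500 | metric recording cadence (transfers) |
| `runs` | 50 | replicate count for averaged series |
| `seed` | — | master seed; fully determines a run |

## Provenance of the built-in amino-acid table

The original work defers its exact property values to supplementary material
that is not available to this implementation, so
`inst/extdata/amino_acids.tsv` is a documented stand-in assembled once from
the cited *kinds* of sources: standard van der Waals volumes and experimental
logP compilations, side-chain pKa for the seven classically ionisable side
chains (Asp 3.65, Glu 4.25, His 6.0, Cys 8.28, Tyr 10.07, Lys 10.53,
Arg 12.48) with a neutral placeholder 7.0 for the rest, standard residue
molecular weights, Woese's polar-requirement scale (the Δ_code axis), a
UniProt-style average protein composition as the cRAAA transfer weights, and
a three-way complexity classification (sulfur = Cys/Met; simple = the ten
low-cost/early amino acids Gly, Ala, Ser, Thr, Asp, Glu, Val, Leu, Ile, Pro;
complex = the remaining eight). The backbone flags encode primary α-amine
(19 amino acids) vs cyclic secondary amine (Pro) — our reading of a
classification the source does not reproduce. Every value can be overridden
by passing a file in the same format to `amino_acid_table()`; validation
rejects missing fields, duplicate names and non-binary flags, naming the
offending row.

## The Δ_code calibration

"Mean square difference in polar requirement", averaged "over all codons",
admits four readings: squared vs absolute differences, and stop codons
excluded from both roles vs kept as diluting neighbours. Before freezing the
implementation we computed all four on the standard code with the canonical
polar-requirement values. Only one — squared differences, per-codon mean over
*sense* neighbours only, then mean over the 61 sense codons — reproduces the
reference value 5.24 (it gives 5.2400; pooling all neighbour pairs instead of
averaging per codon gives 5.19, the classic Haig–Hurst variant; the absolute
scale gives 1.45). That reading is the default and the adjudication is
re-run in `test-acceptance.R`. For simulator tables all 64 codons
participate; stop codons exist only in the bundled standard-code comparator.

## What the synthetic world does and does not establish

The simulator *is* the stated world: no external data enter. Its initial
populations are near-degenerate — a fresh network's outputs barely vary
across codons, so mean initial expressivity is ≈ 1.1 (the "few amino acids
initially encoded" regime), and early transfers *diversify* the receivers
faster than they assimilate, so donor–receiver distance can rise before the
convergent regime takes over a few hundred transfers in. Green tests
establish the qualitative claims at desk scale: expressivity rising from ~1
toward 20; mean pairwise table distance declining after its early peak; the
evolved codes' Δ_code falling far below the random-code null; and the three
regularity directions (simple class over complex and sulfur even after
correcting for class size, assignment counts increasing with transfer weight
and decreasing with molecular weight). They do *not* establish the
full-scale printed magnitudes (e.g. final universality near 17/64, or a
best expressivity-20 code below the standard code's 5.24), which require
50 × 100,000-transfer runs outside the test budget; the desk-scale numbers
move monotonically in those directions as runs lengthen.

Real biology the model deliberately omits: stop/start signals, mRNA context
and wobble, any chemically explicit learning substrate, and amino acids
beyond the canonical 20.

## Numerical and design notes

* The printed activation "(1 ∗ e^{−v})^{−1}" is read as the standard
  logistic (1 + e^{−v})^{−1}; it is called a logistic function and must map
  into (0, 1).
* Training is online stochastic gradient descent: the full gradient of the
  per-sample error is computed from the pre-update weights, then applied;
  presentation order is reshuffled every pass (Fisher–Yates on R's RNG).
  The backpropagation is verified against central-difference gradients at
  1e-6 relative error in the gradient-vector norm — componentwise relative
  checks are meaningless for the near-zero input-layer components, whose
  finite-difference error floor is ~1e-5.
* One RNG stream: initialisation, pair choice, fragment sampling and
  training shuffles all consume the single seeded R stream in a fixed
  order. Metric recording consumes no randomness, so the recording cadence
  cannot perturb trajectories; a single stream keeps runs bit-reproducible
  (same config + seed ⇒ identical metrics, codes and weights, asserted in
  the suite). Replicate runs derive distinct sub-seeds from the master seed.
* Weighted sampling without replacement is R's `sample(prob = )`, which is
  exactly the successive-renormalised-draws scheme; its inclusion
  probabilities are checked against exact enumeration on a 5-element,
  2-draw miniature.
* Network checkpoints and codon tables serialise to JSON/TSV; doubles are
  written with 17 significant digits, which round-trips IEEE doubles.
* A 3–6–11 network cannot represent an *arbitrary* 64→20 labelling (random
  tables plateau near 12 decoded amino acids); the capacity claim holds for
  the smooth, neighbour-respecting tables the obverter/assimilation loop
  actually produces, and the suite verifies that 20 distinct codons can be
  trained to express all 20 amino acids. Near-duplicate amino acids
  (Ile/Leu at distance 0.057) are the slowest to separate, and account for
  most residual decode mismatches after heavy training.

## Known limitations

* The stand-in property table reproduces the model's qualitative behaviour
  and the 5.24 calibration anchor, but individual evolved-code statistics
  will differ in detail from results computed with the original
  (unavailable) property values.
* Desk-scale runs stop at a few thousand transfers; the printed full-scale
  magnitudes are approached but not reached at that scale.
* The early diversification phase means "assimilation reduces donor–receiver
  distance" holds in the evolving regime, not from fresh initialisation —
  the property test samples populations ~600 transfers in.
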