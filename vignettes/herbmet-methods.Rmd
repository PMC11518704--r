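---
title: "Methods: exact-mass annotation, metabolic fate, and target screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-mass annotation, metabolic fate, and target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbmet)
```

herbmet implements the computational chain used when a multi-herb decoction
is profiled by high-resolution LC-MS/MS and its constituents are then traced
through the body and screened against protein targets: (1) exact-mass and
diagnostic-fragmentation annotation of centroided MS/MS spectra against a
compound library, (2) assignment of sequential-metabolism fate labels from
presence/absence observations across in vitro and in vivo sample matrices,
and (3) a bilinear attention drug–target interaction network for ranking
candidate bioactive metabolites. A fourth module generates synthetic inputs
with known ground truth for all three stages, so the whole chain is testable
without instrument data.

## Exact-mass arithmetic

All m/z computation reduces to monoisotopic masses summed from a shipped
IUPAC atomic-mass table (six or more decimals per element) plus CODATA
proton and electron masses. Four singly charged ion species cover the
chemistry in scope: `[M-H]-`, `[M+H]+`, the formate adduct `[M+COOH]-`
common for saponins in formic-acid mobile phases, and the intrinsic cation
`M+` for permanently charged quaternary alkaloids. For the last of these the
supplied formula is the cation's own composition and only the electron mass
is subtracted; treating the printed "[M+H]+" label of quaternary alkaloids
this way reproduces the observed ions (e.g. a berberine-type C20H18NO4
cation at m/z 336.1230) where naive protonation would be 1 u off. m/z values
are reported rounded to 4 decimals by convention, but every comparison in
the package is tolerance-based (ppm), never string equality. Multiply
charged species and isotope patterns are out of scope.

Reported deviations between theoretical and observed masses in
reference-grade spectra reach about 3 ppm, so the shipped defaults are 5 ppm
for precursor matching and 10 ppm for fragments; tighter settings would
reject genuine matches of the very examples the rulebase is built from.

## The fragmentation rulebase

Compound classes in this chemistry fragment in characteristic ways:
anthraquinones lose CH3/CO/CO2 singly and in sequence, the coumarin lactone
loses CO and CO2 consecutively, flavonoid C-rings open by retro-Diels-Alder
(RDA) cleavage, glycosides shed glycosyl residues (glucose 162.0528 u,
rhamnose 146.0579 u), aporphine alkaloids expel dimethylamine, amino acids
lose NH3 and the carboxyl as formic acid. The rulebase encodes each class as
a set of ordered neutral-loss chains plus optional fixed product-ion
formulas for RDA ions (e.g. C7H3O4- at 151.0037 for flavones). Encoding RDA
products as fixed ion compositions rather than bond-level chemistry is
deliberate: the reasoning this reproduces operates at the formula level, and
it keeps the engine structure-free.

Some printed fragment labels in reference work are shorthand rather than
elemental bookkeeping — a "[M+H-COOH]+" that is numerically a 46.0055 u
formic-acid loss, or an "-H2O-COOH" that is numerically H2O+CO2. The shipped
chains encode the numerically verified losses. Radical (odd-electron) losses
such as CH3 and the H of flavonol radical aglycones are tracked with an
electron-parity flag so product compositions stay integral.

A class score for a spectrum is the matched weight fraction of the rule's
entries *applicable* to the candidate precursor (chains that are elementwise
subtractable, product ions contained in the precursor ion). All shipped
weights are 1 and a single matched entry suffices for a class call; the
source methodology gives no quantitative weighting scheme, so this choice is
the simplest defensible one and is flagged in the output metadata
(`minimum_hits`). Chain expansion is capped at depth 3 by default (the
deepest routinely printed ladders); a few glycoside ladders need depth 4,
which callers request explicitly.

## Annotation tiers

Candidates are found by precursor exact mass (polarity-compatible species
only), scored by their class rule, and tiered the way reference-standard
profiling reports identifications: `identified_with_standard` needs a
retention-time match within ±0.2 min of a library reference plus a class
score of at least 0.5; `tentatively_characterized` needs the precursor match
and at least one diagnostic hit; everything else is `unmatched`. Exact-mass
isomers are never merged — both candidates are reported, and only retention
time separates, say, the catechin diastereomers or the three caffeoylquinic
acids, exactly as standards-based work resolves them. Ranking is
deterministic: tier, then class score, then |precursor ppm|, then name.

Per-peak explanation is a breadth-first search over the neutral-loss
vocabulary for the shortest loss path reaching each fragment within
tolerance, with at most one odd-electron step per path (matching observed
radical ladders and preventing combinatorial blow-up) and heavier losses
tried first, so glycosidic cleavages lead the reported path.

Collision-energy stepping in acquisition is not modelled; spectra are
treated as merged peak lists.

## Sequential metabolism

The fate module reasons over seven matrices: the dosed extract (prototype
universe - every compound is present), artificial gastric juice,
mesenteric-vein plasma (intestinal absorption), femoral-vein plasma
(hepatic passage), systemic plasma, urine and feces. Fate labels are a
deterministic truth table: absence from gastric juice means degradation in
the stomach; presence in any of the three plasma-derived matrices means
absorbed (the sampling routes are complementary, so the union is the
defensible pooled claim); presence in mesenteric- but absence from
femoral-vein plasma indicates hepatic first-pass removal; presence
post-hepatically but absence from systemic plasma indicates clearance.
Excretion is the subset of {urine, feces} detected. Presence is boolean at
the caller's detection threshold; intensity-based presence calling and
parent-to-metabolite linkage are out of scope, since the reproduced workflow
reports prototype detect/non-detect only.

## The screening model

The drug–target stage follows the bilinear attention interaction network
family. A molecule's SMILES is parsed (ChemmineR/OpenBabel) into a graph
whose nodes carry the standard 74-dimensional atom descriptor (atom type 43,
degree 11, implicit H 7, formal charge 1, radical electrons 1, hybridization
5, aromatic flag 1, total H 5 - one-hot within blocks). Three graph
convolutions over the symmetrically normalized adjacency with self-loops
produce node-level drug features; the representation is kept at node level
for local interaction modelling. Proteins pass through a trainable 23-symbol
embedding and three 1D convolutions (kernels 3/6/9), each output row
describing a subsequence. A bilinear interaction map scores every (atom
node, subsequence) pair, softmax attention over all pairs weights a bilinear
pooling into a joint representation, and a fully connected head with sigmoid
output gives the interaction probability. Binary cross-entropy is minimised
with Adam.

Since aromaticity and hybridization are not stored in kekulized connection
tables, they are perceived with documented heuristics: a 5- or 6-ring is
aromatic when every ring carbon takes part in an in-ring double bond
(heteroatoms exempt), and hybridization follows bond orders (aromatic or one
double bond: sp2; triple or two doubles: sp; else sp3). These cover the
chemistry of the fixture library and the synthetic grammar; exotic ring
systems may be approximated.

Dimensions, kernel sizes, learning rate and batch size are not dictated by
the reproduced methodology; defaults follow the configuration family of the
cited network (feature dimension 128, kernels 3/6/9, Adam 5e-4, batch 64)
and everything is overridable through `dta_config()`. The protein embedding
is initialized one-hot in the first 23 latent dimensions (zero elsewhere):
the first convolution then sees raw residue identity from the first step, so
a linear k-mer detector exists at initialization - with few informative
examples this materially accelerates motif discovery compared to random
embeddings, and the embedding remains fully trainable. Node caps follow the
protein convention: molecules above `theta_d` heavy atoms truncate with a
warning. Virtual-node padding and sequence padding are masked by
construction (the encoders operate on real atoms and effective lengths), so
padding can never change an output - a property the test suite asserts
bit-exactly. The adversarial domain-adaptation branch of the cited framework
is out of scope: the reproduced experiments are in-domain.

Training defaults reflect the prevalence structure of curated bioassay
data: the binary cross-entropy is class-weighted (positives weighted by the
negative/positive count ratio, `class_weight = "balanced"`), the learning
rate follows a cosine decay, and when a validation split is supplied the
returned parameters are the best-validation-AUPRC checkpoint. The class
weighting matters most: at ~13% positives the gradient from the rare
informative positives is otherwise swamped and the optimizer settles on
marginal-feature solutions; with balanced weighting the planted-rule
recovery benchmark in the test suite passes with a wide margin. All three
behaviours are configurable. With a fixed seed a run is bit-reproducible on
one device; cross-hardware bitwise identity is not promised.

Evaluation reports AUROC (rank-based, ties at half credit), AUPRC as average
precision over the step-wise precision-recall curve (a random scorer
converges to prevalence), and F1/sensitivity/specificity/accuracy at the
F1-optimal threshold scanned over all distinct scores. All five are verified
against brute-force enumeration oracles in the tests.

## Synthetic data: what it emulates, and what not

The spectrum generator draws a library compound, expands its class rule into
the true peak list, perturbs each m/z multiplicatively with Gaussian noise
of a few ppm, adds decoy peaks at least 20 ppm off-grid (decoy count
binomial so the expected decoy share of the peak list equals the configured
fraction), samples cosmetic intensities (annotation is m/z-driven), and
jitters the retention time by 0.05 min around the library reference. It
emulates the mass accuracy and contamination structure that matter for
annotation; it does not emulate intensity physics, collision-energy
dependence, isotope envelopes or chromatographic co-elution, so passing
recovery benchmarks says nothing about intensity-based scoring on real data.

The presence generator draws compound rows i.i.d. from a 64-pattern
distribution whose default is a sequential-passage chain (gastric survival
0.95; intestinal absorption 0.70; hepatic passage 0.80; systemic persistence
0.85; excretion odds differing between absorbed and unabsorbed compounds) -
values chosen once as a realistic oral-dosing regime; the generator's
bookkeeping is exact, so summaries must recover it with no estimation error.

The drug–target generator plants an imide pharmacophore token into random
fragment-grammar SMILES and a fixed 5-mer motif into random protein
sequences; the activity rule is their co-occurrence, and observed labels are
the rule XOR Bernoulli noise. The positive-class fraction defaults to 0.13,
the prevalence regime of curated public senolytic bioassay data, and the
pharmacophore probability is solved from that balance. Because the noise is
symmetric, no scorer can exceed an expected AUROC of 1 − ε against the noisy
labels for balanced classes, and less under imbalance (the generator reports
this ceiling in closed form); discrimination recovery is therefore measured
against the noise-free rule labels the generator emits as ground truth,
while training sees only the noisy labels. At the default conditions
(n = 2000, ε = 0.05, 13% positives, encoder width 64, 30 epochs) this is a
deliberately hard benchmark: roughly a third of the positive labels carry no
signal, and there are only ≈140 clean positive training pairs.

## Problem sizes and numerical choices

The test suite exercises annotation recovery on 1,000 simulated spectra over
the 73-compound library and trains the screening network on 2,000 synthetic
pairs at width 64 for 30 epochs (with a label-permuted control run),
problem sizes chosen so the full suite runs on a single CPU in minutes. The
network core is compiled (RcppArmadillo); its gradients are verified against
central finite differences at tolerance 1e-4. Softmax attention subtracts
the maximum logit before exponentiation; predicted probabilities are clipped
at 1e-12 for the cross-entropy; dataset splits use largest-remainder
rounding (ties to the later split) and stratify by label by default, since
the 80-10-10 design at 13% prevalence can otherwise leave a partition
single-class - the class-wise partition counts in the reproduced methodology
imply the same.

## Known limitations

* Aromaticity/hybridization perception is heuristic (see above), not a full
  aromaticity model.
* The annotator identifies library compounds only; de novo elucidation,
  spectral-library cosine matching and intensity prediction are non-goals.
* Fate logic is boolean and prototype-only; no pharmacokinetics.
* The screening stage reproduces the architecture and evaluation protocol,
  not the published headline metrics, which depend on an unreleased
  curated bioassay set; those numbers are covered by schema- and
  property-level tests only.
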