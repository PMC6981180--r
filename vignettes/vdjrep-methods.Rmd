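---
title: "Models and methods behind vdjrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vdjrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjrep)
```

vdjrep is a toolkit for comparative analysis of antibody heavy- and
kappa-chain repertoires from AIRR-seq experiments, built around a generative
V(D)J recombination simulator with full ground truth. This vignette explains
the models, the parameter choices, and the design decisions a maintainer or
reviewer would want spelled out. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`; the vignette itself
makes no empirical claims beyond those.

## The recombination model

A heavy-chain rearrangement is described by a factorized generative model
(class `recomb_model`):

$$P(\text{rearrangement}) = P(V)\,P(D,J)\,P(t_V \mid V)\,
P(t_{D5}, t_{D3} \mid D)\,P(t_J \mid J)\,P(\ell_1)\,P(s_1 \mid \ell_1)\,
P(\ell_2)\,P(s_2 \mid \ell_2)$$

where $t_\bullet$ are exonucleolytic trim lengths, $\ell_1, \ell_2$ the
lengths of the non-templated (N) insertions at the V–D and D–J junctions,
and $s_1, s_2$ the inserted nucleotide strings, generated by a first-order
Markov chain shared by both junctions (a simplification: scenario-based
tools fit one chain per junction). The kappa model drops the D segment and
uses a single V–J insertion. The joint (D, J) event captures the known
coupling of D- and J-gene choice; D trims are a joint conditional per D
gene.

P nucleotides are modelled as a deterministic assembly rule rather than a
stochastic event: whenever a coding end is untrimmed, a 2-nt palindromic
(reverse-complement) extension is added, mimicking hairpin opening. This
keeps the per-record junction-length identity exact —

    |junction| = kept V after the CYS codon + P + n1 + kept D + P + n2 + P + kept J through the TRP/PHE codon

— which the test suite checks record by record, and it adds no event to the
KL factorization because the rule is identical across models.

### Sequence assembly, frames and productivity

Junctions run from the conserved second-CYS codon of V to the end of the
J-TRP (heavy) or J-PHE (kappa) codon, the IMGT convention; `cdr3_aa` is the
junction minus the two anchors. A draw is *productive* when the junction
length is a multiple of three, the translation starts with C, ends with W or
F, and contains no stop codon. Non-productive draws are kept and flagged by
`simulate_rearrangement()`/`generate()` — their frequency is itself
informative — while every statistics operation excludes them by default,
because RNA-derived expressed repertoires are productive. One deliberate
exception: `simulate_repertoire()` draws its clone founders *conditioned on
productivity* (rejection sampling). Expressed clones in an animal have
passed selection, and an SHM-free founder set gives a clean, well-defined
true richness for recovery experiments.

## Species presets

Both presets share one synthetic human-style toy germline set (12 IGHV, 12
IGHD, 6 IGHJ; 12 IGKV, 5 IGKJ), because the transgenic rat the rat-like
preset emulates carries human V, D and J segments. Identical germline
references are also what make models from different presets comparable by
KL divergence. The presets differ in:

* **Gene-choice distributions.** The rat-like preset prefers the short D
  families (D1/D4/D7) and uses the long-CDR3 pairing of D family 3 with J
  family 6 at an expected frequency of 0.012 versus 0.028 for the
  human-like preset.
* **Insertion lengths.** Truncated negative-binomial profiles with means
  about 1.6/1.4 nt (rat-like) versus 4.3/4.0 nt (human-like) at the V–D and
  D–J junctions.
* **Trim profiles.** Truncated geometric; decay constants chosen per preset
  during construction so the expected CDRH3 means land near 12 aa
  (rat-like) and 15 aa (human-like), and so 5-aa CDRL3 kappa chains are
  roughly an order of magnitude rarer under the rat-like preset.
* **Isotype and SHM.** Per-read Bernoulli IgG assignment with tissue-
  dependent probabilities for the rat-like preset (0.15 lymph node, 0.003
  spleen) and 0.16 throughout for the human-like preset; Poisson V-region
  mutation counts with means 2.5 (IgM) / 9 (IgG) versus 5 / 18 — the
  rat-like burden is about half the human-like one.

A separate short-D, wild-type-rat-style IGHD FASTA is packaged purely for
germline D-segment length comparisons (`mean_segment_length()`); it is not
used for sequence generation. All packaged germline sequences are synthetic
and deterministic; gene names follow real nomenclature so family parsing
behaves as it would on IMGT data, but the sequences are constructed, with
realistic lengths and anchor architecture.

## The clone and tissue layer

`simulate_repertoire()` seeds `n_clones` productive founders; each clone is
placed in both tissue compartments with probability `tissue_overlap_prob`
(default 0.5) or in one compartment chosen fairly. Clone sizes are drawn
i.i.d. from a truncated power law $P(k) \propto k^{-\alpha}$ on
$1..10^4$ with $\alpha = 2$. We read the clone-size law as a distribution
over sizes, not rank-weights: rank-based Zipf with $\alpha = 2$ would put
the majority of reads on a single clone, which is incompatible with the
near-diagonal rarefaction behaviour the analyses assume. Reads are sampled
per compartment with probability proportional to clone size, then isotype
and SHM are applied per read. The default of 10,000 clones against 20,000
reads per compartment keeps rarefaction near the diagonal — the
low-recapture regime reported for real two-tissue data.

SHM applies a Poisson number of point substitutions uniformly over the
retained V region (no hotspot motifs; only mean mutation counts are being
emulated). Mutations falling inside the junction re-derive the junction,
CDR3 and productivity, so heavily mutated reads can drop out of productive
statistics — and can also split one clone into several observed clonotypes,
exactly as in real data. For this reason richness-recovery experiments are
run with SHM at 0, where true clonotype richness is unambiguous.

All randomness flows from a single root seed; subsystems (founders, sizes,
placement, per-compartment sampling) use child streams derived by fixed
offsets, so identical configs give byte-identical AIRR output.

## Model inference and KL divergence

`infer_model()` estimates every event distribution as empirical conditional
frequencies with additive smoothing, $(c + \varepsilon)/(N + \varepsilon
K)$ over a declared support, with pseudocount $\varepsilon = 0.5$ per cell
by default so all probabilities stay positive and divergences finite. It
uses the single best annotation per record — no scenario marginalization —
which is exact on simulator annotations and a documented simplification for
real data. The estimator trains on the records it is given:
`select_unmutated()` implements the productive, zero-mutation,
subsample-to-$n$ selection used for repertoire model fitting. Note that
conditioning on productivity biases event marginals (the in-frame
constraint couples insertions and trims), so parameter-recovery experiments
train on the raw generated stream; preset-versus-preset comparisons use the
selected records on both sides, where the bias is shared.

Divergences are forward Kullback–Leibler, $D(p \| q)$, in bits (log base
2), reported asymmetrically for ordered pairs with a Jeffreys
(symmetrized) option. Conditional events contribute the expectation of the
conditional divergence under *p*'s parent distribution, and the
insertion-string events are computed exactly by propagating state
occupancies of the Markov chain through the length distribution. The sum
over events therefore equals the divergence of the full joint — verified
in the tests against brute-force enumeration of every joint state of a
small model.

## Diversity estimation

Clonotypes are exact-identity classes (V gene, J gene, CDR3 amino-acid
sequence), allele-stripped. With two sampling units (lymph node, spleen),
the incidence-based Chao2 lower bound keeps the finite-unit factor
explicitly:

$$\hat S = S_{obs} + \frac{m-1}{m}\frac{Q_1^2}{2 Q_2}, \qquad m = 2,$$

with the bias-corrected form $S_{obs} + \tfrac{1}{2} Q_1(Q_1-1)/(2(Q_2+1))$
whenever $Q_2 = 0$ (or on request). The abundance-based Chao1 on
singleton/doubleton counts is provided as a documented stand-in for a
second estimator; maximum-likelihood abundance-curve fitting is out of
scope. Rarefaction subsamples reads (duplicate counts expanded) without
replacement, averaging 10 replicates per fraction except the full fraction,
which is computed once; `diversity_vs_fraction()` applies the same scheme
and re-estimates at each fraction. "Sequence diversity" uses the full
rearrangement nucleotide string as the unit, which is why it always
dominates clonotype diversity on the same data.

## Sharing

Sharing operations work on unique clonotype keys (set semantics). Because
the appropriate denominator for a "percent shared" is genuinely ambiguous,
`pairwise_sharing()` always reports three normalizations side by side:
union (Jaccard, the default), mean set size, and per-set. Multiway Venn
regions are computed by direct membership tabulation and checked against
brute-force enumeration. Shared-versus-unshared contrasts count each
clonotype once and compare CDR3-length distributions and V-family usage;
`cdr3_logo()` builds column-normalized position frequency matrices with the
standard residue-category annotation (polar GSTYCQN, basic KRH, acidic DE,
hydrophobic AVLIPWFM) and configurable torso flags (first/last two
positions by default). Sharing fractions scale strongly with sequencing
depth and clone numbers: at the desk scales used here, convergent-key
collisions are rare, so simulated sharing percentages sit far below values
reported from datasets with millions of reads per subject. Only the
*directions* (higher intra-preset than inter-preset sharing, shorter shared
CDRH3s in planted constructions) are meaningful at this scale.

## Usage profiling and clustering

Gene usage is the duplicate-weighted frequency of each allele-stripped gene
among productive records, with unobserved germline genes held in the
support at zero. Cross-repertoire matrices align profiles on the
intersection of gene supports and renormalize — the original scaling
procedure for cross-species comparison is not reproducible from the
published description, so intersection-renormalization is this package's
documented choice; absolute z-scores would differ under a different
scaling, the clustering structure should not. Rows are z-scored with a
population (n) denominator; zero-variance rows map to all-zeros rather
than NaN. Clustering is agglomerative with Euclidean distance and average
(UPGMA) linkage — the metric is fixed by the figure being emulated, the
linkage is unstated there and UPGMA is our choice. Columns are sorted
lexicographically before clustering so dendrogram tie-breaks are
reproducible; dendrograms serialize to Newick via ape.

## Numerical and boundary conventions

* Probability vectors must sum to 1 within 1e-9 (`validate_model()`).
* Model JSON uses 17 significant digits, so a deserialized model generates
  bit-identical sequences under the same seed.
* Over-trimmed D segments (trims exceeding gene length, possible only for
  the shortest genes at the tail of the trim distribution) keep their drawn
  trim values and contribute an empty D segment.
* SHM counts exceeding the retained V length are capped with a warning.
* Single-member groups report SEM 0 and are flagged; empty groups are
  omitted with a warning.
* `read_airr()` drops rows violating record invariants and tallies them by
  reason; accepted plus rejected always equals the input row count.

## Problem sizes used by the checks

The test suite and acceptance script run at sizes chosen to make sampling
error negligible relative to the effects being demonstrated: 30,000
generated heavy-chain and 40,000–50,000 kappa rearrangements per preset for
distribution contrasts; 100,000 versus 1,000 training sequences for model
recovery; richness recovery at a true richness of 1,000 with 5,000 reads
per compartment over 20 replicates; and six simulated subjects at 5,000
clones / 5,000 reads for the clustering separation check. The full
synthetic study (`default_pipeline_config()`: three rat-like and two
human-like subjects, two compartments, 20,000 reads each) is the package's
reference end-to-end run.

## Known limitations

* Inference uses best annotations, not scenario marginalization; on real,
  noisily annotated data the inferred models inherit annotator bias.
* The insertion Markov chain is shared between junctions, and SHM is
  position-uniform without hotspot targeting.
* Sharing percentages and absolute diversity magnitudes at desk scale are
  not comparable to full-scale sequencing studies; directions and estimator
  behaviour are.
* The lambda light chain, allelic variation, and sequencing-error modelling
  (upstream of UMI-corrected input) are out of scope.
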