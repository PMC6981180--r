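# vdjrep

Comparative analysis of antibody V(D)J repertoires, with a generative
simulator that provides ground truth for every downstream method.

Immunoglobulin repertoire sequencing (AIRR-seq) studies routinely compare a
transgenic or model animal's antibody repertoire against the human one:
which V, D and J gene segments are used, how long the CDR3 loops are, how
much junctional insertion and trimming shaped them, how diverse the
clonotype pool is, and how many clonotypes are shared between individuals
or species. vdjrep implements that comparison pipeline for heavy (IGH) and
kappa (IGK) chains, for immunogenomics researchers who work with annotated
rearrangement tables in the AIRR TSV dialect.

At its core are four pieces of methodology:

* **A factorized recombination model.**
  `P(V) P(D,J) P(t_V|V) P(t_D5,t_D3|D) P(t_J|J) P(l1) P(s1|l1) P(l2) P(s2|l2)` —
  gene choices, trims, insertion lengths and first-order-Markov insertion
  nucleotides. Models are inferred from annotated records by smoothed
  empirical frequencies (`infer_model()`), generate synthetic sequences
  (`generate()`), and are compared by exact event-level and complete
  Kullback–Leibler divergence in bits (`kl_event()`, `kl_complete()`);
  the chain-rule sum over events equals the divergence of the full joint.
* **A two-compartment repertoire simulator** (`simulate_repertoire()`):
  clones drawn from species-like preset models, power-law clone sizes,
  lymph-node/spleen placement, per-tissue isotype (IgM/IgG) assignment and
  Poisson somatic hypermutation — with the generating model, the founder
  clone table and all event-level truth returned alongside the reads.
* **Capture–recapture diversity estimation**: exact-identity clonotypes
  (V gene, J gene, CDR3 amino acids), cross-tissue incidence, Chao2 with
  the explicit (m−1)/m factor, Chao1, rarefaction and
  estimate-versus-fraction sweeps.
* **Sharing analysis**: pairwise and multiway Venn decompositions of
  clonotype sets, pool overlap, shared-versus-unshared CDR3
  characterization and sequence logos; plus gene-usage z-score heatmap
  clustering and pairwise usage regressions.

## A worked example

```r
library(vdjrep)

om <- species_preset("omnirat_like")   # rat-like transgenic preset
hu <- species_preset("human_like")

# generate rearrangements from each preset model and contrast them
r_om <- generate(om$igh_model, 20000, seed = 1)
r_hu <- generate(hu$igh_model, 20000, seed = 2)
length_distribution(r_om, "cdr3_length")$mean   # 12.3 aa
length_distribution(r_hu, "cdr3_length")$mean   # 14.9 aa
family_pair_frequency(r_om)                     # D3-J6 co-usage 0.011
family_pair_frequency(r_hu)                     # 0.028

# simulate a two-tissue animal with known richness and recover it
sim <- simulate_repertoire(simulator_config("omnirat_like",
         n_clones = 1000, n_reads_per_compartment = 5000,
         shm_rate_igm = 0, shm_rate_igg = 0, seed = 3))
inc <- build_incidence(assign_clonotypes(sim$lymph_node),
                       assign_clonotypes(sim$spleen))
inc
#> <incidence_table> m = 2: S_obs 910, Q1 517, Q2 393
chao2(inc)
#> <diversity_estimate> chao2: 1080.0 (inputs: S_obs=910, Q1=517, Q2=393)

# infer a model back from generated sequences and measure the divergence
inf <- infer_model(generate(om$igh_model, 50000, seed = 4))
kl_complete(om$igh_model, inf)                  # 0.012 bits
```

The rat-like preset produces shorter CDRH3 loops and rarer long-CDR3 gene
pairings than the human-like preset; Chao2 recovers the planted richness of
1,000 clones from the two-compartment incidence counts; and model inference
converges to the generating model (divergence in hundredths of a bit at
50,000 training sequences).

The full study — simulation of several subjects per preset, usage
clustering, model inference with pairwise divergences, diversity and
sharing — runs as one call:

```r
run_pipeline(default_pipeline_config(seed = 1), "report/")
```

which writes per-repertoire AIRR TSVs with truth sidecars, per-analysis
tables, serialized models, Newick dendrograms, figures, a run log with
record-count conservation at every stage, and `summary.json`. A thin
command-line wrapper is available at `inst/scripts/run_pipeline.R`. Real
annotated AIRR TSV files can be substituted for the simulator via the
`inputs` config key.

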