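---
title: "Methods: a graph-attention VAE for de novo SMILES generation"
author: "MolGraphVAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a graph-attention VAE for de novo SMILES generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

De novo molecular design asks a generative model to propose new, valid,
synthesizable molecules that resemble a reference chemical space without
copying it. MolGraphVAE implements a graph-to-sequence variational
autoencoder for this task: molecules are *read* as graphs, which expose
bonds and neighborhoods directly, and *written* as SMILES strings, which
are compact, easy to validate, and the lingua franca of compound
databases. The package trains and evaluates the model end to end on
commodity hardware, with a deterministic fixture-corpus generator standing
in for large screening corpora so that every stage is testable offline.

## Molecular representation

A molecule with $n$ heavy atoms becomes three matrices:

* $V (1 \times n)$ — one feature per node, the atom's element symbol
  (hydrogens are implicit, as in standard SMILES graph practice);
* $E^{index} (2 \times e)$ — directed bond columns; every chemical bond
  contributes a forward and a reversed column so that message passing is
  symmetric;
* $E^{feat} (1 \times e)$ — a bond-type code per column: single 0,
  double 1, triple 2, aromatic 3.

Aromaticity follows the perception model of the chemistry toolkit
(OpenBabel via ChemmineOB); kekulized input is re-aromatized before
conversion, and stereochemistry is stripped, since neither wedge bonds nor
chirality survive the representation. Node indices are 0-based parse
order.

Because the node feature is the bare element symbol, hydrogen counts on
aromatic nitrogens are not representable: pyrrole-type and pyridine-type
nitrogens with identical bond patterns collapse to the same graph. The
fixture grammar therefore uses only unambiguous aromatic systems
(benzenes, pyridines, thiophenes), and `graphToSmiles()` documents the
limitation. This is a property of the single-feature design, not of the
implementation.

## Architecture

**Encoder.** Each of `nLayers` (default 8) encoder layers applies two
graph-attention (GAT) sublayers and then a position-wise feed-forward
sublayer, every sublayer wrapped in a residual connection and layer
normalisation. A GAT sublayer scores each directed edge $u \to v$ with
$\mathrm{LeakyReLU}(a_s^\top W h_u + a_d^\top W h_v + a_e^\top E_{type})$,
softmax-normalises over the incoming edges of $v$ (self-loops, with their
own learned edge type, guarantee a non-empty neighborhood even for single
atoms), and aggregates $\sum \alpha_{uv} W h_u$. Bond-type embeddings
enter the attention score only; with multiple heads the concatenated head
outputs are projected back to `hiddenDim`. DenseNet-style connections feed
the concatenation of the atom embeddings and all previous layer outputs
(linearly projected) into each layer, countering over-smoothing and giving
every layer a direct gradient path. After the last layer, *global add
pooling* sums node vectors per molecule; two linear heads map the pooled
vector to the posterior mean $\mu_\phi(x)$ and log standard deviation.

**Latent space.** $q_\phi(z|x) = \mathcal{N}(\mu_\phi(x),
\sigma_\phi(x))$ with a standard Gaussian prior. $\sigma$ is parameterised
on the log scale for positivity. Samples use the reparameterization
$z = \mu + \epsilon \sigma$, $\epsilon \sim \mathcal{N}(0, 1)$.

**Decoder.** A standard transformer decoder (sinusoidal positional
encodings, causal multi-head self-attention, post-norm residuals) whose
cross-attention attends to the latent vector presented as a memory
sequence of length one — the simplest reading of "attend to the latent
space"; expanding $z$ into a multi-token memory is a possible variant we
did not pursue. Tokens come from a regex SMILES tokenizer in which bracket
atoms, `Cl`/`Br` and two-digit ring closures are atomic; the vocabulary is
corpus-derived, sorted, with reserved pad/begin/end/unknown ids.

## Objective

$$ L = \beta \, D_{KL}\!\left(q_\phi(z|x) \,\|\, \mathcal{N}(0, I)\right)
   + \mathrm{NLL}(x \mid z) $$

The KL term has the diagonal-Gaussian closed form
$\sum_d \tfrac12 (\mu_d^2 + \sigma_d^2 - 1 - \ln \sigma_d^2)$; the
reconstruction term is the negative log softmax probability of each target
token under teacher forcing. Reduction: reconstruction is **summed over
tokens** and averaged over molecules, KL summed over latent dimensions and
averaged over molecules. With $\beta \in [5\times10^{-5}, 10^{-4}]$ a
per-token mean would make the KL term numerically irrelevant; the
sum-over-tokens convention keeps the printed $\beta$ range meaningful.

$\beta$ follows a schedule that advances once per epoch: *monotonic*
(linear ramp from `betaLow` = 5e-5 to `betaHigh` = 1e-4 across the
horizon) or *cyclical* (the horizon split into `nCycles` equal cycles,
each a pure linear ramp resetting to `betaLow` at the cycle boundary; the
bounds are shared with the monotonic mode, and the within-cycle shape is a
design choice — ramp-and-hold variants exist but a pure ramp is the
simplest policy consistent with periodic reset). A single $\epsilon$ draw
per molecule per forward pass gives the usual one-sample ELBO estimate.

## Training

Adam (learning rate 3e-4, weight decay 1e-6 folded into the gradient),
default 100 epochs, seeded shuffling, disjoint-union graph batching so
that add pooling segments per molecule. One integer seed controls weight
initialisation, shuffling, $\epsilon$ draws, dropout and sampling, making
training logs bit-reproducible. Optional global-norm gradient clipping
(off by default) protects the tiny-$\beta$ regime. Checkpoints store
config, weights, vocabulary and seed; resumed runs continue the $\beta$
schedule at the correct step.

Two numerical choices matter:

* **Posterior-head initialisation.** Global add pooling sums node
  vectors, so pooled activations scale with molecule size; full-scale
  Xavier weights in the $\mu$/$\sigma$ heads put $|\log\sigma|$ in the
  tens and overflow $\exp(2\log\sigma)$ in the KL. The heads are therefore
  initialised near zero (factors 0.05 and 0.01), which starts the
  posterior at the prior and the KL near zero.
* **The autodiff engine.** No neural-network framework is available to R
  in this stack, so the package includes a small reverse-mode tape over
  dense matrices (`R/autograd.R`) with fused layer-norm, multi-head
  attention, softmax cross-entropy and Gaussian-KL ops. Every op is
  validated against central finite differences (tolerance 1e-4) in the
  test suite, including a full-loss gradient check through encoder and
  decoder.

## Evaluation suite

All metrics operate on the valid subset of the generated set G, in
canonical form (canonicalization makes set membership well defined — a
molecule has many SMILES spellings but one canonical string):

* **validity** — fraction of generated strings the toolkit parses and
  perceives as chemically consistent molecules;
* **Unique@K** — distinct fraction among the first K = 10,000 valid
  molecules (all of them when fewer than K);
* **novelty** — fraction of valid molecules absent from the training set;
* **IntDiv$_p$** — $1 - \frac{1}{|G|^2}\sum_{m_1, m_2 \in G}
  T(m_1, m_2)^p$ over *all ordered pairs including self-pairs*, exactly as
  the double sum reads; the off-diagonal variant used by some reference
  code is one flag away (`includeSelfPairs = FALSE`). $T$ is the Tanimoto
  coefficient over radius-2 circular hashed fingerprints (ECFP4-style,
  1024 bits), computed in-package on the graph representation so that
  million-pair similarity workloads stay memory-flat;
* **scaffold similarity** — cosine similarity of Bemis-Murcko scaffold
  frequency vectors over the union scaffold set. Frameworks are computed
  by stripping terminal atoms to the ring-and-linker core and restoring
  atoms double- or triple-bonded directly to it (so a benzophenone keeps
  its carbonyl oxygen while an acetyl side chain disappears). Acyclic
  molecules map to the empty scaffold and are excluded from the scaffold
  universe, with a log message;
* **property distributions** — 1-D Wasserstein distances between
  generated and test-set distributions of MW, logP, QED and a
  synthetic-accessibility score, plus a descriptor table (HBD, HBA, NH/OH
  hydrogen count, heavy atoms, TPSA, rotatable bonds).

QED is computed in-package from the published desirability
parameterisation over MW/logP/HBA/HBD/PSA/rotatable-bonds/aromatic-rings/
alerts; the structural-alert screen is optional (off by default, leaving
the alert term neutral) and uses a compact SMARTS subset the OpenBabel
matcher supports. The SA value is the package's own complexity heuristic
(size, rings, macrocycles, branching, heteroatom load, scaled 1–10), not
the fragment-database score; both are clearly labelled and no headline
result depends on either.

## The corpus filter and fixture generator

The admission filter reproduces the clean-leads rules: MW in
[250, 350] g/mol, at most 7 rotatable bonds, logP ≤ 3.5, elements within
{C, N, S, O, F, Cl, Br, H}, no ring larger than 8 atoms, no formally
charged atoms. Ring size is measured as the largest smallest-ring any bond
participates in (breadth-first search per ring bond), which coincides with
the largest relevant ring for drug-like fused systems and flags
macrocycles correctly.

The fixture generator enumerates a scaffold + substituent grammar
(20 aryl amide / sulfonamide / urea / ether / piperazine templates ×
15 substituents at two sites), canonicalizes, de-duplicates, and in strict
mode keeps only filter-passing molecules — about 1,100 distinct molecules,
every one valid, neutral, and within the filter by construction. A seeded
draw from this pool is the study corpus at desk scale. What the fixtures
deliberately do **not** emulate: the scale (thousands, not millions), the
scaffold breadth of a real screening library, pyrrole-type heteroaromatics
(see above), and any property imbalance between train and test splits.
Passing tests on fixtures therefore demonstrates mechanical correctness
and trainability, not chemical-space coverage at benchmark scale.

## Problem sizes

The shipped tests and the acceptance script run entirely at desk scale,
chosen as the smallest sizes at which each property is meaningful: graph
and metric invariants on 1,000 fixture molecules; model contracts on a
2-layer, 64-wide configuration; an overfitting run on 32 molecules for
250 epochs (teacher-forced accuracy ≥ 0.95, greedy reconstruction of at
least half the corpus, and at least one valid molecule per 100 prior
draws); generation-quality metrics on sets of a few hundred. The
full-scale defaults (8 layers, width 512, 100 epochs, 30,000-molecule
generation sets, Unique@10,000) remain the configuration defaults and are
exercised by the same code paths.

## Known limitations

* Validity and canonicalization follow OpenBabel's chemistry model;
  toolkits differ at the margins (exotic valences, aromaticity edge
  cases), so absolute validity numbers are toolkit-relative.
* The single-feature node representation cannot express formal charges,
  isotopes, stereochemistry, or aromatic N–H counts.
* The latent-as-single-memory-token reading of cross-attention is one of
  several defensible designs; so is the per-epoch (rather than per-step)
  advancement of the beta schedule.
* The engine is CPU-bound, single-threaded R + BLAS: suitable for
  desk-scale studies and method development, not for training on
  million-molecule corpora.
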