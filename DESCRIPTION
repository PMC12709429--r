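Package: MolGraphVAE
Title: Graph-Attention Variational Autoencoder for De Novo SMILES Generation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A graph-to-sequence variational autoencoder for de novo molecular
    design. Molecules are encoded as attributed graphs (atom-symbol nodes,
    directed bonds with single/double/triple/aromatic type codes) and passed
    through a stack of graph-attention encoder layers with DenseNet-style
    inter-layer connections and a global-add-pool readout onto a diagonal
    Gaussian latent space; a transformer decoder cross-attends to the latent
    vector and emits SMILES tokens autoregressively. Training minimises a
    beta-weighted evidence lower bound with monotonic or cyclical KL annealing.
    The package ships the full generation-quality metric suite used by the
    MOSES benchmark (validity, Unique@K, novelty, internal diversity,
    Bemis-Murcko scaffold cosine similarity, property-distribution Wasserstein
    distances), a corpus filter implementing the MOSES dataset rules, a seeded
    combinatorial fixture-corpus generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Cheminformatics, MachineLearning, GraphAndNetwork
RoxygenNote: 7.3.3
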