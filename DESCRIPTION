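Package: tmcdiff
Title: Scaffold-Conditioned Diffusion Generation of Transition-Metal
    Complex Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates missing ligands of mononuclear transition-metal
    complexes with an equivariant denoising diffusion model conditioned on
    a frozen scaffold (the metal centre plus any subset of retained
    ligands) and on user-specified ligand denticities. Provides the
    multi-ligand masking combinatorics used to expand a training corpus,
    the integer-partition enumeration of ligand-denticity assignments, a
    geometric-vector-perceptron noise-prediction network with full-graph
    message passing, generation quality metrics (ligand validity,
    connectivity, complex validity, novelty, uniqueness), structural
    analyses (metal-donor bond lengths, conformer RMSD), deterministic
    synthetic fixture corpora, and a spin-crossover candidate screening
    pipeline with pluggable energy backends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    bio3d,
    ChemmineOB,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
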