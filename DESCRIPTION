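Package: phoregen
Title: Hierarchical Pharmacophore-Guided Molecular Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for structure-based molecular design that
    operates through coarse-grained pharmacophore point clouds. Ligand
    pharmacophores are sampled inside a protein pocket with a conditional
    variance-preserving denoising diffusion model whose noise predictor is an
    E(3)-equivariant graph network; repeated samples are consensus-clustered
    with a Gaussian mixture in space and a per-cluster feature vote; clusters
    are decoded into molecules by a pharmacophore-conditioned, property-gated
    latent-variable SMILES generator; generated molecules are embedded in 3D
    and posed by rigid Kabsch alignment of their features onto the sampled
    cloud; and two pockets' clouds can be registered and differenced to
    propose selectivity-driving features. Includes synthetic fixture
    generators (pocket-ligand pharmacophore pairs, a drug-like SMILES corpus)
    so every stage is trainable and testable on one CPU with no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    mclust,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
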