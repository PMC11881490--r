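Package: hergforge
Title: Scaffold-Constrained Generative Re-Engineering of hERG-Active Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Tools for re-engineering cardiotoxic drug candidates for reduced
    hERG (human Ether-a-go-go-Related Gene) potassium channel liability while
    preserving their physicochemical profile. Provides a scaffold- and
    property-conditioned autoregressive SMILES transformer for molecular
    generation, a bidirectional masked-token transformer used as a molecular
    feature extractor, and tri-modal (transformer embedding, ECFP4 fingerprint,
    molecular graph attention network) predictors of hERG, NaV1.5 and CaV1.2
    channel activity. A re-engineering pipeline generates analogues of an input
    molecule, filters them with per-channel activity constraints, and ranks
    survivors by cosine similarity in a mutual-information-pruned 2D descriptor
    space. Includes synthetic corpus and planted-activity generators so the
    whole stack can be trained and exercised at desk scale, plus the standard
    QSAR evaluation toolbox (confusion-matrix metrics, ROC AUC, Pearson
    correlation, Y-randomization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
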