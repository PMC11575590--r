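Package: hanna
Title: Hard-Constraint Neural Networks for Activity Coefficients in Binary
    Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts the molar Gibbs excess energy of binary liquid
    mixtures with a permutation-invariant (deep-set) neural network whose
    architecture enforces the thermodynamic consistency criteria exactly:
    activity coefficients of pure components are unity, pseudo-binary
    mixtures of a component with itself are ideal, predictions are
    permutation-equivariant, and the Gibbs-Duhem equation is satisfied by
    construction because the logarithmic activity coefficients are
    obtained from the Gibbs excess energy by exact differentiation.
    Includes the surrounding pipeline: SMILES-keyed component embeddings
    with a deterministic offline backend, conversion of vapor-liquid
    equilibrium measurements to activity coefficients via extended
    Raoult's law with Antoine vapor pressures, system-wise data
    splitting, smooth-L1 training with decoupled weight decay, analytic
    Margules/NRTL reference models, a synthetic-data generator for
    desk-scale validation, thermodynamic consistency checkers, and
    isothermal vapor-liquid phase-diagram prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
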