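Package: ratemorph
Title: Phylogenetic Mixed Models Linking Gene-Family Evolutionary Rates to
    Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analyses that relate molecular evolutionary
    rates of large gene families to anatomical traits, motivated by olfactory
    receptor (OR) evolution and olfactory epithelium morphology in bats.
    Extracts cumulative root-to-tip branch lengths from paired codon-model and
    nucleotide-model gene trees via phylogenetic variance-covariance matrices;
    assembles and filters per-gene rate tables; and fits hierarchical Bayesian
    Gaussian mixed models with phylogenetic (animal-model) random effects,
    unstructured us() and independent-variance idh() covariance blocks,
    multiresponse stacking with missing-response augmentation, DIC model
    selection and HPD summaries via a purpose-built Gibbs sampler. Includes a
    synthetic-data generator emulating diet-dependent allometry of olfactory
    epithelium surface area on body mass and per-subfamily coupling of codon
    to nucleotide branch lengths with partial gene detection, plus
    orchestration of the three analysis suites (allometry, rate regression,
    multiresponse rate-morphology) with taxa-exclusion reruns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
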