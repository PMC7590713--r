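Package: ocsr
Title: Optical Chemical Structure Recognition Pipeline
Version: 0.1.0
Authors@R: person("OCSR", "Maintainers", email = "ocsr@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for optical chemical structure recognition:
    curation of molecule corpora by structural filter rules, deterministic 2D
    depiction of molecules to fixed-size bitmaps, interconversion of SMILES,
    DeepSMILES and SELFIES string representations, tokenization and vocabulary
    construction, an attention-based encoder-decoder network (GRU decoder with
    additive soft attention) trained by teacher forcing to translate structure
    bitmaps into molecular strings, and Tanimoto-fingerprint based evaluation
    of predictions. Includes a seeded synthetic molecule generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
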