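Package: BoneAgeQC
Title: Self-Validation and Agreement Statistics for Automated Bone Age Assessment
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quality-control layer of automated bone age
    assessment from hand radiographs. Implements a six-step self-validation
    cascade that rejects individual tubular bones (anomalous appearance,
    deviation from the consensus bone age) and whole images (too few bones,
    over-sharpened or blurred images, missing radius in near-mature hands),
    a dimensionless contrast-invariant edge-sharpness metric for metacarpal
    shaft edges, a synthetic-cohort and synthetic-radiograph simulator, and
    an accuracy toolkit: RMS and MAD errors, multi-rater reference
    construction, quadrature decomposition of observed error into method
    accuracy and rater variability, variance fractions, Bland-Altman
    agreement analysis, and a disputed-case workflow that counts grave
    rating errors per method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
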