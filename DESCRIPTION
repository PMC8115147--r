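Package: LarynxCAD
Title: Quantitative Laryngoscopy Image Analysis and Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided analysis of laryngoscopic video and still images.
    Selects the clearest frame from an endoscopic sequence using PSNR screening,
    a four-interval fast Otsu threshold and glottal structure filters; normalizes
    brightness by histogram translation to a fixed set value; segments the
    glottis and both vocal cords with a greedy active-contour method whose
    iteration count is chosen adaptively by an entropy-difference stopping rule;
    extracts geometric (protrusion) and hue (grayscale standard deviation)
    features of each cord; and classifies five laryngeal conditions (healthy,
    polyp, cyst, leukoplakia, tumor) with a decision-tree-structured support
    vector machine. Includes a seeded synthetic laryngeal-phantom generator with
    ground-truth masks so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'phantom.R'
    'io.R'
    'preprocess.R'
    'screening.R'
    'segmentation.R'
    'features.R'
    'classify.R'
    'pipeline.R'
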