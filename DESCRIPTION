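Package: rosetteScreen
Title: High-Content Morphometric Phenotyping of Single-Rosette Neural Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
        role = c("aut", "cre"))
Description: An image-analysis pipeline for high-content screening of
        self-organizing single-rosette cortical organoids, an in vitro model
        of neural tube closure. Segments organoid bodies and their apical
        lumens from two-channel fluorescence fields, extracts a large
        per-organoid feature vector (shape, intensity, six-ring radial
        distribution, Zernike moments, texture), applies single-lumen and
        size quality filters, measures individual apical cell-surface areas
        from high-magnification tight-junction mosaics, and recovers drug
        dose or mosaic knockout fraction with cross-validated random-forest
        models. Ships a synthetic two-channel field and tight-junction
        mosaic generator with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, EBImage, tiff, ranger,
        jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: CellBasedAssays, Software, Visualization
RoxygenNote: 7.3.3
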