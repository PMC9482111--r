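Package: scleromech
Title: Mechanics and Image Quantification for Scleral Fibroblast
    Mechanobiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for cyclic-tensile-strain experiments on
    scleral fibroblasts. Converts intraocular pressure and ocular geometry
    into Young-Laplace hoop stress and the cyclic tensile strain band over a
    stated Young's modulus range; generates ground-truthed synthetic
    fluorescence micrographs (elliptical cells with oriented fibre texture,
    nuclei with punctate heterochromatin foci) under a three-group by
    three-timepoint design; measures cell and nucleus morphometrics
    (maximum-intensity projection, area, width/length eccentricity),
    structure-tensor fibre anisotropy, and the Sobel-based chromatin
    condensation parameter; and runs the assumption-gated group-comparison
    statistics (Anderson-Darling and Bartlett gating, one-way ANOVA with
    Tukey HSD or Kruskal-Wallis with Dunn post-hoc, box-whisker summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    nortest,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
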