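Package: choromap
Title: Geographic Choroidal Thickness Mapping and Ocular Biometry from SD-OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring choroidal thickness (CT) geographically around
    the macula from 3D spectral-domain optical coherence tomography (SD-OCT)
    volumes, and for measuring intraocular axial length (IOL) from a composite
    A-scan acquired with a dual-reference-arm geometry. Includes axial motion
    correction by cross-correlation of B-scan profiles, dynamic-programming
    boundary segmentation of the inner limiting membrane, outer retinal pigment
    epithelium and choroid-sclera interface, RPE-normal thickness mapping onto
    a 1/5/10 mm nine-sector macular grid and a 1 mm nasal-temporal ring
    profile, cohort statistics for myopia severity groups, and a synthetic OCT
    volume generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
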