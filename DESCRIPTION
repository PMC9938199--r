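Package: exuscan
Title: Pixel-Wise Hard-Exudate Detection in Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Retinal Imaging", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects hard exudates (bright, sharp-margin lipid deposits seen
    in diabetic retinopathy) in color fundus photographs with a pixel-wise
    radial intensity analysis: around every pixel, eight semicircular sectors
    are scanned along several directions for significant intensity drops at
    non-necessarily-equal distances, and pixels whose evidence spans enough
    consecutive sectors are labeled as exudate. Includes an edge-based optic
    disc localizer used to suppress false positives, a seeded generator of
    fundus-like synthetic scenes with ground truth, a patch-based
    intersection-over-union evaluation protocol, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
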