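Package: rlbp
Title: Roughness Local Binary Patterns for Fruit Peel Texture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Texture analysis toolkit for fruit ripeness imaging. Implements
    a peel-roughness metric (mean absolute directional deviation over nine
    sampling regions of a fruit's bounding rectangle), the R-LBP encoding (a
    local binary pattern variant that compares the dispersion of an outward
    pixel ray with and without the target pixel), the classic LBP baseline,
    mask-based compositing of texture-enhanced fruit onto grayscaled
    backgrounds for building detector training sets, a seeded synthetic
    fruit-scene generator, and an experiment harness summarizing
    adjacent-ripeness-stage roughness differences. Includes a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
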