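Package: TuringGrowth
Title: Growth-Coupled Turing Colour Pattern Simulation and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates two-morphogen Turing colour patterns on an
    exponentially growing tissue mapped to a fixed periodic grid, and
    quantifies the resulting putative-growth patterns (rosettes, intermediate
    bands, line-and-dots alternations, mazes of mazes).  Includes colour
    rendering with an averaging memory mechanism, persistence-based motif
    counting, centered 2D DFT magnitude spectra with log/normalize/threshold
    post-processing, inverse-distance-squared tissue growth maps from segment
    morphometrics, a reverse method estimating pattern-formation timing and
    wavelength from adult motif counts, the motif-count delta calibration
    under growth, and a record model with tallies for classic-versus-growth
    pattern surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, withr, png, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
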