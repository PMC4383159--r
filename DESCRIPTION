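Package: specklemotion
Title: Firefly-Swarm and Full-Search Block Matching for Speckle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Dense block-matching motion estimation for speckle-corrupted
    (B-mode ultrasound-like) grayscale image sequences.  Implements two
    iterative estimators sharing a smoothness-regularized matching fitness:
    a firefly swarm optimizer (IFA) that samples few candidate displacements
    per pixel, and an exhaustive full search (IFSA) baseline.  Includes
    motion-compensation quality metrics (PSNR, PSNR degradation ratio,
    computation-saving ratio, endpoint error), a synthetic speckle-phantom
    generator with known ground-truth motion for validation, image sequence
    I/O (PNG, TIFF), and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
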