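Package: tractrel
Title: Test-Retest Reliability of Diffusion MRI Tractometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the test-retest reliability of white-matter fiber
    bundles reconstructed from paired-session diffusion MRI. Computes
    weighted and unweighted Dice overlap between streamline density maps
    of repeated bundle reconstructions, intraclass correlation ICC(A,1)
    with F-based confidence intervals and reliability categories,
    Bland-Altman limits of agreement for per-bundle micro- and
    macro-structural measures (FA, MD, AD, RD, NuFO, volume, mean
    streamline length), and bundle geometry primitives (affine transport,
    density mapping, volume, streamline length). Includes a synthetic
    paired-session cohort generator with known variance components for
    parameter-recovery studies, and a pipeline producing a per-bundle,
    per-metric reliability report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
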