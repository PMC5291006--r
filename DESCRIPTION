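Package: lacunaseq
Title: Fractal Lacunarity of Mitochondrial DNA from Chaos Game Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the mutation load of a mitochondrial genome as a
    fractal-texture index. A subject's mtDNA sequence, reconstructed from a
    reference plus a per-position call table that may contain degenerate IUPAC
    symbols (heteroplasmic calls), is mapped to a weighted Chaos Game
    Representation k-mer matrix; the matrix is rendered as a gray-scale image,
    smoothly thresholded with a sigmoid, and its texture summarized by
    gliding-box lacunarity. A three-parameter hyperbola model fitted to the
    lacunarity curve yields the scale parameter beta, a per-subject biomarker
    that can be compared across cohorts with a one-tailed pooled t-test and a
    median-cutoff classifier. A synthetic-data module generates sequences,
    mutation tables, Sierpinski carpets and Bernoulli images for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cgr.R'
    'cohort.R'
    'hypfit.R'
    'io.R'
    'iupac.R'
    'lacunarity.R'
    'lacunaseq-package.R'
    'pipeline.R'
    'seqio.R'
    'synthetic.R'
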