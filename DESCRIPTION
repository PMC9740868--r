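Package: protexopt
Title: Response-Surface and Neural-Surrogate Optimization of Protein Extraction
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for optimizing alkaline protein-extraction processes with a
    four-factor Box-Behnken design: quadratic response-surface fitting with a
    full ANOVA (partial sums of squares, lack-of-fit against pure error, PRESS
    predicted R-squared), a single-hidden-layer back-propagation neural
    surrogate trained by Levenberg-Marquardt with validation-based early
    stopping, a real-coded genetic algorithm that maximizes a surrogate over
    the factor box, model-comparison metrics (RMSE, MAD, SPE), and the assay
    arithmetic used alongside such studies (Bradford-type protein quantitation,
    yield, radical-scavenging, cytostatic and migration rates, amino-acid
    composition summaries). Ships the 29-run design table and amino-acid
    profile of a selenium-enriched rape protein extraction study as packaged
    fixtures, plus a synthetic-data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
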