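Package: centdesign
Title: Design of Growth Reference Centile Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing cross-sectional growth reference centile
    studies. Implements the Box-Cox Cole-Green (LMS method) distribution and
    its centile/z-score transforms, penalized B-spline (P-spline) fitting of
    age-varying median, coefficient-of-variation and skewness curves by cyclic
    penalized maximum likelihood, simulation of anthropometric datasets under
    age-power (age^lambda) sample composition schemes, bootstrap estimation of
    centile standard-error curves on the z-score scale, and design calculators
    that return the optimal age power, predicted centile precision, required
    sample size and centile confidence intervals for a target precision.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
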