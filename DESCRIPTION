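Package: fetalface
Title: Developmental Complexity of Fetal Facial Movement Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the developmental complexity of coded fetal
    facial movements from 4-D ultrasound observation sessions. Timestamped
    facial action annotations are clustered into co-occurrence events (movements
    with onsets within one second of one another), scored for overall and
    pain/distress-gestalt complexity, and tabulated into ordinal category count
    tables by gestational age. A random-intercept proportional-odds (cumulative
    logit) model of event complexity against gestational age and fetal sex is
    fitted by maximum likelihood with Gauss-Hermite quadrature over the
    per-fetus random effect, with likelihood-ratio tests and typical-fetus
    trajectory prediction. Includes Cohen's kappa inter-rater reliability for
    dual-coded sessions and a seeded synthetic-data generator emulating the
    study design, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
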