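Package: ppa
Title: Principal Process Analysis of ODE Models of Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes ordinary-differential-equation models of biological
    networks into additive biological processes, quantifies the time-resolved
    relative weight of each process along a simulated trajectory, classifies
    processes as active or inactive against a threshold, and simplifies the
    model by eliminating inactive processes -- globally, or per time window in
    a sequence of sub-models delimited by clustered switching times. Reduction
    quality is quantified by global relative errors and a conservative
    Gronwall-type a priori bound, and its robustness to parameter uncertainty
    is assessed with two-level resolution-V fractional factorial designs,
    ANOVA variance decomposition, and PCA-weighted generalised sensitivity
    indices. Ships a 16-variable model of the mammalian circadian clock as the
    packaged reference case, together with small toy models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
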