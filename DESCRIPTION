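Package: pcion
Title: Alkali-Metal Ion Association with Phosphatidylcholine Liposome
    Surfaces from Electrophoretic Titration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of monovalent-ion association with
    zwitterionic phosphatidylcholine (PC) liposome surfaces. Implements a
    four-equilibrium surface model in which H+ and Me+ (Li+, Na+, K+, Cs+)
    bind the phosphate group while OH- and Cl- bind the trimethylammonium
    group, giving membrane surface charge density as a closed-form function
    of pH; the electrokinetic conversion between electrophoretic mobility
    and surface charge density through the diffuse-layer (Debye) thickness;
    asymptotic-linearization and direct nonlinear least-squares estimation
    of the four association constants from pH titration data, with residual
    bootstrap uncertainty; a seeded synthetic-titration generator emulating
    replicate microelectrophoresis measurements; and delimited-text I/O with
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
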