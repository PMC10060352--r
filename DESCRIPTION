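Package: morphospheroid
Title: Morphoelastic Models of Tumour Spheroid Growth
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a hierarchy of five morphoelastic models of avascular
    tumour spheroid growth. A quasistatic, parabolic nutrient profile limits
    proliferation in the Greenspan tradition, while incompressible
    neo-Hookean solid mechanics supplies radial and hoop Cauchy stresses
    that feed back on growth through local and non-local stress modifiers.
    Includes closed-form analytic results for the nutrient-only model
    (steady radii, necrotic geometry, boundary-stress asymptotics),
    residual-stress computation, growth-curve fitting with parameters
    shared across external-stiffness conditions, and a synthetic
    growth-curve generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
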