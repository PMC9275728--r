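Package: bubbleacoustics
Title: Acoustics of Driven Gas Bubbles and Fish Swim Bladders at Depth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Linear acoustics of a driven spherical gas bubble in seawater,
    intended as a model of the fish swim bladder. Computes the frequency
    dependent complex polytropic index, bubble stiffness, the thermal,
    viscous and acoustic (radiation) damping decomposition, and the
    scattering cross-section; solves for the undamped, natural and
    far-field (peak scattering) resonance frequencies and the quality
    factor; and evaluates depth-resolved resonance and radiated-power
    loss on cubic-spline property profiles. Ships the water and gas
    parameter sets for five ocean environments (warm and cold surface,
    and 1000 m, 2000 m, 3500 m depths) for nitrogen and oxygen bubbles,
    together with seeded synthetic parameter generators for property
    based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
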