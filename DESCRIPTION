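Package: vapedose
Title: Reduced-Order Simulation of First- and Secondhand E-Cigarette
    Cannabis Vapor Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation of tetrahydrocannabinol (THC) exposure
    from e-cigarette cannabis vaping. Builds transient puff and breathing
    waveforms, solves a layered air-mucus-tissue-blood (AMTB) transient
    diffusion model of airway-wall uptake with a double-film partition
    boundary condition, transports vapor through a segmented airway tree
    to produce absorbed/exhaled/remaining/to-lung mass budgets, disperses
    the exhaled pulse in a ventilated room (well-mixed and two-zone),
    computes bystander inhaled and transdermal doses, and closes the
    first-to-secondhand dose chain from e-liquid assumptions to per-puff
    and per-session masses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
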