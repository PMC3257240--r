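Package: vtsim
Title: Agent-Based Spatial Simulation of Intracellular Vesicle Transport
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A particle-based stochastic simulator of membrane trafficking in a
    virtual cell. Molecule and vesicle agents move by Brownian dynamics or by
    molecular-motor transport along generated cytoskeleton architectures.
    Vesicles bud from donor compartments through coat polymerization, load
    cargo, SNAREs and motor proteins with class-wise saturation, and fuse with
    target compartments at SNARE-pairing-dependent rates. Internal vesicle
    chemistry runs as well-mixed stochastic kinetics coupled to the spatial
    layer. Includes clathrin-style endocytosis at the plasma membrane with an
    actin boost, recycling of machinery components, and an optional
    receptor/MAPK signaling layer driven by receptor-mediated endocytosis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
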