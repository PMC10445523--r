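Package: oleodrop
Title: Oleosome Interface Density, Dilatational Rheology and Coarse-Grained
    Droplet Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the dilatable phospholipid membrane of
    oleosomes (seed lipid droplets). Computes moment mean diameters (d4,3,
    d3,2) from binned droplet size distributions and translates dispersion
    composition into total interfacial area, phospholipid counts and surface
    densities; extracts dilatational elastic and viscous moduli, amplitude
    sweeps, Lissajous curves and nonlinearity metrics from oscillating
    drop-tensiometer records; builds coarse-grained bead configurations of
    phospholipid-coated triacylglycerol droplets (core packing, spherical
    monolayer shells, two-droplet boxes, solvent hydration) with GRO-format
    input/output; analyses bead trajectories for radial component density
    profiles, core radii, shell densities and droplet-fusion events; provides
    binomial statistics for fusion probabilities; and ships seeded synthetic
    generators emulating every input so the full pipeline is testable without
    instruments or a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
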