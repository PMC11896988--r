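Package: ivimon
Title: Interaction Vertex Imaging Simulation and 4D Motion Monitoring for
    Scanned Carbon-Ion Therapy
Version: 0.1.0
Authors@R:
    person("IVI", "Maintainers", email = "ivimon@example.org", role = c("aut", "cre"))
Description: Tools to study interaction vertex imaging (IVI) as a range and
    motion monitor for scanned carbon-ion therapy of moving targets. Provides
    a seeded forward simulator of a breathing lung-tumour phantom (PMMA
    sphere-plus-cylinder insert in low-density foam) irradiated spot-by-spot,
    including nozzle, motor and FPGA timing logfiles and CMOS-tracker cluster
    observations; straight-track and vertex reconstruction by closest approach
    of the primary pencil-beam line and back-projected secondary-fragment
    tracks (with and without Highland multiple-Coulomb-scattering
    randomisation); and the 4D monitoring decision layer that compares
    per-spot computed vertices against static references to flag
    motion-induced range overshoots and assign respiratory motion phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
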