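Package: sdhrev
Title: Kinetic Modeling of Reverse Electron Transfer and ROS Production
    in the SDHA/SDHB Subcomplex of Succinate Dehydrogenase
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic mass-action model of reverse (quinol-fumarate
    reductase) electron transfer through the soluble SDHA/SDHB subcomplex
    of succinate dehydrogenase, as probed in protein-film voltammetry.
    The network couples a Butler-Volmer electrode reaction at the
    [3Fe-4S] cluster to one-electron transfer through the iron-sulfur
    relay, flavin reduction, fumarate/succinate binding and release, and
    superoxide/hydrogen-peroxide side reactions (22 processes, 13 state
    variables, 4 conserved moieties). Parameter sets are built from
    midpoint potentials with detailed-balance propagation around the four
    thermodynamic cycles. Steady states are computed by stiff integration
    cross-checked against a damped Newton solver, and drivers reproduce
    electrode-potential sweeps (tunnel-diode behavior), succinate-flux
    decomposition, redox-state profiles, ROS production scans, and
    fumarate titrations. The network exports to SBML Level 3.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
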