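Package: sdrmap
Title: Intramural Needle Mapping of Spatial Dispersion of Repolarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intramural unipolar electrogram mapping in
    the chronic AV-block dog model of Torsade de Pointes. Builds the 56-needle
    mapping lattice, detects activation and repolarization times (minimum and
    maximum dV/dt fiducials) with the standard channel-rejection rules,
    computes spatial dispersion of repolarization in transmural, vertical,
    horizontal and cubic orientations, scores ectopic beats and Torsade de
    Pointes episodes per pacing block, rate-corrects intervals with the Van de
    Water formula, fits repolarization restitution curves, and exports polar
    (bullseye) maps. A seeded synthetic-data generator produces ground-truthed
    electrograms, rhythm streams and repolarization fields under the
    RVA50-100-80-60 pacing protocol for testing and demonstration.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
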