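Package: splintforge
Title: Semi-Automatic Design of 3D-Printed Forearm Splints from Scanned Limb Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable geometry pipeline that turns a 3D-scanned limb surface and
    two clinician-drawn boundary curves into multi-part, latticed, screw-assembled,
    watertight splint solids ready for 3D printing. Implements flaw-tolerant mesh
    intake (scan holes are repaired at the cross-section level by periodic cubic
    interpolation), gradual-station cross-sectioning with dual-section (thumb)
    merging, skinned covering-surface construction, area-driven part-count and
    thickness rules, parametric diamond-lattice engraving, rounded rim tubes, and
    M3 screw-seat placement and assembly. Includes a parametric synthetic forearm
    and hand generator with injectable scan flaws so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    polyclip,
    sp,
    igraph,
    jsonlite,
    RcppTOML,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
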