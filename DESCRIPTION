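Package: nailguide
Title: Guided Freehand Distal Interlocking from Single-View Fluoroscopy
Version: 0.1.0
Authors@R:
    person("nailguide", "developers", email = "nailguide@example.org",
           role = c("aut", "cre"))
Description: Computes drill guidance for distal interlocking of intramedullary
    nails from a single cone-beam fluoroscopic projection. The two interlocking
    holes of a nail project as bright lens-shaped regions when viewed obliquely;
    the package detects these regions, extracts significant contour landmarks,
    recovers the 6 degree-of-freedom pose of the distal nail segment by matching
    virtual projection landmarks to the detected ones with damped least squares,
    and emits surgeon-facing overlays (two targeting ellipses per hole plus a
    skin-incision landmark) that align a two-ring drill jig coaxially with the
    hole. Includes a ray-cast synthetic radiograph generator with full ground
    truth used as the test oracle, inter-frame shift correction by phase
    correlation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
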