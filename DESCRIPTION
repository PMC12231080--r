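Package: fireprogress
Title: Day-of-Burning Interpolation, Daily Fire Spread Metrics, and the
    Fire Perimeter Effect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for landscape fire-progression analysis: interpolation
    of per-pixel day-of-burning from dated satellite-style fire detections
    inside a final fire perimeter, decomposition of the day-of-burning map
    into spatially discrete daily patches with area and maximum linear
    spread metrics, reclassification of fine vegetation legends into
    coarse cover groups with prior-burn overlays, the Fire Perimeter
    Effect statistic contrasting cover-type abundance at fire perimeters
    versus burn interiors with exact sign tests under Bonferroni control,
    and Gaussian mixed-effects models of log10 spread metrics on aspen
    cover. A cellular-automaton landscape-fire simulator with a
    cover-type-dependent spread probability provides a fully synthetic,
    reproducible test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    glmmTMB,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
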