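Package: cfeddy
Title: Larval Dispersal in a Cyclonic Eddy Scenario off Cape Frio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale biophysical dispersal experiment for sun-coral
    (Tubastraea spp.) planula larvae released over the Campos Basin shelf
    break during a Cape Frio cyclonic eddy event. Provides an analytically
    controlled synthetic ocean (Brazil-Current-like boundary jet plus a
    growing, translating cyclonic sea-surface-height depression), Lagrangian
    particle tracking with RK4 horizontal advection and random-walk vertical
    mixing, closed-contour eddy identification and tracking from daily SSH
    with swirl/translation/nonlinearity metrics, and the dispersal
    statistics that summarise larval capture by the eddy: trapped fractions,
    residence-distance correlation, depth and temperature exposure,
    vicinity analysis, coastal arrivals and density maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    grDevices,
    jsonlite,
    minpack.lm,
    ncdf4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
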