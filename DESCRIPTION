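Package: hospalloc
Title: Hospital Network Design Balancing Quality, Accessibility and Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing a regional or national hospital landscape as a
    mixed-integer program that allocates diagnosis groups to candidate hospital
    locations. The objective monetizes a volume-outcome quality relationship
    (QALYs gained by concentrating care on fewer locations) against patient
    travel costs, subject to maximum travel times per diagnosis group and
    minimum annual utilization of operating rooms, wards and intensive-care
    units. Includes calibration of piecewise-linear quality functions from a
    reference concentration scenario, a synthetic-instance generator (zip
    areas, candidate sites, drive-time matrices, demand spreading, resource
    usage), an exact brute-force oracle for small instances, an independent
    feasibility validator, willingness-to-pay sensitivity sweeps, travel-time
    reporting, and a command-line interface over CSV instance bundles.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH, used as
    the HiGHS mixed-integer solver backend.
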