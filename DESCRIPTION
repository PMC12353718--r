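Package: dietopt
Title: Mixed-Integer Diet Optimisation Against Nutrient Reference Values
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and solves mixed-integer linear programs that design
    weekly diets meeting demographic-specific nutrient reference values
    (recommended dietary intakes as lower bounds, upper limits where
    defined) while minimising deviation from a baseline diet, total
    retail price, or total greenhouse-gas emissions, optionally under
    price or emission caps expressed as fractions of the baseline.
    Includes food-database compilation utilities (composition averaging,
    amino-acid normalisation to protein, bioavailability adjustment,
    per-kilogram price averaging), a config-driven scenario battery with
    tidy reporting, an exhaustive-enumeration oracle for verifying the
    solver on small instances, and a seeded synthetic-data generator
    with controlled feasibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with scipy >= 1.9 on PATH as
    'python' (HiGHS backend for scipy.optimize.milp)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
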