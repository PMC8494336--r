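Package: exertvalue
Title: Simulation and Model Fitting for Exercise Reward Valuation and
    Delay Discounting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse self-paced exercise studies in
    which elevated heart rate is evaluatively conditioned with a sweet
    taste. Provides the heart-rate-driven dual-pump reward controller and
    ramped interval-training schedule, an adjusting-amount (bisection)
    delay-discounting task for money, food and exercise commodities,
    hyperbolic (Mazur) discounting fits with goodness-of-fit exclusion
    rules, a shared-k hyperbolic effort-valuation model with exact sign
    tests, and a seeded synthetic-cohort generator so every stage can be
    exercised and validated by parameter recovery without raw study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
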