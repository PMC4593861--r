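Package: motorsynergy
Title: Model-Based Muscle Synergies for One-Dimensional Operational Spaces
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Defines muscle synergies from a musculoskeletal model rather than
    from electromyographic recordings. For one-degree-of-freedom operational
    spaces (elbow angle, crank/steering angle) the effort-minimizing muscle
    force-sharing problem has a closed-form solution, and the ratios between
    optimal muscle activations are fixed, posture-dependent functions. The
    package implements Hill-type muscle mechanics, forward dynamics of
    one-degree-of-freedom plants, the closed-form force-sharing optimum with an
    independent quadratic-programming oracle, posture-dependent synergy-ratio
    tables, a non-negative matrix factorization baseline for static synergies,
    and feedback controllers (synergy-driven PID and forward static
    optimization) with tracking-versus-effort comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
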