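Package: screenstate
Title: Derive Objective Smartphone Screen-State from ON/OFF Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital phenotyping studies that derive objective
    smartphone screen time ("screen-state") from raw screen ON/OFF event
    streams. Reconstructs continuous usage sessions from timestamped
    transition logs, applies a sensitivity grid of notification cut-points
    (minimum valid session duration), continuous-usage cut-points (maximum
    plausible session duration) and a 10 hours/day rule, splits sessions at
    local-day boundaries, aggregates to weekday/weekend participant means,
    and compares objective screen-state against self-reported screen time
    from an adapted sedentary behaviour questionnaire using Wilcoxon signed
    rank, paired t and rank correlation tests. Includes a seeded synthetic
    cohort simulator with ground truth (auto-notification blips, stuck-screen
    artifacts, under-reported questionnaires) so the full pipeline can be
    validated without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
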