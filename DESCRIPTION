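Package: sowactivity
Title: Peripartum Sow Activity Patterns and Piglet Outcome Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-frequency (5-second) posture and
    standing-activity streams of peripartum sows and linking daily behavioural
    traits to piglet survival and early growth. Provides a calibrated
    semi-Markov simulator of sow posture streams and piglet outcomes; stream
    despiking and posture-change counting; daily postural and standing-activity
    time budgets; isometric log-ratio (ILR) transformation of compositional
    budgets with cross-sectional and longitudinal k-means clustering and
    elbow-based model-size selection; and the three-step Cox proportional
    hazards and linear-model variable-selection protocol (AIC coding choice,
    per-period backward likelihood-ratio elimination, global model) with
    Kaplan-Meier and Schoenfeld-residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
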