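Package: oxipredict
Title: Personalized Short-Horizon Forecasting of Oxygen Saturation from
    Pulse-Oximetry Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds personalized short-horizon forecasters of peripheral
    oxygen saturation (SpO2) from 1 Hz pulse-oximetry traces. Raw traces are
    segmented into time-continuous runs (a gap of more than 3 seconds starts
    a new run), turned into supervised sliding-window datasets parameterized
    by window size, stride and prediction horizon, and used to train small
    fully connected and gated recurrent forecasters under a repeated
    train/validation/test protocol. Candidate dataset/architecture
    combinations are ranked by a composite fitness score combining maximum
    absolute error, MSE, MAPE and MAE, and the winner is exported as a
    self-contained deployment bundle for streaming edge inference. A
    seedable simulator of ambulatory SpO2/heart-rate traces with
    desaturation episodes and sensor dropouts supports development and
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
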