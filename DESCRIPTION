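Package: perceptbias
Title: Optimal Perceptron Models of Choice and Contraction Bias in
    Delayed Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of two-alternative delayed
    frequency-discrimination experiments with biased feedback.
    Generates trial blocks with the task's stimulus statistics and five
    feedback protocols, models observers as noisy-representation linear
    discriminators (Perceptrons) whose contraction weight and decision
    criterion can be tuned to maximize expected feedback, fits the
    internal-noise parameter by maximum likelihood under the optimal
    Perceptron and psychometric-curve models, and provides the
    descriptive bias analyses (region-split psychometric curves,
    contraction-bias magnitude, impossible-trial choice-bias time
    courses) used to dissociate feedback-sensitive choice bias from
    feedback-insensitive contraction bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
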