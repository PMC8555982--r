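Package: costchoice
Title: Behavioral and Neuronal Analysis of Economic Choice Under Variable Action Costs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analyzing economic choice behavior and single-neuron
    activity in tasks where juice offers carry variable action (saccade)
    costs. Implements a per-session logistic choice model yielding relative
    value, action cost, hysteresis and spatial-bias parameters; computation
    of a panel of candidate decision variables in juice-, cost-, spatial-
    and action-based reference frames; task-relatedness screening of
    windowed firing rates by three-way ANOVA; tuning classification by
    parallel-lines and horizontal-lines ANCOVA models; stepwise and
    best-subset variable selection by explanatory power; a cost-affected
    versus cost-independent chosen-value model comparison; population-level
    nonparametric tests and cross-area comparisons; and a synthetic
    session and Poisson-spiking neuron generator so the full pipeline can
    be exercised without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
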