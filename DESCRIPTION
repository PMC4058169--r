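Package: cspsosvm
Title: Hybrid Cuckoo Search and Particle Swarm Tuning of Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Soft-margin kernel support vector machines trained by sequential
    minimal optimization, with hyperparameters (the penalty C and the kernel
    parameter) tuned by metaheuristic search: a two-stage cuckoo-search-then-
    particle-swarm hybrid (CS-PSO-SVM) together with particle swarm (PSO-SVM)
    and real-coded genetic algorithm (GA-SVM) baselines. Includes delimited-
    table readers for UCI-style clinical datasets, min-max normalization,
    stratified splitting, a two-class Gaussian synthetic data generator,
    cross-validation fitness, confusion-matrix metrics (accuracy, precision,
    recall, F-measure), convergence traces, and a comparison runner that
    benchmarks the three tuners on a shared split.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
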