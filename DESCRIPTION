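Package: HaploRich
Title: Truncated Power-Law Estimation of Haplotype and Allele Diversity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Richness and coverage estimation for heavy-tailed category
    frequency distributions, with HLA haplotype and allele registries as
    the motivating application. Models population relative frequencies as
    a truncated power law and provides closed-form estimators for the
    expected number of unique categories discovered at any sampling depth,
    the fraction of the population covered by observed categories, and the
    probability that a new draw carries an unseen category. Includes
    direct exponent estimators (Clauset continuous/discrete, a
    KS-selected-cutoff variant, and the Ohannessian singleton-ratio
    estimator), a discovery-curve fitting procedure that recovers the
    distribution parameters from subsampled data, a reproducible
    population simulator, classical richness comparators
    (capture-recapture, first-order jackknife, Chao1, ACE), and readers
    and writers for delimited frequency tables including six-locus HLA
    haplotype strings and allele marginalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), vegan, withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'HaploRich-package.R'
    'incompleteGamma.R'
    'powerModel.R'
    'occupancy.R'
    'alphaEstimators.R'
    'modelFitting.R'
    'classicalEstimators.R'
    'syntheticPopulation.R'
    'registryIO.R'
    'utils.R'
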