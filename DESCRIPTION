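Package: poem
Title: Point of Care Microcirculation (POEM) Scoring and Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the point of care microcirculation (POEM) grading
    system for sublingual video-microscopy: per-clip classification of
    microvascular flow (normal, impaired, critically impaired, from the
    fraction of sluggish/stopped vessel segments) and heterogeneity
    (more than five segments flowing differently from the remainder),
    and aggregation of four clips into the 1-5 ordinal POEM score.
    Also computes the consensus comparator parameters (total and
    perfused vessel density, proportion of perfused vessels,
    quadrant-based microcirculatory flow index, and the heterogeneity
    index) from the same segment-level annotations, the rater-agreement
    statistics used to validate such ordinal scores (two-way intraclass
    correlation with confidence intervals, error-score regression,
    linear R-squared, Kruskal-Wallis with Dunn's pairwise comparisons),
    and a synthetic vessel-field simulator with controllable severity,
    heterogeneity and rater noise for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'scoring.R'
    'consensus.R'
    'agreement.R'
    'simulate.R'
    'io.R'
    'cli.R'
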