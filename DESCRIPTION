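Package: flychron
Title: Circadian Locomotor Ethomics for Single-Housed Drosophila
Version: 0.1.0
Authors@R: person("flychron", "maintainers", email = "maintainers@flychron.org",
    role = c("aut", "cre"))
Description: A tested pipeline for video-derived circadian behavior analysis of
    individually housed flies: synthetic trajectory and video generation with
    known ground truth, centroid tracking from frame sequences, per-second
    displacement activity, sleep-bout scoring (five-minute immobility rule),
    the morning anticipation index (MAI), a virtual single-infrared-beam
    activity monitor emulator with Trikinetics-style file IO, a rank-based and
    parametric statistical battery (Kruskal-Wallis with Dunn post hoc,
    Scheirer-Ray-Hare, one- and two-way ANOVA with Tukey HSD, Wilcoxon tests
    with Benjamini-Hochberg correction, D'Agostino-Pearson normality gate),
    and maximum-projection threshold-ROI quantification of fluorescence
    z-stacks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
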