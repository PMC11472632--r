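Package: optoclamp
Title: Whole-Cell Patch-Clamp Analysis for Photoswitchable Channel Activators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell patch-clamp recordings of
    light-gated (azobenzene photoswitch) ion-channel activators such as the
    TRPC6 agonists OptoDArG, PhoDAG and OptoBI-1.  Provides half-life
    kinetics fitting of current activation, deactivation and biphasic
    inactivation by Nelder-Mead simplex minimisation of the summed squared
    residuals; normalized slope conductance (NSC) of current-density-voltage
    relations via cubic smoothing splines with per-voltage nonparametric
    group comparison; nonparametric cohort statistics (Mann-Whitney U,
    Wilcoxon signed rank, Kruskal-Wallis, Friedman, Dunn's post hoc); and a
    seeded synthetic recording generator emulating constant-holding traces,
    voltage-ramp sweeps and thermal cis-to-trans relaxation time courses, so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
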