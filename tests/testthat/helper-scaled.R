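# Scaled-down study conditions used by the simulation tests: the full
# 20-step design and candidate windows are kept, population sizes are
# reduced (4 sires, 16/8 dams, litters of 4) so that a replicated
# 12-scenario sweep fits in a routine test run. The same configuration is
# described in the methods vignette.
scaled_cfg <- function(scheme, goal, intensity, ...) {
  if (scheme == "OS") {
    scheme_config("OS", goal, intensity = intensity,
                  n_sires_org = 4L, n_dams_org = 16L, litter_size = 4L, ...)
  } else {
    scheme_config("CS", goal, intensity = intensity,
                  n_sires_conv = 4L, n_dams_conv = 16L,
                  n_sires_org = 4L, n_dams_org = 8L, litter_size = 4L, ...)
  }
}

# z statistic for the difference of two scenario means given their SEs
z_diff <- function(m1, se1, m2, se2) (m1 - m2) / sqrt(se1^2 + se2^2)

# pull a metric's mean/se from a scenario_result summary
metric_of <- function(x, metric, col = "mean") {
  s <- x$summary
  s[[col]][s$metric == metric]
}
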