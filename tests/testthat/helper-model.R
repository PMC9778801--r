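# Shared fixtures: the basal parameter set, common variants, and a variant
# with all ROS-producing reactions switched off (pure electron transfer).
base_ps <- build_base_parameters()

ros_off <- function(ps = base_ps) {
  make_variant(ps, list(k17 = 0, k18 = 0, k19 = 0, k20 = 0),
               label = "ros-off")
}

slow_release <- function(k = 1e-2, ps = base_ps) {
  make_variant(ps, list(k14 = k, k16 = k),
               label = sprintf("k14=k16=%g", k))
}

slow_fum_binding <- function(k = 1e-4, ps = base_ps) {
  make_variant(ps, list(k10 = k, k12 = k),
               label = sprintf("k10=k12=%g", k))
}

# relative difference helper
rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.xmin)
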