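# Small fixture geometries used across tests, all built in code.

# one rigid rod per arm, length b nm (duplex with 1 nm/bp for round numbers)
rod_arm <- function(b) list(segment_spec("duplex", b, contour_per_unit = 1))

rod_design <- function(b, capture_radius = 0.5) {
  walker_design(rod_arm(b), rod_arm(b), capture_radius = capture_radius)
}

# a pure two-link freely-jointed chain (link length 1.5 nm)
two_link_arm <- function() {
  list(segment_spec("single_stranded", 2, contour_per_unit = 1.5,
                    kuhn_length = 1.5))
}

default_calibration <- list(d_ref = 12, k_s_ref = 3, k_FB = 2.3e5)
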