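#' Segment of a walker arm
#'
#' Arms are built from duplex segments (rigid rods, all duplexes here are far
#' below the ~50 nm dsDNA persistence length) and single-stranded segments
#' (freely-jointed chains of Kuhn links).
#'
#' @param kind `"duplex"` or `"single_stranded"` (abbreviations `"ds"`,
#'   `"ss"` accepted).
#' @param n_units Base pairs (duplex) or nucleotides (single-stranded).
#' @param contour_per_unit nm per unit; defaults 0.34 nm/bp for duplex and
#'   0.63 nm/nt for single-stranded DNA.
#' @param kuhn_length Kuhn length in nm for single-stranded segments
#'   (default 1.5 nm); ignored for duplexes.
#' @param label Optional name used in conformation dumps.
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(kind, n_units, contour_per_unit = NULL,
                         kuhn_length = 1.5, label = NULL) {
  kind <- switch(match.arg(kind, c("duplex", "single_stranded", "ds", "ss")),
                 ds = "duplex", ss = "single_stranded", kind)
  .check_num(n_units, "n_units", min = 1)
  if (is.null(contour_per_unit)) {
    contour_per_unit <- if (kind == "duplex") 0.34 else 0.63
  }
  .check_num(contour_per_unit, "contour_per_unit", min = 0, strict = TRUE)
  .check_num(kuhn_length, "kuhn_length", min = 0, strict = TRUE)
  structure(
    list(kind = kind, n_units = as.integer(n_units),
         contour_per_unit = contour_per_unit, kuhn_length = kuhn_length,
         label = label %||% kind),
    class = "segment_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

segment_contour <- function(seg) seg$n_units * seg$contour_per_unit

# Decompose one segment into link lengths (nm), anchor-proximal first.
# A duplex is one rigid link. An ss segment shorter than one Kuhn length is
# a single rigid link of its true contour; otherwise full Kuhn links plus a
# partial terminal link carrying the remaining contour.
segment_links <- function(seg) {
  L <- segment_contour(seg)
  if (seg$kind == "duplex") return(L)
  b <- seg$kuhn_length
  if (L <= b) return(L)
  n_full <- floor(L / b)
  rem <- L - n_full * b
  if (rem > 1e-9) c(rep(b, n_full), rem) else rep(b, n_full)
}

arm_links <- function(arm) unlist(lapply(arm, segment_links), use.names = FALSE)

arm_contour <- function(arm) sum(vapply(arm, segment_contour, numeric(1)))

#' Walker design: the two tethered arms of the leg-placing reaction
#'
#' Before contact the system is two independent tethered chains: the bound
#' arm (foothold-2 stem, the fuel-connected duplex complex, the inter-leg
#' hinge and the free leg, reactive end at the free leg's terminus) and the
#' fuel arm (foothold-1 stem, the foothold-fuel duplex and the fuel's free
#' overhang, reactive end at the overhang terminus). The leg-placing
#' transition state is reached when the two reactive ends approach within
#' the capture radius.
#'
#' @param arm_bound List of [segment_spec()] from anchor A outward.
#' @param arm_fuel List of [segment_spec()] from anchor B outward.
#' @param capture_radius Contact threshold in nm (default 1 nm, of order one
#'   base-pair bond distance).
#' @return An object of class `walker_design`.
#' @export
walker_design <- function(arm_bound, arm_fuel, capture_radius = 1.0) {
  stopifnot(length(arm_bound) >= 1, length(arm_fuel) >= 1)
  ok <- function(a) all(vapply(a, inherits, logical(1), "segment_spec"))
  if (!ok(arm_bound) || !ok(arm_fuel)) {
    stop("arms must be lists of segment_spec objects", call. = FALSE)
  }
  .check_num(capture_radius, "capture_radius", min = 0, strict = TRUE)
  structure(
    list(arm_bound = arm_bound, arm_fuel = arm_fuel,
         capture_radius = capture_radius),
    class = "walker_design"
  )
}

#' @export
print.walker_design <- function(x, ...) {
  fmt <- function(arm) paste(vapply(arm, function(s) {
    sprintf("%s[%d%s]", s$label, s$n_units,
            if (s$kind == "duplex") "bp" else "nt")
  }, character(1)), collapse = " + ")
  cat("<walker_design>\n")
  cat(sprintf("  bound arm: %s (contour %.2f nm)\n",
              fmt(x$arm_bound), arm_contour(x$arm_bound)))
  cat(sprintf("  fuel arm:  %s (contour %.2f nm)\n",
              fmt(x$arm_fuel), arm_contour(x$arm_fuel)))
  cat(sprintf("  capture radius: %.2f nm\n", x$capture_radius))
  invisible(x)
}

#' Default walker design
#'
#' Segment-level description of the walker studied here. The fuel is held on
#' the foothold by an 18 bp duplex and binds the leg by 16 bp. Contiguous
#' duplexes meeting at a nick are treated as one coaxially stacked rod
#' (nicked duplexes are predominantly stacked), so the bound arm is a short
#' foothold stem flexibly jointed (at the three-way junction where the bound
#' leg branches off) to a 34 bp stacked complex, followed by the
#' single-stranded inter-leg hinge and free leg; the fuel arm is a 24 bp
#' stacked stem+duplex rod carrying the single-stranded fuel overhang. Stem,
#' hinge and overhang lengths are set so the fully-stretched distal-termini
#' reach of the two arms reproduces the ~40 nm maximum step this walker
#' supports. Every length is overridable through the config.
#'
#' @param capture_radius Contact threshold in nm.
#' @return A [walker_design()].
#' @export
walker_default_design <- function(capture_radius = 1.0) {
  walker_design(
    arm_bound = list(
      segment_spec("duplex", 6, label = "T2_stem"),
      segment_spec("duplex", 34, label = "T2.F2.L2_stack"),
      segment_spec("single_stranded", 3, label = "hinge"),
      segment_spec("single_stranded", 15, label = "L1_free")
    ),
    arm_fuel = list(
      segment_spec("duplex", 24, label = "T1.F1_stack"),
      segment_spec("single_stranded", 9, label = "F1_overhang")
    ),
    capture_radius = capture_radius
  )
}

#' Track geometries
#'
#' The origami is reduced to a hard wall: a flat plane, or (for the short
#' axis, which prefers to curl) a cylinder whose circumference defaults to
#' the 60 nm origami width, with the walker on the convex side. `separation`
#' is the anchor-to-anchor distance: straight-line on the flat track, arc
#' length along the surface on the cylinder. `track_free()` removes the wall
#' entirely (used for closed-form sampler checks).
#'
#' @param separation Anchor separation in nm (step size `d`).
#' @param radius Cylinder radius in nm; default `60 / (2*pi)`.
#' @param walker_side Side of the curved surface the walker occupies; only
#'   `"convex"` is supported.
#' @return An object of class `track_geometry`.
#' @export
track_flat <- function(separation = 0) {
  .check_num(separation, "separation", min = 0)
  structure(list(kind = "flat", separation = separation),
            class = "track_geometry")
}

#' @rdname track_flat
#' @export
track_cylinder <- function(separation = 0, radius = 60 / (2 * pi),
                           walker_side = "convex") {
  .check_num(separation, "separation", min = 0)
  .check_num(radius, "radius", min = 0, strict = TRUE)
  walker_side <- match.arg(walker_side, "convex")
  structure(
    list(kind = "cylinder", separation = separation, radius = radius,
         walker_side = walker_side),
    class = "track_geometry"
  )
}

#' @rdname track_flat
#' @export
track_free <- function(separation = 0) {
  .check_num(separation, "separation", min = 0)
  structure(list(kind = "free", separation = separation),
            class = "track_geometry")
}

with_separation <- function(track, separation) {
  track$separation <- separation
  track
}

#' Chord length from an arc on a cylinder
#'
#' Through-space distance between two surface points separated by arc length
#' `s` on a cylinder of radius `R`. Beyond half the circumference the shorter
#' way around is used, which is why footholds at large arc separations on a
#' curled-up origami can still be geometrically close.
#'
#' @param s Arc length(s) in nm, `>= 0`.
#' @param R Cylinder radius in nm, `> 0`.
#' @return Chord length(s) in nm.
#' @examples
#' chord_from_arc(pi * 10, 10) # diameter = 20
#' @export
chord_from_arc <- function(s, R) {
  .check_num(s, "s", min = 0)
  .check_num(R, "R", min = 0, strict = TRUE)
  circ <- 2 * pi * R
  s_eff <- pmin(s %% circ, circ - s %% circ)
  2 * R * sin(s_eff / (2 * R))
}

# anchor points and wall predicate for each track kind; the cylinder axis is
# the x-axis and anchors sit at the same axial position.
track_frame <- function(track) {
  switch(track$kind,
    flat = list(
      anchor_A = c(0, 0, 0),
      anchor_B = c(track$separation, 0, 0)
    ),
    free = list(
      anchor_A = c(0, 0, 0),
      anchor_B = c(track$separation, 0, 0)
    ),
    cylinder = {
      R <- track$radius
      circ <- 2 * pi * R
      s <- track$separation %% circ
      theta <- min(s, circ - s) / R
      list(
        anchor_A = c(0, 0, R),
        anchor_B = c(0, R * sin(theta), R * cos(theta)),
        theta = theta
      )
    },
    stop("unknown track kind", call. = FALSE)
  )
}

#' Maximum reachable step size of a design
#'
#' Largest anchor separation at which the two reactive ends can still meet:
#' the sum of both arms' contour lengths plus the capture radius. On the flat
#' track the limiting configuration lies along the surface, which the
#' hard-wall constraint permits, so no further correction applies. On the
#' cylinder the same bound applies to the shorter-way-around arc separation;
#' a chain hugging the convex surface approximates the arc, so the bound is
#' slightly optimistic there (by the chord-vs-arc difference per link).
#'
#' @param design A [walker_design()].
#' @param track A track geometry (default flat).
#' @return Reach in nm. On a cylinder, `Inf` means every arc separation is
#'   reachable the shorter way around.
#' @export
max_reach <- function(design, track = track_flat()) {
  stopifnot(inherits(design, "walker_design"))
  reach <- arm_contour(design$arm_bound) + arm_contour(design$arm_fuel) +
    design$capture_radius
  if (inherits(track, "track_geometry") && track$kind == "cylinder") {
    half <- pi * track$radius
    if (reach >= half) return(Inf)
  }
  reach
}
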