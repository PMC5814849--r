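# Contact-probability estimators. The transition state of leg placing is a
# first base pair between the two reactive ends, modelled as the two ends
# approaching within the capture radius delta. Because the two molecules are
# independent before contact, P(contact) factorises into an overlap integral
# of the two end densities:
#   p ~ (4*pi/3) * delta^3 * integral rho_A(r) rho_B(r) dr,
# valid when the densities are smooth on the scale of delta. The integral is
# evaluated on a shared voxel grid with each cloud KDE-smoothed; this
# resolves the rare-contact regime (p << 1e-6 near maximal reach) that a
# direct pairwise hit counter cannot reach. The direct counter is kept as an
# internal cross-check where hits are common enough.

# symmetric grid-product overlap estimator with multinomial bootstrap
.overlap_from_clouds <- function(endsA, endsB, delta, bandwidth = 1,
                                 voxel = 1, n_boot = 30, seed = 1L) {
  pad <- 4 * max(bandwidth, voxel)
  loA <- apply(endsA, 2, min) - pad; hiA <- apply(endsA, 2, max) + pad
  loB <- apply(endsB, 2, min) - pad; hiB <- apply(endsB, 2, max) + pad
  lo <- pmax(loA, loB); hi <- pmin(hiA, hiB)
  if (any(hi <= lo)) {
    return(list(p = 0, se = 0))
  }
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  nA <- as.numeric(nrow(endsA)); nB <- as.numeric(nrow(endsB))
  cA <- .bin_counts(endsA, lo, voxel, dims)
  cB <- .bin_counts(endsB, lo, voxel, dims)
  if (sum(cA) == 0 || sum(cB) == 0) {
    return(list(p = 0, se = 0))
  }
  sigma <- bandwidth / voxel
  vol <- voxel^3
  pref <- (4 * pi / 3) * delta^3
  p_of <- function(a, b) {
    pref * sum(.smooth3d(a, sigma) * .smooth3d(b, sigma)) / (nA * nB * vol)
  }
  p_hat <- p_of(cA, cB)
  se <- 0
  if (n_boot > 0 && p_hat > 0) {
    set.seed(as.integer(seed))
    boot_counts <- function(counts, n_total) {
      occ <- which(counts > 0)
      probs <- c(counts[occ], n_total - sum(counts)) / n_total
      draw <- stats::rmultinom(n_boot, n_total, probs)
      list(occ = occ, draw = draw[seq_along(occ), , drop = FALSE])
    }
    bA <- boot_counts(cA, nA)
    bB <- boot_counts(cB, nB)
    reps <- vapply(seq_len(n_boot), function(r) {
      a <- array(0, dim = dims); a[bA$occ] <- bA$draw[, r]
      b <- array(0, dim = dims); b[bB$occ] <- bB$draw[, r]
      p_of(a, b)
    }, numeric(1))
    se <- stats::sd(reps)
  }
  list(p = p_hat, se = se)
}

# paired direct hit counter
.direct_from_clouds <- function(endsA, endsB, delta) {
  m <- min(nrow(endsA), nrow(endsB))
  d2 <- rowSums((endsA[seq_len(m), , drop = FALSE] -
                   endsB[seq_len(m), , drop = FALSE])^2)
  p <- mean(d2 <= delta^2)
  list(p = p, se = sqrt(p * (1 - p) / m), n_pairs = m,
       n_hits = sum(d2 <= delta^2))
}

#' Activation-barrier difference from contact probabilities
#'
#' In the reach-limited picture the step-size dependence of the leg-placing
#' barrier is the entropic cost of bringing the two reactive ends together,
#' so barrier differences follow from contact-probability ratios:
#' `ddG = -ln(p_d / p_ref)` in k_B T. A vanishing contact probability maps
#' to an infinite barrier.
#'
#' @param p_d Contact probability at the step size of interest.
#' @param p_ref Reference contact probability, `> 0`.
#' @return Barrier difference(s) in k_B T.
#' @export
delta_barrier <- function(p_d, p_ref) {
  .check_num(p_d, "p_d", min = 0)
  .check_num(p_ref, "p_ref", min = 0)
  if (any(p_ref == 0)) {
    stop("undefined reference: p_ref must be positive", call. = FALSE)
  }
  ifelse(p_d == 0, Inf, -log(p_d / p_ref))
}

#' Contact probability of the two reactive ends
#'
#' Samples the two arms independently over the track wall and estimates the
#' probability that their reactive ends lie within the capture radius. The
#' default estimator is the KDE overlap integral; `method = "direct"` counts
#' paired hits (only useful where contacts are not rare). Separations beyond
#' [max_reach()] return an exact zero without sampling.
#'
#' @param x A [walker_design()] or the result of [apply_hairpin()].
#' @param track Track geometry carrying the anchor `separation` (step size).
#' @param n Accepted conformations per arm.
#' @param seed Integer master seed (per-arm sub-streams are derived).
#' @param method `"overlap"` (default) or `"direct"`.
#' @param bandwidth KDE bandwidth in nm.
#' @param voxel Grid voxel edge in nm.
#' @param n_boot Bootstrap replicates for the overlap stderr.
#' @param ref_p Optional reference contact probability; when given,
#'   `dG_rel` is filled via [delta_barrier()].
#' @return An object of class `contact_estimate` with fields `d`,
#'   `p_contact`, `stderr`, `dG_rel`, `n_samples`, `seed`, `method`.
#' @export
contact_probability <- function(x, track, n = 1e4, seed = 1L,
                                method = c("overlap", "direct"),
                                bandwidth = 1, voxel = 1, n_boot = 30,
                                ref_p = NULL) {
  UseMethod("contact_probability")
}

.contact_estimate <- function(d, p, se, n, seed, method, ref_p = NULL) {
  structure(
    list(d = d, p_contact = p, stderr = se,
         dG_rel = if (is.null(ref_p)) NA_real_ else delta_barrier(p, ref_p),
         n_samples = n, seed = seed, method = method),
    class = "contact_estimate"
  )
}

#' @export
print.contact_estimate <- function(x, ...) {
  cat(sprintf(
    "<contact_estimate> d = %g nm: p = %.3g (se %.2g), dG_rel = %s kBT [%s, n = %g]\n",
    x$d, x$p_contact, x$stderr,
    if (is.na(x$dG_rel)) "NA" else sprintf("%.3g", x$dG_rel),
    x$method, x$n_samples
  ))
  invisible(x)
}

#' @export
contact_probability.walker_design <- function(x, track, n = 1e4, seed = 1L,
                                              method = c("overlap", "direct"),
                                              bandwidth = 1, voxel = 1,
                                              n_boot = 30, ref_p = NULL) {
  method <- match.arg(method)
  .check_num(n, "n", min = 1)
  reach <- max_reach(x, track)
  sep_eff <- if (track$kind == "cylinder") {
    circ <- 2 * pi * track$radius
    s <- track$separation %% circ
    min(s, circ - s)
  } else {
    track$separation
  }
  if (is.finite(reach) && sep_eff > reach) {
    return(.contact_estimate(track$separation, 0, 0, as.integer(n),
                             as.integer(seed), method, ref_p))
  }
  fr <- track_frame(track)
  edA <- sample_end_density(x$arm_bound, track, anchor = fr$anchor_A,
                            n = n, seed = derive_seed(seed, "arm_bound"))
  edB <- sample_end_density(x$arm_fuel, track, anchor = fr$anchor_B,
                            n = n, seed = derive_seed(seed, "arm_fuel"))
  est <- if (method == "overlap") {
    .overlap_from_clouds(edA$ends, edB$ends, x$capture_radius,
                         bandwidth = bandwidth, voxel = voxel,
                         n_boot = n_boot, seed = derive_seed(seed, "boot"))
  } else {
    .direct_from_clouds(edA$ends, edB$ends, x$capture_radius)
  }
  .contact_estimate(track$separation, est$p, est$se, as.integer(n),
                    as.integer(seed), method, ref_p)
}

#' Fuel-hairpin model
#'
#' A transient hairpin in the fuel's free overhang (when bound to the
#' foothold) sequesters part of the overhang, shortening the effective fuel
#' arm and pulling the reactive end away from where the first leg-placing
#' base pair must form. `dG_hp` is the folding free energy in k_B T
#' (negative = folded favoured); the open-state probability is the
#' two-state weight `1 / (1 + exp(-dG_hp))`.
#'
#' @param dG_hp Folding free energy (k_B T).
#' @param sequestered_units Overhang nucleotides unavailable when folded.
#' @return An object of class `hairpin_model`.
#' @export
hairpin_model <- function(dG_hp, sequestered_units) {
  .check_num(dG_hp, "dG_hp", allow_inf = TRUE)
  .check_num(sequestered_units, "sequestered_units", min = 0)
  structure(
    list(dG_hp = dG_hp, sequestered_units = as.integer(sequestered_units)),
    class = "hairpin_model"
  )
}

#' Apply a fuel hairpin to a walker design
#'
#' Builds the two-state contact model: with probability `p_open` the full
#' overhang is available, otherwise the overhang is shortened by the
#' sequestered nucleotides. Contact probabilities of the mixture are
#' `p_eff = p_open * p_full + (1 - p_open) * p_short`.
#'
#' @param design A [walker_design()].
#' @param hp A [hairpin_model()].
#' @return An object of class `hairpin_contact_model` usable with
#'   [contact_probability()] and [predict_yield_curve()].
#' @export
apply_hairpin <- function(design, hp) {
  stopifnot(inherits(design, "walker_design"), inherits(hp, "hairpin_model"))
  arm <- design$arm_fuel
  iss <- which(vapply(arm, function(s) s$kind == "single_stranded", logical(1)))
  if (length(iss) == 0) {
    stop("fuel arm has no single-stranded overhang to sequester", call. = FALSE)
  }
  last <- max(iss)
  overhang <- arm[[last]]$n_units
  if (hp$sequestered_units > overhang) {
    stop(sprintf(
      "sequestered_units (%d) exceeds overhang length (%d nt)",
      hp$sequestered_units, overhang
    ), call. = FALSE)
  }
  folded <- design
  if (hp$sequestered_units == overhang) {
    folded$arm_fuel <- arm[-last]
    if (length(folded$arm_fuel) == 0) {
      stop("folded fuel arm would be empty", call. = FALSE)
    }
  } else if (hp$sequestered_units > 0) {
    folded$arm_fuel[[last]]$n_units <- overhang - hp$sequestered_units
  }
  structure(
    list(open = design, folded = folded,
         p_open = 1 / (1 + exp(-hp$dG_hp)), hairpin = hp),
    class = "hairpin_contact_model"
  )
}

#' @export
contact_probability.hairpin_contact_model <- function(x, track, n = 1e4,
                                                      seed = 1L,
                                                      method = c("overlap", "direct"),
                                                      bandwidth = 1, voxel = 1,
                                                      n_boot = 30,
                                                      ref_p = NULL) {
  method <- match.arg(method)
  po <- x$p_open
  co <- contact_probability(x$open, track, n = n,
                            seed = derive_seed(seed, "hp_open"),
                            method = method, bandwidth = bandwidth,
                            voxel = voxel, n_boot = n_boot)
  cf <- contact_probability(x$folded, track, n = n,
                            seed = derive_seed(seed, "hp_folded"),
                            method = method, bandwidth = bandwidth,
                            voxel = voxel, n_boot = n_boot)
  p <- po * co$p_contact + (1 - po) * cf$p_contact
  se <- sqrt((po * co$stderr)^2 + ((1 - po) * cf$stderr)^2)
  .contact_estimate(track$separation, p, se, as.integer(n),
                    as.integer(seed), method, ref_p)
}

# transform a fuel-arm cloud sampled at the local anchor into the frame
# where it is separated from arm A by `sep` (translation on flat/free
# tracks, rotation about the cylinder axis on curved ones).
.place_cloud <- function(ends, track, sep) {
  if (track$kind %in% c("flat", "free")) {
    ends[, 1] <- ends[, 1] + sep
    return(ends)
  }
  R <- track$radius
  circ <- 2 * pi * R
  s <- sep %% circ
  theta <- min(s, circ - s) / R
  y <- ends[, 2]; z <- ends[, 3]
  ends[, 2] <- y * cos(theta) + z * sin(theta)
  ends[, 3] <- -y * sin(theta) + z * cos(theta)
  ends
}

# internal: contact probabilities over a separation grid from shared clouds
.contact_grid <- function(design, track, d_all, n, seed, bandwidth, voxel,
                          n_boot) {
  base <- with_separation(track, 0)
  fr <- track_frame(base)
  edA <- sample_end_density(design$arm_bound, base, anchor = fr$anchor_A,
                            n = n, seed = derive_seed(seed, "arm_bound"))
  edB <- sample_end_density(design$arm_fuel, base, anchor = fr$anchor_A,
                            n = n, seed = derive_seed(seed, "arm_fuel"))
  reach <- max_reach(design, track)
  out <- lapply(seq_along(d_all), function(i) {
    d <- d_all[i]
    sep_eff <- if (track$kind == "cylinder") {
      circ <- 2 * pi * track$radius
      s <- d %% circ
      min(s, circ - s)
    } else d
    if (is.finite(reach) && sep_eff > reach) {
      return(list(p = 0, se = 0))
    }
    endsB <- .place_cloud(edB$ends, track, d)
    .overlap_from_clouds(edA$ends, endsB, design$capture_radius,
                         bandwidth = bandwidth, voxel = voxel,
                         n_boot = n_boot,
                         seed = derive_seed(seed, paste0("boot", i)))
  })
  list(p = vapply(out, `[[`, numeric(1), "p"),
       se = vapply(out, `[[`, numeric(1), "se"))
}

#' Predict the yield curve from the mechanical model
#'
#' Chains the mechanics and kinetics: contact probabilities over the step
#' grid give relative activation barriers `ddG(d) = -ln(p(d)/p(d_ref))`,
#' the calibration anchors the absolute scale via
#' `k_s(d) = k_s_ref * exp(-ddG(d))`, and the kinetic competition converts
#' rates into yields for each fuel concentration. Arm clouds are sampled
#' once per arm and re-placed for every separation (translation on the flat
#' track, rotation on the cylinder), which the hard-wall constraint leaves
#' exact.
#'
#' @param x A [walker_design()] or [apply_hairpin()] result.
#' @param track Track geometry template (its `separation` is ignored).
#' @param d_grid Step sizes in nm.
#' @param F1_list Fuel concentrations in M.
#' @param calibration List with `d_ref` (nm), `k_s_ref` (s^-1), `k_FB`
#'   (M^-1 s^-1).
#' @param n Accepted conformations per arm.
#' @param seed Integer master seed.
#' @param bandwidth,voxel,n_boot Overlap-estimator controls.
#' @return A `data.frame` (class `yield_curve`) with columns
#'   `step_size_nm`, `fuel_conc_M`, `yield`, `yield_se`, `source`; the
#'   per-step contact table is attached as attribute `"contacts"`.
#' @export
predict_yield_curve <- function(x, track, d_grid,
                                F1_list,
                                calibration = list(d_ref = 12, k_s_ref = 3,
                                                   k_FB = 2.3e5),
                                n = 1e5, seed = 1L, bandwidth = 1,
                                voxel = 1, n_boot = 30) {
  stopifnot(inherits(track, "track_geometry"))
  .check_num(d_grid, "d_grid", min = 0)
  .check_num(F1_list, "F1_list", min = 0)
  .check_num(calibration$d_ref, "calibration$d_ref", min = 0)
  .check_num(calibration$k_s_ref, "calibration$k_s_ref", min = 0, strict = TRUE)
  .check_num(calibration$k_FB, "calibration$k_FB", min = 0, strict = TRUE)
  d_all <- c(d_grid, calibration$d_ref)
  grids <- if (inherits(x, "hairpin_contact_model")) {
    go <- .contact_grid(x$open, track, d_all, n, derive_seed(seed, "hp_open"),
                        bandwidth, voxel, n_boot)
    gf <- .contact_grid(x$folded, track, d_all, n,
                        derive_seed(seed, "hp_folded"),
                        bandwidth, voxel, n_boot)
    list(p = x$p_open * go$p + (1 - x$p_open) * gf$p,
         se = sqrt((x$p_open * go$se)^2 + ((1 - x$p_open) * gf$se)^2))
  } else if (inherits(x, "walker_design")) {
    .contact_grid(x, track, d_all, n, seed, bandwidth, voxel, n_boot)
  } else {
    stop("'x' must be a walker_design or hairpin_contact_model", call. = FALSE)
  }
  iref <- length(d_all)
  p_ref <- grids$p[iref]
  if (p_ref <= 0) {
    stop(sprintf(
      "reference step size %.3g nm has zero contact probability; cannot calibrate",
      calibration$d_ref
    ), call. = FALSE)
  }
  idx <- seq_along(d_grid)
  p_d <- grids$p[idx]
  ddG <- delta_barrier(p_d, p_ref)
  rel_se <- sqrt(ifelse(p_d > 0, (grids$se[idx] / p_d)^2, 0) +
                   (grids$se[iref] / p_ref)^2)
  k_s <- calibration$k_s_ref * exp(-ddG)
  rows <- expand.grid(step_size_nm = d_grid, fuel_conc_M = F1_list,
                      KEEP.OUT.ATTRS = FALSE)
  ks_row <- k_s[match(rows$step_size_nm, d_grid)]
  rel_row <- rel_se[match(rows$step_size_nm, d_grid)]
  Y <- ifelse(ks_row == 0 & rows$fuel_conc_M == 0, 1,
              ifelse(ks_row == 0, 0,
                     ks_row / (ks_row + calibration$k_FB * rows$fuel_conc_M)))
  out <- data.frame(
    step_size_nm = rows$step_size_nm,
    fuel_conc_M = rows$fuel_conc_M,
    yield = Y,
    yield_se = Y * (1 - Y) * rel_row,   # delta method through ln k_s
    source = "model",
    stringsAsFactors = FALSE
  )
  attr(out, "contacts") <- data.frame(
    d_nm = d_grid, p_contact = p_d, p_stderr = grids$se[idx],
    dG_rel_kBT = ddG, k_s = k_s, n_samples = n, seed = as.integer(seed)
  )
  attr(out, "calibration") <- calibration
  class(out) <- c("yield_curve", "data.frame")
  out
}
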