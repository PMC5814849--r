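#' Kinetic parameters of the leg-placing / trapping race
#'
#' The leg-placing reaction is a kinetic competition: from the fuel-bound
#' intermediate the walker either places its free leg on the foothold
#' (intramolecular, rate `k_s`) or binds a second fuel strand from solution
#' and falls into the irreversible trapped state (pseudo-first-order, rate
#' `k_FB * F1`). Trapping is absorbing, so the long-time leg-placed fraction
#' is set entirely by this race.
#'
#' @param k_s Stepping rate (s^-1).
#' @param k_FB Fuel-binding rate constant (M^-1 s^-1). Default 2.3e5, the
#'   experimentally determined value for this walker.
#' @param F1 Fuel concentration (M).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(k_s = 1, F1 = 1e-9)
#' @export
kinetic_params <- function(k_s, k_FB = 2.3e5, F1) {
  .check_num(k_s, "k_s", min = 0)
  .check_num(k_FB, "k_FB", min = 0)
  .check_num(F1, "F1", min = 0)
  structure(list(k_s = k_s, k_FB = k_FB, F1 = F1), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> k_s = %g s^-1, k_FB = %g M^-1 s^-1, [F1] = %g M\n",
    x$k_s, x$k_FB, x$F1
  ))
  invisible(x)
}

#' Leg-placing yield from the kinetic competition
#'
#' Fraction of motors reaching the leg-placed state,
#' `Y = k_s / (k_s + k_FB * F1)`. With no fuel in solution (`F1 = 0`) and a
#' positive stepping rate every motor places its leg and the yield is 1.
#'
#' @param p A [kinetic_params()] object, or a stepping rate `k_s` when
#'   `k_FB` and `F1` are supplied directly.
#' @param k_FB,F1 Rate constant and fuel concentration, used when `p` is
#'   numeric. Any of the three may be vectors (recycled).
#' @return Yield(s) in `[0, 1]`.
#' @examples
#' yield_from_rates(kinetic_params(k_s = 1, F1 = 1e-9))
#' @export
yield_from_rates <- function(p, k_FB = NULL, F1 = NULL) {
  if (inherits(p, "kinetic_params")) {
    k_s <- p$k_s; k_FB <- p$k_FB; F1 <- p$F1
  } else {
    k_s <- p
    .check_num(k_s, "k_s", min = 0)
    .check_num(k_FB, "k_FB", min = 0)
    .check_num(F1, "F1", min = 0)
  }
  trap <- k_FB * F1
  if (any(k_s == 0 & trap == 0)) {
    stop("undefined competition: both k_s and k_FB*F1 are zero", call. = FALSE)
  }
  k_s / (k_s + trap)
}

#' Stepping rate from a measured yield
#'
#' Inverts the kinetic-competition yield: `k_s = k_FB * F1 * Y / (1 - Y)`.
#' This is how experimental stepping rates are obtained from measured yields
#' once the fuel-binding rate constant is known.
#'
#' @param Y Yield strictly inside (0, 1).
#' @param k_FB Fuel-binding rate constant (M^-1 s^-1).
#' @param F1 Fuel concentration (M); `k_FB * F1` must be positive.
#' @return Stepping rate(s) in s^-1.
#' @examples
#' stepping_rate_from_yield(0.132, k_FB = 2.3e5, F1 = 1e-9) # ~3.5e-5 s^-1
#' @export
stepping_rate_from_yield <- function(Y, k_FB, F1) {
  .check_num(Y, "Y", min = 0)
  if (any(Y > 1)) stop("'Y' must be within [0, 1]", call. = FALSE)
  if (any(Y == 0 | Y == 1)) {
    stop("yield of exactly 0 or 1 is not invertible to a finite rate",
         call. = FALSE)
  }
  .check_num(k_FB, "k_FB", min = 0)
  .check_num(F1, "F1", min = 0)
  if (any(k_FB * F1 <= 0)) {
    stop("'k_FB * F1' must be positive to extract a stepping rate",
         call. = FALSE)
  }
  k_FB * F1 * Y / (1 - Y)
}

#' Activation-barrier pair for the yield model
#'
#' Holds the leg-placing activation free energy and the fuel-binding
#' activation free energy at a reference concentration, both in units of
#' `k_B T`. `dG_s = Inf` encodes a geometrically impossible placement.
#'
#' @param dG_s Leg-placing activation free energy (k_B T).
#' @param dG_FB0 Fuel-binding activation free energy at concentration `c0`.
#' @param c0 Reference concentration (M), default 1 M.
#' @return An object of class `barrier_pair`.
#' @export
barrier_pair <- function(dG_s, dG_FB0, c0 = 1) {
  .check_num(dG_s, "dG_s", allow_inf = TRUE)
  .check_num(dG_FB0, "dG_FB0", allow_inf = TRUE)
  .check_num(c0, "c0", min = 0, strict = TRUE)
  structure(list(dG_s = dG_s, dG_FB0 = dG_FB0, c0 = c0),
            class = "barrier_pair")
}

#' Concentration-dependent fuel-binding barrier
#'
#' Pseudo-first-order convention: the fuel-binding rate is linear in fuel
#' concentration, so its effective activation free energy falls by
#' `ln(F1/c0)` (in k_B T) relative to the reference concentration:
#' `dG_FB(F1) = dG_FB0 - ln(F1/c0)`.
#'
#' @param F1 Fuel concentration (M), positive.
#' @param b A [barrier_pair()].
#' @return Barrier(s) in k_B T.
#' @export
fuel_binding_barrier <- function(F1, b) {
  stopifnot(inherits(b, "barrier_pair"))
  .check_num(F1, "F1", min = 0, strict = TRUE)
  b$dG_FB0 - log(F1 / b$c0)
}

#' Leg-placing yield from activation barriers
#'
#' Barrier form of the competition: assuming the two rates share a common
#' attempt prefactor, the yield is the two-state Boltzmann weight
#' `exp(-dG_s) / (exp(-dG_s) + exp(-dG_FB(F1)))` with both barriers in
#' k_B T. An infinite leg-placing barrier gives yield 0.
#'
#' @param b A [barrier_pair()].
#' @param F1 Fuel concentration (M), positive.
#' @return Yield(s) in `[0, 1]`.
#' @export
yield_from_barriers <- function(b, F1) {
  stopifnot(inherits(b, "barrier_pair"))
  dG_fb <- fuel_binding_barrier(F1, b)
  # computed on the log scale so huge barriers do not underflow pairwise
  delta <- b$dG_s - dG_fb                 # Inf when placement impossible
  ifelse(is.infinite(delta) & delta > 0, 0, 1 / (1 + exp(delta)))
}

#' Relative stepping rate from a barrier difference
#'
#' `k_s(d) / k_s(ref) = exp(-(dG_d - dG_ref))`, the ratio of Arrhenius
#' rates when only the activation free energy changes with step size.
#'
#' @param dG_d Barrier at the step size of interest (k_B T); may be `Inf`.
#' @param dG_ref Barrier at the reference step size (k_B T), finite.
#' @return Dimensionless rate ratio.
#' @export
relative_stepping_rate <- function(dG_d, dG_ref) {
  .check_num(dG_d, "dG_d", allow_inf = TRUE)
  .check_num(dG_ref, "dG_ref")
  exp(-(dG_d - dG_ref))
}

#' Stochastic race oracle for the leg-placing competition
#'
#' Resolves each motor by an explicit exponential-clock race: waiting times
#' for stepping and for trapping are drawn independently and the earlier
#' event wins. Serves as an independent simulation oracle for
#' [yield_from_rates()].
#'
#' @param p A [kinetic_params()] object.
#' @param n_motors Number of independent motors (>= 1).
#' @param seed Integer RNG seed.
#' @return List with `fraction_placed`, binomial `stderr`, `n_motors`,
#'   `seed`.
#' @export
simulate_race <- function(p, n_motors, seed) {
  stopifnot(inherits(p, "kinetic_params"))
  .check_num(n_motors, "n_motors", min = 1)
  trap <- p$k_FB * p$F1
  if (p$k_s == 0 && trap == 0) {
    stop("undefined competition: both k_s and k_FB*F1 are zero", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- as.integer(n_motors)
  if (p$k_s == 0) {
    placed <- 0L
  } else if (trap == 0) {
    placed <- n
  } else {
    t_step <- stats::rexp(n, rate = p$k_s)
    t_trap <- stats::rexp(n, rate = trap)
    placed <- sum(t_step < t_trap)
  }
  frac <- placed / n
  list(
    fraction_placed = frac,
    stderr = sqrt(frac * (1 - frac) / n),
    n_motors = n,
    seed = as.integer(seed)
  )
}

#' Cumulative yield of a multi-step walk
#'
#' Independent identical steps compound geometrically:
#' `Y_total = per_step ^ n_steps`. A 97.47% per-step yield over 32 steps
#' gives ~44% total, matching the operational yield reported for this
#' walker's 32-step run.
#'
#' @param per_step Per-step yield in `[0, 1]`.
#' @param n_steps Number of steps (>= 0).
#' @return Total yield.
#' @export
cumulative_walk_yield <- function(per_step, n_steps) {
  .check_num(per_step, "per_step", min = 0)
  if (any(per_step > 1)) stop("'per_step' must be within [0, 1]", call. = FALSE)
  .check_num(n_steps, "n_steps", min = 0)
  per_step ^ n_steps
}

#' Map kinetic rates onto an equivalent barrier pair
#'
#' With a common attempt prefactor `A` (s^-1), `dG = -ln(k/A)` converts the
#' rate picture into the barrier picture; the two yield formulas are then
#' algebraically identical for every fuel concentration.
#'
#' @param p A [kinetic_params()].
#' @param A Attempt prefactor (s^-1), default 1.
#' @param c0 Reference concentration (M), default 1 M.
#' @return A [barrier_pair()].
#' @export
barriers_from_rates <- function(p, A = 1, c0 = 1) {
  stopifnot(inherits(p, "kinetic_params"))
  .check_num(A, "A", min = 0, strict = TRUE)
  barrier_pair(
    dG_s = -log(p$k_s / A),
    dG_FB0 = -log(p$k_FB * c0 / A),
    c0 = c0
  )
}

#' Parse a concentration string to molar
#'
#' Accepts tokens such as `"1 nM"`, `"100 nM"`, `"10 uM"` (micro sign
#' allowed), `"2 mM"`, `"1 M"`, or a bare number already in molar.
#'
#' @param x Character vector (or numeric, returned as-is).
#' @return Numeric vector of concentrations in molar.
#' @examples
#' parse_concentration("10 nM") # 1e-8
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  units <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9,
             pM = 1e-12, fM = 1e-15)
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec(
      "^([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)\\s*([a-zA-Zµ]+)?$", s
    ))[[1]]
    if (length(m) == 0) {
      stop(sprintf("cannot parse concentration '%s'", s), call. = FALSE)
    }
    val <- as.numeric(m[2])
    unit <- m[4]
    if (is.na(unit) || unit == "") return(val)
    if (!unit %in% names(units)) {
      stop(sprintf("unknown concentration unit '%s' in '%s'", unit, s),
           call. = FALSE)
    }
    val * units[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}
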