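# Synthetic diffusion-based smFRET yield measurement. Each diffusing motor
# contributes one burst whose apparent FRET efficiency is drawn from the
# population it belongs to: leg-placed (S_LP) or trapped (S_Trap). The two
# populations are modelled as truncated normals on [0,1]; photon-level
# effects (shot noise, gamma, background) are deliberately out of scope.

#' Two-population FRET model
#'
#' @param E_LP,E_Trap Mean FRET efficiencies of the leg-placed and trapped
#'   populations (defaults 0.2 and 0.8: the two states are clearly
#'   separated, with the leg-placed state on the low-FRET side; the
#'   assignment is a labelling convention and can be swapped).
#' @param sd_LP,sd_Trap Population widths (default 0.1).
#' @param f_LP True leg-placed fraction in `[0, 1]`.
#' @return An object of class `population_model`.
#' @export
population_model <- function(E_LP = 0.2, E_Trap = 0.8, sd_LP = 0.1,
                             sd_Trap = 0.1, f_LP = 0.5) {
  .check_num(E_LP, "E_LP", min = 0); .check_num(E_Trap, "E_Trap", min = 0)
  if (E_LP > 1 || E_Trap > 1) stop("FRET means must lie in [0, 1]", call. = FALSE)
  .check_num(sd_LP, "sd_LP", min = 0, strict = TRUE)
  .check_num(sd_Trap, "sd_Trap", min = 0, strict = TRUE)
  .check_num(f_LP, "f_LP", min = 0)
  if (f_LP > 1) stop("'f_LP' must lie in [0, 1]", call. = FALSE)
  structure(
    list(E_LP = E_LP, E_Trap = E_Trap, sd_LP = sd_LP, sd_Trap = sd_Trap,
         f_LP = f_LP),
    class = "population_model"
  )
}

# truncated-normal draws on [0,1] by inverse-CDF (deterministic given the
# uniform stream)
.rtnorm01 <- function(u, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  pmin(1, pmax(0, stats::qnorm(lo + u * (hi - lo), mean, sd)))
}

.dtnorm01 <- function(x, mean, sd) {
  z <- stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd)
  stats::dnorm(x, mean, sd) / z
}

#' Generate a synthetic burst set
#'
#' Mixture draw: each burst belongs to the leg-placed population with
#' probability `f_LP`, otherwise to the trapped population; its efficiency
#' is a truncated-normal variate on `[0, 1]`. Deterministic given the seed.
#'
#' @param model A [population_model()].
#' @param n_bursts Number of bursts (>= 1).
#' @param seed Integer RNG seed.
#' @param d_nm,F1_M Optional condition labels carried in the output.
#' @return An object of class `burst_set` with `efficiencies`, `condition`,
#'   `seed`.
#' @export
generate_bursts <- function(model, n_bursts, seed, d_nm = NA_real_,
                            F1_M = NA_real_) {
  stopifnot(inherits(model, "population_model"))
  .check_num(n_bursts, "n_bursts", min = 1)
  if (abs(model$E_LP - model$E_Trap) < 1e-12) {
    warning("E_LP equals E_Trap: downstream mixture fit is unidentifiable",
            call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- as.integer(n_bursts)
  is_lp <- stats::runif(n) < model$f_LP
  u <- stats::runif(n)
  e <- numeric(n)
  e[is_lp] <- .rtnorm01(u[is_lp], model$E_LP, model$sd_LP)
  e[!is_lp] <- .rtnorm01(u[!is_lp], model$E_Trap, model$sd_Trap)
  structure(
    list(efficiencies = e,
         condition = c(d_nm = d_nm, F1_M = F1_M),
         seed = as.integer(seed),
         n_lp_true = sum(is_lp)),
    class = "burst_set"
  )
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf(
    "<burst_set> %d bursts (d = %s nm, [F1] = %s M, seed %d)\n",
    length(x$efficiencies),
    format(x$condition[["d_nm"]]), format(x$condition[["F1_M"]]), x$seed
  ))
  invisible(x)
}

# EM for a two-component truncated-normal mixture on [0,1]. With
# fix_means = TRUE (the default: state means are pre-characterised from
# donor-only / fully-placed controls) only the mixing weight and the widths
# are free. Weighted-moment width updates are used; under truncation these
# are slightly biased low, which is immaterial for the well-separated
# populations this measurement relies on.
.em_mix <- function(x, m1, m2, s1, s2, w, fix_means, max_iter = 500,
                    tol = 1e-10) {
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w * .dtnorm01(x, m1, s1)
    d2 <- (1 - w) * .dtnorm01(x, m2, s2)
    tot <- pmax(d1 + d2, 1e-300)
    r <- d1 / tot
    ll <- sum(log(tot))
    w <- mean(r)
    w <- min(max(w, 1e-8), 1 - 1e-8)
    if (!fix_means) {
      m1 <- sum(r * x) / sum(r)
      m2 <- sum((1 - r) * x) / sum(1 - r)
    }
    s1 <- max(sqrt(sum(r * (x - m1)^2) / sum(r)), 5e-3)
    s2 <- max(sqrt(sum((1 - r) * (x - m2)^2) / sum(1 - r)), 5e-3)
    if (abs(ll - ll_prev) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(w = w, m1 = m1, m2 = m2, s1 = s1, s2 = s2,
       converged = converged, n_iter = it, loglik = ll)
}

#' Estimate the leg-placed fraction from a burst set
#'
#' Two-component truncated-normal mixture fit by expectation-maximisation.
#' The returned fraction is the mixing weight of the component whose mean is
#' nearer the initial leg-placed mean, so swapping the component order in
#' the initialiser does not change the answer. The 95% confidence interval
#' is a percentile bootstrap over bursts.
#'
#' @param bursts A [generate_bursts()] result (>= 50 bursts).
#' @param init A [population_model()] providing initial means/widths.
#' @param fix_means Keep the population means fixed at `init` (default).
#' @param n_boot Bootstrap resamples (default 200).
#' @param max_iter,tol EM controls.
#' @return An object of class `fret_fit`: `f_LP_hat`, `ci_low`, `ci_high`,
#'   `converged`, plus the fitted component parameters.
#' @export
estimate_fractions <- function(bursts, init, fix_means = TRUE, n_boot = 200,
                               max_iter = 500, tol = 1e-10) {
  stopifnot(inherits(bursts, "burst_set"), inherits(init, "population_model"))
  x <- bursts$efficiencies
  if (length(x) < 50) {
    stop("at least 50 bursts are required for a stable mixture fit",
         call. = FALSE)
  }
  if (abs(init$E_LP - init$E_Trap) < 1e-12) {
    stop("unidentifiable initialiser: E_LP equals E_Trap", call. = FALSE)
  }
  fit_one <- function(xx) {
    f <- .em_mix(xx, init$E_LP, init$E_Trap, init$sd_LP, init$sd_Trap,
                 w = 0.5, fix_means = fix_means, max_iter = max_iter,
                 tol = tol)
    # weight of the component nearer the leg-placed mean
    w_lp <- if (abs(f$m1 - init$E_LP) <= abs(f$m2 - init$E_LP)) f$w else 1 - f$w
    list(w_lp = w_lp, fit = f)
  }
  main <- fit_one(x)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(derive_seed(bursts$seed, "bootstrap_ci"))
    reps <- vapply(seq_len(n_boot), function(b) {
      fit_one(sample(x, replace = TRUE))$w_lp
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
    # percentile intervals can exclude the point estimate by a hair
    ci[1] <- min(ci[1], main$w_lp)
    ci[2] <- max(ci[2], main$w_lp)
  }
  structure(
    list(f_LP_hat = main$w_lp, ci_low = ci[1], ci_high = ci[2],
         converged = main$fit$converged, n_iter = main$fit$n_iter,
         components = main$fit[c("m1", "m2", "s1", "s2")],
         n_bursts = length(x)),
    class = "fret_fit"
  )
}

#' @export
print.fret_fit <- function(x, ...) {
  cat(sprintf(
    "<fret_fit> f_LP = %.4f [%.4f, %.4f], %s after %d EM iterations (n = %d)\n",
    x$f_LP_hat, x$ci_low, x$ci_high,
    if (x$converged) "converged" else "NOT converged", x$n_iter, x$n_bursts
  ))
  invisible(x)
}

#' Synthesize a full leg-placing yield experiment
#'
#' For every (step size, fuel concentration) condition the true leg-placed
#' fraction follows the kinetic competition given the true stepping rates,
#' and one burst set is generated at that fraction. The noiseless true yield
#' table is returned alongside.
#'
#' @param true_ks Named numeric vector of stepping rates (s^-1); names are
#'   step sizes in nm. A two-column `data.frame` (`d_nm`, `k_s`) is also
#'   accepted.
#' @param k_FB Fuel-binding rate constant (M^-1 s^-1).
#' @param F1_list Fuel concentrations (M).
#' @param model A [population_model()] (its `f_LP` is overridden per
#'   condition).
#' @param n_bursts Bursts per condition.
#' @param seed Integer master seed; per-condition seeds are derived.
#' @return List with `bursts` (list of `burst_set`) and `truth`
#'   (yield-curve `data.frame`, `source = "model"`).
#' @export
synthesize_experiment <- function(true_ks, k_FB, F1_list, model, n_bursts,
                                  seed) {
  if (is.data.frame(true_ks)) {
    ks <- stats::setNames(true_ks$k_s, true_ks$d_nm)
  } else {
    ks <- true_ks
  }
  stopifnot(!is.null(names(ks)), inherits(model, "population_model"))
  d_vals <- as.numeric(names(ks))
  .check_num(d_vals, "step sizes")
  .check_num(F1_list, "F1_list", min = 0)
  conds <- expand.grid(d = d_vals, F1 = F1_list, KEEP.OUT.ATTRS = FALSE)
  bursts <- vector("list", nrow(conds))
  truth <- data.frame(
    step_size_nm = conds$d, fuel_conc_M = conds$F1,
    yield = NA_real_, yield_se = NA_real_, source = "model",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(conds))) {
    k_s_i <- ks[[as.character(conds$d[i])]]
    f <- yield_from_rates(k_s_i, k_FB, conds$F1[i])
    truth$yield[i] <- f
    m <- model
    m$f_LP <- f
    bursts[[i]] <- generate_bursts(
      m, n_bursts,
      seed = derive_seed(seed, sprintf("cond_%g_%g", conds$d[i], conds$F1[i])),
      d_nm = conds$d[i], F1_M = conds$F1[i]
    )
  }
  list(bursts = bursts, truth = truth)
}

#' Write / read burst sets as long-format CSV
#'
#' Columns: `efficiency`, `condition_d_nm`, `condition_F1_M`, `seed`.
#'
#' @param bursts A `burst_set` or list of them.
#' @param path Output file.
#' @return Invisibly, the path (writer) or a list of `burst_set` (reader).
#' @export
write_bursts <- function(bursts, path) {
  if (inherits(bursts, "burst_set")) bursts <- list(bursts)
  df <- do.call(rbind, lapply(bursts, function(b) {
    data.frame(
      efficiency = b$efficiencies,
      condition_d_nm = b$condition[["d_nm"]],
      condition_F1_M = b$condition[["F1_M"]],
      seed = b$seed,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @export
read_bursts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("efficiency", "condition_d_nm", "condition_F1_M", "seed")
  if (!all(need %in% names(df))) {
    stop(sprintf("burst CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  key <- interaction(df$condition_d_nm, df$condition_F1_M, drop = TRUE)
  lapply(split(df, key), function(g) {
    structure(
      list(efficiencies = g$efficiency,
           condition = c(d_nm = g$condition_d_nm[1],
                         F1_M = g$condition_F1_M[1]),
           seed = g$seed[1]),
      class = "burst_set"
    )
  })
}
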