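# Orchestration: a structured YAML config drives the five analysis stages
# (simulate-fret -> fit-yields -> extract-rates, predict-mechanics,
# compare), each writing CSV/JSON into a stage-named subdirectory of the
# configured output directory. All randomness flows from the single config
# seed through derived sub-streams, so two runs from the same config are
# byte-identical.

.known_keys <- list(
  top = c("output_dir", "walker", "track", "kinetics", "fret", "sampling"),
  walker = c("capture_radius_nm", "kuhn_length_nm", "ss_nm_per_nt",
             "ds_nm_per_bp", "arm_bound", "arm_fuel"),
  segment = c("kind", "n_units", "label"),
  track = c("kind", "radius_nm", "walker_side"),
  kinetics = c("k_FB", "F1", "d_ref_nm", "k_s_ref", "true_k_s"),
  fret = c("E_LP", "E_Trap", "sd_LP", "sd_Trap", "n_bursts", "n_boot_ci"),
  # "n" would be a YAML boolean literal, hence the longer key name
  sampling = c("n_conformations", "seed", "d_grid_nm", "bandwidth_nm",
               "voxel_nm", "n_boot")
)

.check_keys <- function(block, section, path) {
  known <- .known_keys[[section]]
  for (k in names(block)) {
    if (!k %in% known) {
      sugg <- known[which.min(utils::adist(k, known))]
      stop(sprintf(
        "unknown config key '%s%s'; did you mean '%s'?",
        if (path == "") "" else paste0(path, "."), k, sugg
      ), call. = FALSE)
    }
  }
}

.as_num <- function(x, key) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    stop(sprintf("config key '%s' must be numeric (got '%s')", key,
                 paste(x, collapse = ", ")), call. = FALSE)
  }
  v
}

#' Default run configuration
#'
#' The shipped defaults describe the study conditions: the default walker
#' geometry, a flat track, fuel concentrations spanning 1 nM to 10 uM, the
#' experimentally determined fuel-binding rate constant, a 12 nm reference
#' step calibrated at 3 s^-1, and true stepping rates for the synthetic
#' experiment that follow the measured pattern (a few per second at short
#' steps, collapsing by orders of magnitude past 30 nm).
#'
#' @return A raw config list (pass to [validate_config()] or write with
#'   [write_config()]).
#' @export
default_config <- function() {
  list(
    output_dir = "walker_out",
    walker = list(
      capture_radius_nm = 1.0,
      kuhn_length_nm = 1.5,
      ss_nm_per_nt = 0.63,
      ds_nm_per_bp = 0.34,
      arm_bound = list(
        list(kind = "duplex", n_units = 6L, label = "T2_stem"),
        list(kind = "duplex", n_units = 34L, label = "T2.F2.L2_stack"),
        list(kind = "single_stranded", n_units = 3L, label = "hinge"),
        list(kind = "single_stranded", n_units = 15L, label = "L1_free")
      ),
      arm_fuel = list(
        list(kind = "duplex", n_units = 24L, label = "T1.F1_stack"),
        list(kind = "single_stranded", n_units = 9L, label = "F1_overhang")
      )
    ),
    track = list(kind = "flat", radius_nm = 60 / (2 * pi),
                 walker_side = "convex"),
    kinetics = list(
      k_FB = 2.3e5,
      F1 = c("1 nM", "10 nM", "100 nM", "1 uM", "10 uM"),
      d_ref_nm = 12,
      k_s_ref = 3.0,
      true_k_s = list(`5` = 2, `10` = 4, `15` = 3, `20` = 2, `25` = 1,
                      `30` = 0.02, `35` = 3.5e-5, `40` = 1e-7, `45` = 0)
    ),
    fret = list(E_LP = 0.2, E_Trap = 0.8, sd_LP = 0.1, sd_Trap = 0.1,
                n_bursts = 3000L, n_boot_ci = 100L),
    sampling = list(n_conformations = 100000L, seed = 20211L,
                    d_grid_nm = c(5, 10, 15, 20, 25, 30, 35, 40, 45),
                    bandwidth_nm = 1.0, voxel_nm = 1.0, n_boot = 30L)
  )
}

#' Validate a raw config list
#'
#' Strict schema validation: unknown keys are rejected with a
#' did-you-mean suggestion naming the full key path, units are normalised
#' (concentration strings become molar), and the walker block is compiled
#' into a [walker_design()].
#'
#' @param raw A named list as produced by [default_config()] or
#'   [yaml::read_yaml()].
#' @return An object of class `run_config`.
#' @export
validate_config <- function(raw) {
  stopifnot(is.list(raw))
  .check_keys(raw, "top", "")
  need <- c("walker", "track", "kinetics", "fret", "sampling")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(sprintf("missing config block(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  w <- raw$walker
  .check_keys(w, "walker", "walker")
  for (armname in c("arm_bound", "arm_fuel")) {
    if (is.null(w[[armname]]) || length(w[[armname]]) == 0) {
      stop(sprintf("config key 'walker.%s' must list segments", armname),
           call. = FALSE)
    }
    for (s in w[[armname]]) .check_keys(s, "segment", paste0("walker.", armname))
  }
  mk_arm <- function(segs) {
    lapply(segs, function(s) {
      kind <- match.arg(s$kind, c("duplex", "single_stranded", "ds", "ss"))
      segment_spec(
        kind, .as_num(s$n_units, "n_units"),
        contour_per_unit = if (kind %in% c("duplex", "ds")) {
          .as_num(w$ds_nm_per_bp %||% 0.34, "walker.ds_nm_per_bp")
        } else {
          .as_num(w$ss_nm_per_nt %||% 0.63, "walker.ss_nm_per_nt")
        },
        kuhn_length = .as_num(w$kuhn_length_nm %||% 1.5,
                              "walker.kuhn_length_nm"),
        label = s$label
      )
    })
  }
  design <- walker_design(
    mk_arm(w$arm_bound), mk_arm(w$arm_fuel),
    capture_radius = .as_num(w$capture_radius_nm %||% 1, "walker.capture_radius_nm")
  )
  tr <- raw$track
  .check_keys(tr, "track", "track")
  kind <- match.arg(tr$kind, c("flat", "cylinder"))
  track <- if (kind == "flat") {
    track_flat()
  } else {
    track_cylinder(radius = .as_num(tr$radius_nm %||% (60 / (2 * pi)),
                                    "track.radius_nm"),
                   walker_side = tr$walker_side %||% "convex")
  }
  kin <- raw$kinetics
  .check_keys(kin, "kinetics", "kinetics")
  F1 <- parse_concentration(unlist(kin$F1))
  true_ks <- NULL
  if (!is.null(kin$true_k_s)) {
    true_ks <- stats::setNames(
      .as_num(unlist(kin$true_k_s), "kinetics.true_k_s"),
      names(kin$true_k_s)
    )
  }
  fr <- raw$fret
  .check_keys(fr, "fret", "fret")
  popmodel <- population_model(
    E_LP = .as_num(fr$E_LP %||% 0.2, "fret.E_LP"),
    E_Trap = .as_num(fr$E_Trap %||% 0.8, "fret.E_Trap"),
    sd_LP = .as_num(fr$sd_LP %||% 0.1, "fret.sd_LP"),
    sd_Trap = .as_num(fr$sd_Trap %||% 0.1, "fret.sd_Trap")
  )
  sm <- raw$sampling
  .check_keys(sm, "sampling", "sampling")
  if (is.null(sm$seed)) stop("config key 'sampling.seed' must be explicit",
                             call. = FALSE)
  structure(
    list(
      raw = raw,
      output_dir = raw$output_dir %||% "walker_out",
      design = design,
      track = track,
      k_FB = .as_num(kin$k_FB %||% 2.3e5, "kinetics.k_FB"),
      F1_list = F1,
      calibration = list(
        d_ref = .as_num(kin$d_ref_nm %||% 12, "kinetics.d_ref_nm"),
        k_s_ref = .as_num(kin$k_s_ref %||% 3, "kinetics.k_s_ref"),
        k_FB = .as_num(kin$k_FB %||% 2.3e5, "kinetics.k_FB")
      ),
      true_ks = true_ks,
      popmodel = popmodel,
      n_bursts = as.integer(.as_num(fr$n_bursts %||% 3000, "fret.n_bursts")),
      n_boot_ci = as.integer(.as_num(fr$n_boot_ci %||% 100, "fret.n_boot_ci")),
      n = as.integer(.as_num(sm$n_conformations %||% 1e5,
                             "sampling.n_conformations")),
      seed = as.integer(.as_num(sm$seed, "sampling.seed")),
      d_grid = .as_num(unlist(sm$d_grid_nm), "sampling.d_grid_nm"),
      bandwidth = .as_num(sm$bandwidth_nm %||% 1, "sampling.bandwidth_nm"),
      voxel = .as_num(sm$voxel_nm %||% 1, "sampling.voxel_nm"),
      n_boot = as.integer(.as_num(sm$n_boot %||% 30, "sampling.n_boot"))
    ),
    class = "run_config"
  )
}

#' Load / write a run configuration
#'
#' @param path YAML file path.
#' @return `load_config()` returns a validated `run_config`;
#'   `write_config()` invisibly returns the path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param cfg A raw config list or `run_config`.
#' @export
write_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

config_hash <- function(cfg) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(raw, tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

.stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$output_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.write_manifest <- function(cfg, dir, stage, extra = list()) {
  manifest <- c(list(
    stage = stage,
    config_md5 = config_hash(cfg),
    seed = cfg$seed,
    package = "dnawalker",
    version = as.character(utils::packageVersion("dnawalker"))
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read/write yield-curve CSV tables
#'
#' Schema: `step_size_nm` (float), `fuel_conc_M` (float, molar), `yield`
#' (float 0-1), `yield_se` (float, may be empty), `source`
#' (`"synthetic" | "model" | "manual"`). Header row mandatory, UTF-8,
#' `.` decimal separator.
#'
#' @param df Yield-curve data.frame.
#' @param path CSV file path.
#' @export
write_yield_curve <- function(df, path) {
  need <- c("step_size_nm", "fuel_conc_M", "yield", "yield_se", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("yield curve is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(df[, need], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_yield_curve
#' @export
read_yield_curve <- function(path) {
  if (!file.exists(path)) stop(sprintf("yield table not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("step_size_nm", "fuel_conc_M", "yield", "yield_se", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("yield CSV %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- !df$source %in% c("synthetic", "model", "manual")
  if (any(bad)) {
    stop("yield CSV 'source' must be one of synthetic|model|manual",
         call. = FALSE)
  }
  df
}

#' Pipeline stage: simulate the smFRET experiment
#'
#' Generates per-condition burst sets from the configured true stepping
#' rates and writes `bursts.csv`, `truth.csv` and a manifest under
#' `<output_dir>/simulate_fret/`.
#'
#' @param cfg A `run_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the [synthesize_experiment()] result.
#' @export
run_simulate_fret <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$true_ks)) {
    stop("config error: kinetics.true_k_s is required to simulate bursts",
         call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  dir <- .stage_dir(cfg, "simulate_fret")
  sim <- synthesize_experiment(cfg$true_ks, cfg$k_FB, cfg$F1_list,
                               cfg$popmodel, cfg$n_bursts,
                               seed = derive_seed(cfg$seed, "fret"))
  write_bursts(sim$bursts, file.path(dir, "bursts.csv"))
  write_yield_curve(sim$truth, file.path(dir, "truth.csv"))
  .write_manifest(cfg, dir, "simulate_fret",
                  list(n_conditions = length(sim$bursts),
                       n_bursts = cfg$n_bursts))
  if (!quiet) {
    message(sprintf("[simulate-fret] %d conditions x %d bursts (seed %d, %.1f s)",
                    length(sim$bursts), cfg$n_bursts, cfg$seed,
                    proc.time()[["elapsed"]] - t0))
  }
  invisible(sim)
}

#' Pipeline stage: fit yields from bursts
#'
#' Runs the mixture estimator on every burst set and writes the fitted
#' yield table (`source = "synthetic"`) under `<output_dir>/fit_yields/`.
#'
#' @param cfg A `run_config`.
#' @param bursts Optional list of `burst_set`; defaults to the
#'   simulate-fret stage output on disk.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the fitted yield-curve data.frame.
#' @export
run_fit_yields <- function(cfg, bursts = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(bursts)) {
    path <- file.path(cfg$output_dir, "simulate_fret", "bursts.csv")
    bursts <- read_bursts(path)
  }
  dir <- .stage_dir(cfg, "fit_yields")
  rows <- lapply(bursts, function(b) {
    fit <- estimate_fractions(b, cfg$popmodel, fix_means = TRUE,
                              n_boot = cfg$n_boot_ci)
    data.frame(
      step_size_nm = b$condition[["d_nm"]],
      fuel_conc_M = b$condition[["F1_M"]],
      yield = fit$f_LP_hat,
      yield_se = (fit$ci_high - fit$ci_low) / (2 * stats::qnorm(0.975)),
      source = "synthetic",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$step_size_nm, out$fuel_conc_M), ]
  rownames(out) <- NULL
  write_yield_curve(out, file.path(dir, "yields.csv"))
  .write_manifest(cfg, dir, "fit_yields", list(n_conditions = nrow(out)))
  if (!quiet) {
    message(sprintf("[fit-yields] %d conditions fitted (%.1f s)", nrow(out),
                    proc.time()[["elapsed"]] - t0))
  }
  invisible(out)
}

#' Pipeline stage: extract stepping rates from yields
#'
#' Inverts the kinetic competition per condition. Conditions whose yield
#' falls outside (0.01, 0.99) are flagged unreliable and not inverted (the
#' race is too one-sided there for the yield to constrain the rate).
#'
#' @param cfg A `run_config`.
#' @param yields Optional yield-curve data.frame or CSV path; defaults to
#'   the fit-yields stage output.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a data.frame with `step_size_nm`, `fuel_conc_M`,
#'   `k_s_hat`, `ci_low`, `ci_high`, `reliable`.
#' @export
run_extract_rates <- function(cfg, yields = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$k_FB) || !is.finite(cfg$k_FB)) {
    stop("config error: kinetics.k_FB is required to extract rates",
         call. = FALSE)
  }
  if (is.null(yields)) {
    yields <- file.path(cfg$output_dir, "fit_yields", "yields.csv")
  }
  if (is.character(yields)) yields <- read_yield_curve(yields)
  if (nrow(yields) == 0) {
    stop("empty yield table: nothing to extract rates from", call. = FALSE)
  }
  dir <- .stage_dir(cfg, "extract_rates")
  inv <- function(Y, F1) {
    if (is.na(Y) || Y <= 0.01 || Y >= 0.99) return(NA_real_)
    stepping_rate_from_yield(Y, cfg$k_FB, F1)
  }
  out <- data.frame(
    step_size_nm = yields$step_size_nm,
    fuel_conc_M = yields$fuel_conc_M,
    k_s_hat = mapply(inv, yields$yield, yields$fuel_conc_M),
    ci_low = mapply(inv, pmax(yields$yield - stats::qnorm(0.975) * yields$yield_se, 0.0101),
                    yields$fuel_conc_M),
    ci_high = mapply(inv, pmin(yields$yield + stats::qnorm(0.975) * yields$yield_se, 0.9899),
                     yields$fuel_conc_M),
    stringsAsFactors = FALSE
  )
  out$reliable <- !is.na(out$k_s_hat)
  out$ci_low[!out$reliable] <- NA_real_
  out$ci_high[!out$reliable] <- NA_real_
  utils::write.csv(out, file.path(dir, "rates.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  .write_manifest(cfg, dir, "extract_rates",
                  list(n_reliable = sum(out$reliable)))
  if (!quiet) {
    message(sprintf("[extract-rates] %d/%d conditions reliable",
                    sum(out$reliable), nrow(out)))
  }
  invisible(out)
}

#' Pipeline stage: mechanics prediction of the yield curve
#'
#' Runs the coarse mechanical model over the configured step grid and fuel
#' concentrations and writes `model_yields.csv` plus the per-step contact
#' table `contacts.csv` under `<output_dir>/predict_mechanics/`.
#'
#' @param cfg A `run_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the [predict_yield_curve()] result.
#' @export
run_predict_mechanics <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir <- .stage_dir(cfg, "predict_mechanics")
  yc <- predict_yield_curve(
    cfg$design, cfg$track, cfg$d_grid, cfg$F1_list,
    calibration = cfg$calibration, n = cfg$n,
    seed = derive_seed(cfg$seed, "mechanics"),
    bandwidth = cfg$bandwidth, voxel = cfg$voxel, n_boot = cfg$n_boot
  )
  write_yield_curve(yc, file.path(dir, "model_yields.csv"))
  utils::write.csv(attr(yc, "contacts"), file.path(dir, "contacts.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  .write_manifest(cfg, dir, "predict_mechanics",
                  list(n_conformations = cfg$n, track = cfg$track$kind))
  if (!quiet) {
    message(sprintf("[predict-mechanics] %d step sizes on %s track (%.1f s)",
                    length(cfg$d_grid), cfg$track$kind,
                    proc.time()[["elapsed"]] - t0))
  }
  invisible(yc)
}

# first Y = 0.5 crossing by linear interpolation; NA when the curve does
# not bracket 0.5
.crossover <- function(d, Y) {
  o <- order(d)
  d <- d[o]; Y <- Y[o]
  s <- Y - 0.5
  for (i in seq_len(length(d) - 1)) {
    if (s[i] == 0) return(d[i])
    if (s[i] * s[i + 1] < 0) {
      return(d[i] + (d[i + 1] - d[i]) * s[i] / (s[i] - s[i + 1]))
    }
  }
  if (s[length(d)] == 0) return(d[length(d)])
  NA_real_
}

#' Pipeline stage: compare fitted and model yield curves
#'
#' Joins the two curves on the exact (step size, fuel concentration) grid
#' (no silent reindexing: missing pairs are an error), computes residuals,
#' the summary RMS residual, and the per-concentration crossover step size
#' (linear-interpolated Y = 0.5 point of the model curve, the natural
#' midpoint of the kinetic competition).
#'
#' @param cfg A `run_config`.
#' @param fitted,model Optional yield-curve data.frames or CSV paths;
#'   default to the fit-yields and predict-mechanics stage outputs.
#' @param quiet Suppress progress messages.
#' @return Invisibly, an object of class `comparison_report`: `table`
#'   (per-pair rows with residuals), `rms_residual`, `crossover_nm` (named
#'   by fuel concentration), `max_reach_nm`.
#' @export
run_compare <- function(cfg, fitted = NULL, model = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(fitted)) {
    fitted <- file.path(cfg$output_dir, "fit_yields", "yields.csv")
  }
  if (is.null(model)) {
    model <- file.path(cfg$output_dir, "predict_mechanics", "model_yields.csv")
  }
  if (is.character(fitted)) fitted <- read_yield_curve(fitted)
  if (is.character(model)) model <- read_yield_curve(model)
  key <- function(df) paste(df$step_size_nm, df$fuel_conc_M, sep = "@")
  kf <- key(fitted); km <- key(model)
  shared <- intersect(kf, km)
  miss_in_model <- setdiff(kf, km)
  miss_in_fit <- setdiff(km, kf)
  if (length(miss_in_model) || length(miss_in_fit)) {
    msg <- c(
      if (length(miss_in_model)) {
        sprintf("missing from model: %s", paste(sort(miss_in_model), collapse = "; "))
      },
      if (length(miss_in_fit)) {
        sprintf("missing from fitted: %s", paste(sort(miss_in_fit), collapse = "; "))
      }
    )
    stop(paste0("grid mismatch between fitted and model yield curves; ",
                paste(msg, collapse = " / ")), call. = FALSE)
  }
  if (length(shared) == 0) {
    stop("comparison grids share no (step size, fuel concentration) pairs",
         call. = FALSE)
  }
  fi <- fitted[match(shared, kf), ]
  mo <- model[match(shared, km), ]
  tab <- data.frame(
    step_size_nm = fi$step_size_nm,
    fuel_conc_M = fi$fuel_conc_M,
    yield_fit = fi$yield,
    yield_model = mo$yield,
    residual = fi$yield - mo$yield,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$fuel_conc_M, tab$step_size_nm), ]
  rownames(tab) <- NULL
  rms <- sqrt(mean(tab$residual^2))
  cross <- vapply(split(model, model$fuel_conc_M), function(g) {
    .crossover(g$step_size_nm, g$yield)
  }, numeric(1))
  report <- structure(
    list(table = tab, rms_residual = rms, crossover_nm = cross,
         max_reach_nm = max_reach(cfg$design, cfg$track)),
    class = "comparison_report"
  )
  dir <- .stage_dir(cfg, "compare")
  utils::write.csv(tab, file.path(dir, "compare.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  jsonlite::write_json(
    list(rms_residual = rms,
         crossover_nm = as.list(cross),
         max_reach_nm = report$max_reach_nm),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null"
  )
  .write_manifest(cfg, dir, "compare", list(n_pairs = nrow(tab)))
  if (!quiet) {
    message(sprintf("[compare] %d pairs, RMS residual %.4f", nrow(tab), rms))
  }
  invisible(report)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  pairs compared: %d\n", nrow(x$table)))
  cat(sprintf("  RMS residual:   %.4f\n", x$rms_residual))
  cat(sprintf("  max reach:      %.2f nm\n", x$max_reach_nm))
  cat("  crossover (nm) by [F1]:\n")
  for (nm in names(x$crossover_nm)) {
    cat(sprintf("    %s M: %s\n", nm,
                if (is.na(x$crossover_nm[[nm]])) "not bracketed"
                else sprintf("%.1f", x$crossover_nm[[nm]])))
  }
  invisible(x)
}

#' Run the full analysis chain
#'
#' simulate-fret -> fit-yields -> extract-rates, then predict-mechanics and
#' compare, all under the configured output directory.
#'
#' @param cfg A `run_config` (or path to a YAML config).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the [run_compare()] report.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  sim <- run_simulate_fret(cfg, quiet = quiet)
  fit <- run_fit_yields(cfg, bursts = sim$bursts, quiet = quiet)
  run_extract_rates(cfg, yields = fit, quiet = quiet)
  run_predict_mechanics(cfg, quiet = quiet)
  invisible(run_compare(cfg, quiet = quiet))
}
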