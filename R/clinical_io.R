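# Synthetic EVLP monitor records and their CSV round trip.
#
# The monitor samples every channel on a 3-s grid.  Since the clinical
# registry behind the model is not public, the package generates synthetic
# stand-in records: a simulated oxygenation challenge with independent
# Gaussian sensor noise per channel and sample.

.record_cols <- c("time_s", "vt_l", "t_insp_s", "t_exp_s", "peep_cmh2o",
                  "fio2", "cstat_ml_per_cmh2o", "q_l_per_min", "ph",
                  "ppa_o2_mmhg", "ppa_co2_mmhg", "pla_o2_mmhg")

#' Describe an oxygenation-challenge scenario
#'
#' The default scenario mirrors a routine donor-lung assessment: a 15-min
#' epoch sampled every 3 s, with the inspired oxygen fraction stepped to
#' 100 % from minute 3 onward.
#'
#' @param duration Epoch length \[s\].
#' @param step_time FiO2 step time \[s\], strictly inside the epoch.
#' @param pre_fio2,post_fio2 FiO2 before/after the step.
#' @param intrinsic Named list overriding intrinsic parameters used as the
#'   generating truth (table units), e.g.
#'   `list(R_aw = 20, V_D = 0.29, F_ds = 0.30, F_sh = 0.35)`.
#' @param noise Add per-sample Gaussian sensor noise?
#' @param seed Optional integer seed for the noise.
#' @return A list of class `evlp_scenario`.
#' @export
challenge_scenario <- function(duration = 900, step_time = 180,
                               pre_fio2 = 0.21, post_fio2 = 1.0,
                               intrinsic = list(), noise = TRUE,
                               seed = NULL) {
  if (step_time >= duration) stop("step time must precede epoch end")
  out <- list(duration = duration, step_time = step_time,
              pre_fio2 = pre_fio2, post_fio2 = post_fio2,
              intrinsic = intrinsic, noise = noise, seed = seed)
  class(out) <- "evlp_scenario"
  out
}

#' Generate a synthetic monitor record
#'
#' Simulates the model at the scenario's true parameters (steady state at
#' the pre-step FiO2, then the challenge), samples every channel on the
#' 3-s monitor grid and adds independent Gaussian sensor noise per channel
#' and sample ([sensor_sds()]; the left-atrial PO2 sensor reuses the
#' pulmonary-artery accuracy of 5.1 mmHg). The noiseless left-atrial PO2
#' and the generating parameters are retained in the `"truth"` attribute.
#'
#' @param scenario An `evlp_scenario`.
#' @param config Base configuration; scenario intrinsic overrides apply on
#'   top.
#' @param ... Passed to the simulation drivers.
#' @return A data.frame of class `evlp_record` with the canonical columns
#'   (see [read_record()]).
#' @export
generate_record <- function(scenario = challenge_scenario(),
                            config = default_config(), ...) {
  stopifnot(inherits(scenario, "evlp_scenario"))
  cfg <- if (length(scenario$intrinsic))
    do.call(update_config, c(list(config), scenario$intrinsic))
  else config
  sim <- run_challenge(cfg, pre_fio2 = scenario$pre_fio2,
                       post_fio2 = scenario$post_fio2,
                       step_time = scenario$step_time,
                       duration = scenario$duration, dt_out = 3, ...)
  grid <- seq(0, scenario$duration, by = 3)
  res <- resample_nearest(sim, grid)
  tv <- as_table_units(cfg)
  nrow <- length(grid)
  fio2 <- ifelse(grid >= scenario$step_time, scenario$post_fio2,
                 scenario$pre_fio2)
  rec <- data.frame(
    time_s = grid,
    vt_l = rep(tv[["Vt"]], nrow),
    t_insp_s = rep(tv[["T_insp"]], nrow),
    t_exp_s = rep(tv[["T_exp"]], nrow),
    peep_cmh2o = rep(tv[["PEEP"]], nrow),
    fio2 = fio2,
    cstat_ml_per_cmh2o = rep(tv[["C_stat"]], nrow),
    q_l_per_min = rep(tv[["Q"]], nrow),
    ph = rep(tv[["pH"]], nrow),
    ppa_o2_mmhg = rep(tv[["P_PA_O2"]], nrow),
    ppa_co2_mmhg = rep(tv[["P_PA_CO2"]], nrow),
    pla_o2_mmhg = res$P_LA_O2,
    pla_co2_mmhg = res$P_LA_CO2)
  if (scenario$noise) {
    if (!is.null(scenario$seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(scenario$seed)
    }
    sds <- sensor_sds()
    add <- function(x, sd) x + stats::rnorm(nrow, 0, sd)
    rec$vt_l <- add(rec$vt_l, sds[["Vt"]])
    rec$t_insp_s <- add(rec$t_insp_s, sds[["T_insp"]])
    rec$t_exp_s <- add(rec$t_exp_s, sds[["T_exp"]])
    rec$peep_cmh2o <- add(rec$peep_cmh2o, sds[["PEEP"]])
    rec$fio2 <- pmin(add(rec$fio2, sds[["FiO2"]]), 1 + 3 * sds[["FiO2"]])
    rec$q_l_per_min <- add(rec$q_l_per_min, sds[["Q"]] * 60)
    rec$ph <- add(rec$ph, sds[["pH"]])
    rec$ppa_o2_mmhg <- add(rec$ppa_o2_mmhg, sds[["P_PA_O2"]])
    rec$ppa_co2_mmhg <- add(rec$ppa_co2_mmhg, sds[["P_PA_CO2"]])
    rec$pla_o2_mmhg <- add(rec$pla_o2_mmhg, sds[["P_PA_O2"]])
  }
  attr(rec, "truth") <- list(
    intrinsic = cfg$intrinsic,
    pla_o2_true = res$P_LA_O2,
    baseline = attr(sim, "baseline"),
    scenario = scenario)
  class(rec) <- c("evlp_record", "data.frame")
  rec
}

validate_record <- function(record) {
  if (!is.data.frame(record) || nrow(record) == 0)
    stop("record must be a non-empty data.frame")
  miss <- setdiff(.record_cols, names(record))
  if (length(miss))
    stop("record is missing column(s): ", paste(miss, collapse = ", "))
  dt <- diff(record$time_s)
  if (length(dt) && any(abs(dt - 3) > 1e-6))
    stop("record grid is not uniform at 3 s (gaps of ",
         paste(unique(round(dt[abs(dt - 3) > 1e-6], 3)), collapse = ", "),
         " s found)")
  # plausibility bounds: normal ranges widened by 6 sensor SDs
  sds <- sensor_sds()
  checks <- list(
    vt_l = c(0.2, 0.8, 6 * sds[["Vt"]]),
    t_insp_s = c(1, 5, 6 * sds[["T_insp"]]),
    t_exp_s = c(2, 10, 6 * sds[["T_exp"]]),
    peep_cmh2o = c(5, 12, 6 * sds[["PEEP"]]),
    fio2 = c(0.21, 1, 6 * sds[["FiO2"]]),
    q_l_per_min = c(0.5, 3, 6 * sds[["Q"]] * 60),
    ph = c(7, 7.5, 6 * sds[["pH"]]),
    ppa_o2_mmhg = c(40, 100, 6 * sds[["P_PA_O2"]]),
    ppa_co2_mmhg = c(20, 45, 6 * sds[["P_PA_CO2"]]))
  for (nm in names(checks)) {
    b <- checks[[nm]]
    v <- record[[nm]]
    if (any(v < b[1] - b[3]) || any(v > b[2] + b[3]))
      stop(sprintf(
        "column %s outside plausible range [%g, %g] (value %g)", nm,
        b[1] - b[3], b[2] + b[3],
        v[which(v < b[1] - b[3] | v > b[2] + b[3])[1]]))
  }
  invisible(TRUE)
}

#' Read / write a monitor record as CSV
#'
#' Comma-separated with a header of canonical column names: `time_s`,
#' `vt_l`, `t_insp_s`, `t_exp_s`, `peep_cmh2o`, `fio2`,
#' `cstat_ml_per_cmh2o`, `q_l_per_min`, `ph`, `ppa_o2_mmhg`,
#' `ppa_co2_mmhg`, `pla_o2_mmhg` and optionally `pla_co2_mmhg`; units as
#' the names indicate. Reading validates the schema: required columns, a
#' uniform 3-s grid, and per-channel plausibility bounds.
#'
#' @param path File path.
#' @param record An `evlp_record` (for writing).
#' @return `read_record` returns an `evlp_record`; `write_record` returns
#'   `path` invisibly.
#' @export
read_record <- function(path) {
  rec <- utils::read.csv(path)
  validate_record(rec)
  class(rec) <- c("evlp_record", "data.frame")
  rec
}

#' @rdname read_record
#' @export
write_record <- function(record, path) {
  validate_record(record)
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}
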