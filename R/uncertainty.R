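# Monte-Carlo uncertainty quantification: propagate sensor-accuracy input
# distributions through the model.

#' Draw clinical-input vectors from the sensor-noise distributions
#'
#' Each monitored input is drawn independently from a normal distribution
#' centred on its configuration value with the sensor-accuracy standard
#' deviation; pH noise is applied on the pH scale. Draws are truncated
#' only at physical-validity bounds (positive volumes, times and flows,
#' FiO2 at most 1), which at the given standard deviations leaves the
#' means essentially unchanged. Static compliance has no reported sensor
#' accuracy and is not perturbed.
#'
#' @param n Number of draws.
#' @param config Configuration providing the means.
#' @param sds Named standard deviations (see [sensor_sds()]; `Q` in L/s,
#'   `pH` in pH units, others in canonical units).
#' @param seed Optional integer seed.
#' @return A matrix with `n` rows and one column per perturbed input
#'   (canonical units; column `pH` on the pH scale).
#' @export
sample_inputs <- function(n, config = default_config(),
                          sds = sensor_sds(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  means <- c(Vt = config$clinical$Vt, T_insp = config$clinical$T_insp,
             T_exp = config$clinical$T_exp, PEEP = config$clinical$PEEP,
             FiO2 = config$clinical$FiO2, Q = config$clinical$Q,
             pH = config$clinical$pH,
             P_PA_O2 = config$clinical$P_PA_O2,
             P_PA_CO2 = config$clinical$P_PA_CO2)
  lower <- c(Vt = 1e-3, T_insp = 0.05, T_exp = 0.05, PEEP = 0,
             FiO2 = 1e-3, Q = 1e-5, pH = 6, P_PA_O2 = 0, P_PA_CO2 = 0)
  upper <- c(Vt = Inf, T_insp = Inf, T_exp = Inf, PEEP = Inf, FiO2 = 1,
             Q = Inf, pH = 9, P_PA_O2 = Inf, P_PA_CO2 = Inf)
  X <- matrix(NA_real_, n, length(means),
              dimnames = list(NULL, names(means)))
  for (nm in names(means)) {
    x <- stats::rnorm(n, means[[nm]], sds[[nm]])
    bad <- x < lower[[nm]] | x > upper[[nm]]
    guard <- 0
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), means[[nm]], sds[[nm]])
      bad <- x < lower[[nm]] | x > upper[[nm]]
      if ((guard <- guard + 1) > 1000) {
        x[bad] <- pmin(pmax(x[bad], lower[[nm]]), upper[[nm]])
        break
      }
    }
    X[, nm] <- x
  }
  X
}

# Apply one row of sample_inputs() to a canonical parameter vector.
apply_draw <- function(pv, draw) {
  pv[1] <- draw[["Vt"]]; pv[2] <- draw[["T_insp"]]
  pv[3] <- draw[["T_exp"]]; pv[4] <- draw[["PEEP"]]
  pv[5] <- draw[["FiO2"]]; pv[7] <- draw[["Q"]]
  pv[8] <- 10^(-draw[["pH"]])
  pv[9] <- draw[["P_PA_O2"]]; pv[10] <- draw[["P_PA_CO2"]]
  pv
}

#' Static steady-state Monte-Carlo uncertainty
#'
#' Propagates the sensor-noise input distributions through the model: for
#' each draw the system is run to cyclic steady state and the cycle-mean
#' left-atrial tensions are recorded. Draws that fail to converge are
#' excluded and counted.
#'
#' @param config Base configuration.
#' @param n Number of Monte-Carlo draws (10,000 reproduces the full
#'   study; about 1,000 suffices at desk scale).
#' @param seed Integer seed (reproducible: same seed, same summary).
#' @param sds Input standard deviations (see [sensor_sds()]).
#' @param tol,max_time Steady-state settings (see
#'   [run_to_steady_state()]).
#' @param mixing Dead-space mixing model.
#' @param verbose Print progress every 200 draws.
#' @return A list of class `evlp_mc`: `mean` and `sd` (named, per output
#'   \[mmHg\]), `draws` (data.frame of per-draw outputs), `n`,
#'   `n_failed`.
#' @export
run_monte_carlo_static <- function(config = default_config(), n = 10000,
                                   seed = 1L, sds = sensor_sds(),
                                   tol = 0.05, max_time = 600,
                                   mixing = c("dilution", "plug"),
                                   verbose = FALSE) {
  mixing <- match.arg(mixing)
  mix <- if (mixing == "plug") 1L else 0L
  X <- sample_inputs(n, config, sds = sds, seed = seed)
  pv0 <- config_to_pars(config)
  y0 <- unname(initial_state()[.state_names])
  fd0 <- y0[2:3]
  o2 <- co2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pv <- apply_draw(pv0, X[i, ])
    ss <- tryCatch(
      cpp_run_to_steady(pv, y0, fd0, tol, max_time, 1e-9, 1e-9, 0.1, mix),
      error = function(e) NULL)
    if (!is.null(ss) && isTRUE(ss$converged)) {
      o2[i] <- ss$mean_pla_o2[ss$n_cycles]
      co2[i] <- ss$mean_pla_co2[ss$n_cycles]
    }
    if (verbose && i %% 200 == 0) message("draw ", i, "/", n)
  }
  ok <- is.finite(o2) & is.finite(co2)
  sd1 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- list(
    mean = c(P_LA_O2 = mean(o2[ok]), P_LA_CO2 = mean(co2[ok])),
    sd = c(P_LA_O2 = sd1(o2[ok]), P_LA_CO2 = sd1(co2[ok])),
    draws = data.frame(P_LA_O2 = o2, P_LA_CO2 = co2),
    n = n, n_failed = sum(!ok))
  class(out) <- "evlp_mc"
  out
}

#' Dynamic Monte-Carlo uncertainty of the oxygenation challenge
#'
#' For each draw, the perturbed inputs are held for a whole challenge
#' epoch (steady state at the pre-step FiO2, then the FiO2 step); the
#' sensor error on FiO2 is applied as a per-draw offset to both the pre-
#' and post-step levels (capped at 1.0). Time-resolved bands are
#' mean +/- SD plus 2.5/97.5 percentiles of the left-atrial PO2 across
#' draws on a 3-s grid.
#'
#' @inheritParams run_monte_carlo_static
#' @param n Number of draws (1,000 reproduces the full study).
#' @param pre_fio2,post_fio2,step_time,duration Challenge description.
#' @return A list of class `evlp_mc_dynamic`: `time` \[s\], `mean`, `sd`,
#'   `lo`, `hi` (per time point \[mmHg\]), `n`, `n_failed`.
#' @export
run_monte_carlo_dynamic <- function(config = default_config(), n = 1000,
                                    seed = 1L, pre_fio2 = 0.21,
                                    post_fio2 = 1.0, step_time = 180,
                                    duration = 900, tol = 0.05,
                                    max_time = 600,
                                    mixing = c("dilution", "plug"),
                                    verbose = FALSE) {
  mixing <- match.arg(mixing)
  mix <- if (mixing == "plug") 1L else 0L
  X <- sample_inputs(n, update_config(config, FiO2 = pre_fio2),
                     seed = seed)
  pv0 <- config_to_pars(config)
  y0 <- unname(initial_state()[.state_names])
  fd0 <- y0[2:3]
  grid <- seq(0, duration, by = 3)
  P <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    pv <- apply_draw(pv0, X[i, ])
    fio2_err <- X[i, "FiO2"] - pre_fio2
    pv[5] <- min(1, pre_fio2 + fio2_err)
    res <- tryCatch({
      ss <- cpp_run_to_steady(pv, y0, fd0, tol, max_time, 1e-9, 1e-9,
                              0.1, mix)
      if (!isTRUE(ss$converged)) stop("no steady state")
      pre_grid <- grid[grid <= step_time]
      s1 <- cpp_simulate(pv, ss$y_end, ss$fd_end, 0, step_time, pre_grid,
                         1e-9, 1e-9, 0.1, mix)
      pv2 <- pv
      pv2[5] <- min(1, post_fio2 + fio2_err)
      post_grid <- grid[grid > step_time]
      s2 <- cpp_simulate(pv2, s1$y_end, s1$fd_end, step_time, duration,
                         post_grid, 1e-9, 1e-9, 0.1, mix)
      fsh <- pv[12]
      c(pv[9] * fsh + (1 - fsh) * s1$states[, 4],
        pv[9] * fsh + (1 - fsh) * s2$states[, 4])
    }, error = function(e) NULL)
    if (!is.null(res) && length(res) == length(grid)) P[i, ] <- res
    if (verbose && i %% 100 == 0) message("draw ", i, "/", n)
  }
  ok <- stats::complete.cases(P)
  Pk <- P[ok, , drop = FALSE]
  out <- list(time = grid,
              mean = colMeans(Pk),
              sd = if (nrow(Pk) < 2) rep(0, ncol(Pk)) else
                apply(Pk, 2, stats::sd),
              lo = apply(Pk, 2, stats::quantile, probs = 0.025),
              hi = apply(Pk, 2, stats::quantile, probs = 0.975),
              n = n, n_failed = sum(!ok))
  class(out) <- "evlp_mc_dynamic"
  out
}
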