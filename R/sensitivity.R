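# Morris elementary-effects global sensitivity analysis.
#
# One-at-a-time screening: randomised trajectories through a p-level grid
# on the unit hypercube, mapped to the physical parameter ranges.  Each
# trajectory yields one elementary effect per parameter; mu* (mean
# absolute effect) ranks importance, sigma (SD of signed effects) flags
# interactions and nonlinearity.

#' Parameter ranges for the sensitivity study
#'
#' Clinical and intrinsic parameters vary over their normal ranges, the
#' physical constants over +/-50 % of their defaults. All ranges are in
#' canonical units; the hydrogen-ion concentration is sampled linearly on
#' its concentration range (1e-7.5 to 1e-7 mol/L).
#'
#' @return data.frame with `name`, `min`, `max` (canonical units).
#' @export
morris_ranges <- function() {
  rng <- evlp_ranges()
  sc <- ifelse(is.na(rng$scale), 1, rng$scale)
  lo <- rng$min * sc
  hi <- rng$max * sc
  lo[rng$name == "pH"] <- 10^-7.5
  hi[rng$name == "pH"] <- 10^-7
  cn <- rng$group == "constant"
  lo[cn] <- 0.5 * rng$default[cn]
  hi[cn] <- 1.5 * rng$default[cn]
  nm <- rng$name
  nm[nm == "pH"] <- "H"
  data.frame(name = nm, min = lo, max = hi)
}

#' Build a Morris one-at-a-time design
#'
#' Randomised trajectories on a `levels`-level grid of the unit hypercube
#' with elementary-effect step `delta = levels / (2 * (levels - 1))`,
#' mapped linearly onto the physical ranges. Trajectories producing any
#' infeasible point with `F_ds + F_sh >= 1` are rejected and redrawn, so
#' every design row is simulable.
#'
#' @param ranges data.frame as from [morris_ranges()].
#' @param trajectories Number of trajectories.
#' @param levels Number of grid levels (even).
#' @param seed Integer seed.
#' @return A list of class `morris_design`: `X` (physical design matrix,
#'   `trajectories * (k + 1)` rows), `U` (unit-space design), `delta`,
#'   `trajectories`, `levels`, `names`.
#' @export
build_morris_design <- function(ranges, trajectories = 75, levels = 10,
                                seed = 1L) {
  k <- nrow(ranges)
  if (k < 1) stop("need at least one parameter")
  if (any(ranges$max <= ranges$min)) stop("degenerate range")
  delta <- levels / (2 * (levels - 1))
  base_levels <- (seq_len(levels / 2) - 1) / (levels - 1)
  i_fds <- which(ranges$name == "F_ds")
  i_fsh <- which(ranges$name == "F_sh")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  one_traj <- function() {
    b <- sample(base_levels, k, replace = TRUE)
    d <- sample(c(-1, 1), k, replace = TRUE)
    ord <- sample.int(k)
    x <- ifelse(d > 0, b, b + delta) # start point
    rows <- matrix(0, k + 1, k)
    rows[1, ] <- x
    for (j in seq_len(k)) {
      i <- ord[j]
      x[i] <- x[i] + d[i] * delta
      rows[j + 1, ] <- x
    }
    rows
  }
  feasible <- function(U) {
    if (!length(i_fds) || !length(i_fsh)) return(TRUE)
    fds <- ranges$min[i_fds] + U[, i_fds] * (ranges$max[i_fds] -
                                               ranges$min[i_fds])
    fsh <- ranges$min[i_fsh] + U[, i_fsh] * (ranges$max[i_fsh] -
                                               ranges$min[i_fsh])
    all(fds + fsh < 1)
  }
  U <- vector("list", trajectories)
  for (tr in seq_len(trajectories)) {
    for (attempt in seq_len(10000)) {
      cand <- one_traj()
      if (feasible(cand)) break
      if (attempt == 10000) stop("could not draw a feasible trajectory")
    }
    U[[tr]] <- cand
  }
  U <- do.call(rbind, U)
  X <- sweep(sweep(U, 2, ranges$max - ranges$min, "*"), 2, ranges$min,
             "+")
  colnames(X) <- colnames(U) <- ranges$name
  out <- list(X = X, U = U, delta = delta, trajectories = trajectories,
              levels = levels, names = ranges$name)
  class(out) <- "morris_design"
  out
}

#' Elementary effects from design outputs
#'
#' Computes, per trajectory and parameter, the elementary effect
#' `EE = (y_after - y_before) / (signed unit-space step)`, then summarises
#' as `mu_star = mean(|EE|)` and `sigma = sd(EE)` per parameter. An
#' elementary effect whose pair of outputs contains a non-finite value
#' (e.g. a design corner that did not reach steady state) is dropped and
#' counted; dropping whole trajectories instead would discard almost the
#' entire design when slow corners are common, see the methods vignette.
#'
#' @param design A `morris_design`.
#' @param y Numeric vector, one model output per design row.
#' @return A list: `scores` (data.frame `parameter`, `mu_star`, `sigma`,
#'   `n_ee` retained effects, `mu_star_scaled`, `sigma_scaled`),
#'   `n_excluded` dropped elementary effects.
#' @export
elementary_effects <- function(design, y) {
  stopifnot(inherits(design, "morris_design"))
  k <- length(design$names)
  rows_per <- k + 1
  if (length(y) != nrow(design$U))
    stop("need one output per design row")
  EE <- matrix(NA_real_, design$trajectories, k)
  n_excluded <- 0L
  for (tr in seq_len(design$trajectories)) {
    off <- (tr - 1) * rows_per
    yt <- y[off + seq_len(rows_per)]
    for (j in seq_len(k)) {
      du <- design$U[off + j + 1, ] - design$U[off + j, ]
      i <- which(abs(du) > 1e-12)
      if (length(i) != 1) stop("design rows must differ in one coordinate")
      if (!is.finite(yt[j + 1]) || !is.finite(yt[j])) {
        n_excluded <- n_excluded + 1L
        next
      }
      EE[tr, i] <- (yt[j + 1] - yt[j]) / du[i]
    }
  }
  if (n_excluded > 0)
    warning(n_excluded, " elementary effects dropped (non-finite output)")
  mu_star <- apply(abs(EE), 2, mean, na.rm = TRUE)
  sigma <- apply(EE, 2, stats::sd, na.rm = TRUE)
  scores <- data.frame(parameter = design$names, mu_star = mu_star,
                       sigma = sigma,
                       n_ee = colSums(is.finite(EE)),
                       mu_star_scaled = minmax_scale(mu_star),
                       sigma_scaled = minmax_scale(sigma))
  list(scores = scores, n_excluded = n_excluded)
}

# Min-max scaling to [0, 1]; an all-constant vector maps to zeros.
minmax_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(diff(r)) || diff(r) <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Model outputs for one design row (canonical parameter vector `pv`):
# steady-state left-atrial tensions and, separately, the time constant of
# the left-atrial PO2 response to an FiO2 step 0.21 -> 1.0.  tau is fitted
# on a 3-s grid over `tau_window` seconds after the step.
morris_point_outputs <- function(pv, want_tau = TRUE, tau_window = 720,
                                 steady_tol = 0.05, max_time = 3600,
                                 mix = 0L) {
  y0 <- unname(initial_state()[.state_names])
  fd0 <- y0[2:3]
  out <- c(PLAO2 = NA_real_, PLACO2 = NA_real_, tau = NA_real_,
           r2 = NA_real_)
  ss <- tryCatch(
    cpp_run_to_steady(pv, y0, fd0, steady_tol, max_time, 1e-9, 1e-9, 0.1,
                      mix),
    error = function(e) NULL)
  if (!is.null(ss) && isTRUE(ss$converged)) {
    out["PLAO2"] <- ss$mean_pla_o2[ss$n_cycles]
    out["PLACO2"] <- ss$mean_pla_co2[ss$n_cycles]
  }
  if (!want_tau) return(out)
  pv_pre <- pv
  pv_pre[5] <- 0.21
  ss2 <- tryCatch(
    cpp_run_to_steady(pv_pre, y0, fd0, steady_tol, max_time, 1e-9, 1e-9,
                      0.1, mix),
    error = function(e) NULL)
  if (is.null(ss2) || !isTRUE(ss2$converged)) return(out)
  pv_post <- pv
  pv_post[5] <- 1.0
  grid <- seq(0, tau_window, by = 3)
  sim <- tryCatch(
    cpp_simulate(pv_post, ss2$y_end, ss2$fd_end, 0, tau_window, grid,
                 1e-9, 1e-9, 0.1, mix),
    error = function(e) NULL)
  if (is.null(sim)) return(out)
  fsh <- pv[12]
  pla <- pv[9] * fsh + (1 - fsh) * sim$states[, 4]
  baseline <- ss2$mean_pla_o2[ss2$n_cycles]
  fit <- tryCatch(
    fit_mono_exponential(sim$time, pla, baseline, step_time = 0),
    error = function(e) NULL)
  if (!is.null(fit)) {
    out["tau"] <- fit$tau
    out["r2"] <- fit$r_squared_raw
  }
  out
}

#' Run the global sensitivity study
#'
#' Morris screening of all 30 parameters and constants for three outputs:
#' steady-state left-atrial PO2 and PCO2 (cycle means), and the time
#' constant of the left-atrial PO2 response to an oxygenation challenge
#' (FiO2 stepped from 0.21 to 1.0 from steady state; for this output the
#' design's FiO2 coordinate is overridden by the challenge itself).
#' Per-output scores are min-max scaled to \[0, 1\].
#'
#' @param config Base configuration (supplies nothing varied; retained for
#'   interface symmetry and the mixing choice).
#' @param trajectories,levels,seed Design parameters (75 trajectories and
#'   10 levels reproduce the full study; ~20 trajectories suffice for
#'   screening at desk scale).
#' @param tau_window Post-step window used for the tau fit \[s\].
#' @param steady_max_time Per-point cap on simulated time when seeking the
#'   cyclic steady state \[s\]. Slow-washout design corners (small tidal
#'   volume, large anatomical dead space) need far longer than routine
#'   settings; points still unconverged at the cap yield dropped
#'   elementary effects.
#' @param mixing Dead-space mixing model.
#' @param verbose Print progress every 100 design rows.
#' @return A list of class `evlp_sensitivity`: `scores` (long data.frame:
#'   `output`, `parameter`, `mu_star`, `sigma`, `mu_star_scaled`,
#'   `sigma_scaled`), `r_squared` (per design row, raw), `design`,
#'   `n_excluded` per output.
#' @export
run_sensitivity_study <- function(config = default_config(),
                                  trajectories = 75, levels = 10,
                                  seed = 1L, tau_window = 720,
                                  steady_max_time = 3600,
                                  mixing = c("dilution", "plug"),
                                  verbose = FALSE) {
  mixing <- match.arg(mixing)
  mix <- if (mixing == "plug") 1L else 0L
  ranges <- morris_ranges()
  design <- build_morris_design(ranges, trajectories, levels, seed)
  n <- nrow(design$X)
  Y <- matrix(NA_real_, n, 4,
              dimnames = list(NULL, c("PLAO2", "PLACO2", "tau", "r2")))
  for (r in seq_len(n)) {
    pv <- as.numeric(design$X[r, ])
    Y[r, ] <- morris_point_outputs(pv, want_tau = TRUE,
                                   tau_window = tau_window,
                                   max_time = steady_max_time, mix = mix)
    if (verbose && r %% 100 == 0)
      message("morris row ", r, "/", n)
  }
  outs <- list(P_LA_O2 = Y[, "PLAO2"], P_LA_CO2 = Y[, "PLACO2"],
               tau_P_LA_O2 = Y[, "tau"])
  scored <- lapply(names(outs), function(nm) {
    ee <- elementary_effects(design, outs[[nm]])
    cbind(output = nm, ee$scores, n_excluded = ee$n_excluded)
  })
  scores <- do.call(rbind, scored)
  rownames(scores) <- NULL
  out <- list(scores = scores, r_squared = Y[, "r2"], design = design,
              outputs = Y)
  class(out) <- "evlp_sensitivity"
  out
}

#' @export
print.evlp_sensitivity <- function(x, ...) {
  cat("<evlp_sensitivity>\n")
  for (nm in unique(x$scores$output)) {
    s <- x$scores[x$scores$output == nm, ]
    top <- s$parameter[order(-s$mu_star)][1:3]
    cat(sprintf("  %-12s top mu*: %s\n", nm,
                paste(top, collapse = ", ")))
  }
  cat(sprintf("  median fit R^2: %.4f\n",
              stats::median(x$r_squared, na.rm = TRUE)))
  invisible(x)
}
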