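test_that("the one-at-a-time design has the stated combinatorics", {
  rng <- data.frame(name = c("a", "b", "c"), min = c(0, 1, -2),
                    max = c(1, 3, 2))
  des <- build_morris_design(rng, trajectories = 2, levels = 10, seed = 9)
  expect_identical(nrow(des$X), 8L)                 # T * (k + 1)
  expect_equal(des$delta, 10 / 18)                  # p / (2 (p - 1))
  # consecutive rows within a trajectory differ in exactly one coordinate
  for (tr in 0:1) {
    for (j in 1:3) {
      du <- des$U[tr * 4 + j + 1, ] - des$U[tr * 4 + j, ]
      expect_identical(sum(abs(du) > 1e-12), 1L)
      expect_equal(unname(abs(du[abs(du) > 1e-12])), des$delta,
                   tolerance = 1e-12)
    }
  }
  # every point sits on the 10-level grid
  lev <- (0:9) / 9
  expect_true(all(apply(des$U, c(1, 2), function(u)
    min(abs(u - lev)) < 1e-12)))
  # physical mapping respects the ranges
  expect_true(all(des$X >= matrix(rng$min, 8, 3, byrow = TRUE) - 1e-12))
  expect_true(all(des$X <= matrix(rng$max, 8, 3, byrow = TRUE) + 1e-12))
  expect_error(build_morris_design(
    data.frame(name = "a", min = 1, max = 1)), "degenerate")
})

test_that("infeasible dead-space/shunt combinations are rejected by
           redrawing trajectories", {
  des <- build_morris_design(morris_ranges(), trajectories = 5,
                             levels = 10, seed = 21)
  expect_true(all(des$X[, "F_ds"] + des$X[, "F_sh"] < 1))
})

test_that("elementary effects recover closed-form behaviour", {
  rng <- data.frame(name = c("x1", "x2"), min = c(0, 0), max = c(1, 1))
  des <- build_morris_design(rng, trajectories = 8, levels = 10,
                             seed = 13)
  # linear additive function: constant EEs, sigma ~ 0; absent parameter
  y <- 3 * des$U[, "x1"] + 0 * des$U[, "x2"]
  ee <- elementary_effects(des, y)
  s <- ee$scores
  expect_equal(s$mu_star[s$parameter == "x1"], 3, tolerance = 1e-10)
  expect_equal(s$sigma[s$parameter == "x1"], 0, tolerance = 1e-10)
  expect_equal(s$mu_star[s$parameter == "x2"], 0, tolerance = 1e-12)
  expect_equal(s$sigma[s$parameter == "x2"], 0, tolerance = 1e-12)
  # interaction: EEs of x1 depend on x2
  y2 <- des$U[, "x1"] * des$U[, "x2"]
  ee2 <- elementary_effects(des, y2)
  expect_gt(ee2$scores$sigma[ee2$scores$parameter == "x1"], 0.05)
  # non-finite outputs drop the affected effects with a warning
  y3 <- y
  y3[2] <- NA
  expect_warning(ee3 <- elementary_effects(des, y3), "dropped")
  expect_lt(sum(ee3$scores$n_ee), sum(ee$scores$n_ee))
})

test_that("min-max scaling is idempotent with maximum exactly one", {
  x <- c(0.2, 5, 3, 1)
  s <- evlpsim:::minmax_scale(x)
  expect_equal(max(s), 1)
  expect_equal(min(s), 0)
  expect_equal(evlpsim:::minmax_scale(s), s)
  expect_equal(evlpsim:::minmax_scale(rep(2, 4)), rep(0, 4))
})

test_that("steady-output rankings are stable across design seeds", {
  # full-size designs (75 trajectories): screening-size designs are too
  # noisy for rank stability.  Steady outputs only; the tau ranking is
  # exercised at a fixed seed in the acceptance suite.
  top2 <- function(seed) {
    des <- build_morris_design(morris_ranges(), trajectories = 75,
                               levels = 10, seed = seed)
    y <- matrix(NA_real_, nrow(des$X), 2)
    for (r in seq_len(nrow(des$X))) {
      out <- evlpsim:::morris_point_outputs(as.numeric(des$X[r, ]),
                                            want_tau = FALSE)
      y[r, ] <- out[c("PLAO2", "PLACO2")]
    }
    list(
      o2 = {
        s <- suppressWarnings(elementary_effects(des, y[, 1]))$scores
        sort(s$parameter[order(-s$mu_star)][1:2])
      },
      co2 = {
        s <- suppressWarnings(elementary_effects(des, y[, 2]))$scores
        s$parameter[which.max(s$mu_star)]
      })
  }
  a <- top2(101)
  b <- top2(202)
  expect_identical(a$o2, b$o2)
  expect_identical(a$co2, b$co2)
})
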