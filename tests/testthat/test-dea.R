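# input-oriented radial DEA: envelopment LPs, slacks, TE/PTE/SE, RTS

simple_problem <- function(x, y, technology = "VRS") {
  dea_problem(matrix(x, ncol = 1), matrix(y, ncol = 1),
              technology = technology)
}

test_that("radial scores match hand-solved reference programs", {
  # 3 DMUs, 1 input/1 output, VRS: hull of (2,2), (4,5), (8,6)
  pr <- suppressWarnings(simple_problem(c(2, 4, 8), c(2, 5, 6)))
  expect_equal(solve_radial(pr, 1)$theta, 1)  # smallest input: undominated
  expect_equal(solve_radial(pr, 2)$theta, 1)
  expect_equal(solve_radial(pr, 3)$theta, 1)  # only DMU reaching y = 6
  # an interior DMU against that hull: (6, 5) -> frontier input at y=5 is 4
  r <- solve_radial(pr, point = list(x = 6, y = 5))
  expect_equal(r$theta, 4 / 6, tolerance = 1e-9)

  # CRS: double inputs of an efficient peer, same outputs -> theta 0.5
  pc <- suppressWarnings(dea_problem(rbind(c(10, 20), c(20, 40)),
                                     rbind(c(5, 2), c(5, 2)),
                                     technology = "CRS"))
  r2 <- solve_radial(pc, 2)
  expect_equal(r2$theta, 0.5, tolerance = 1e-9)
  sl <- max_slacks(pc, 2, r2$theta)
  expect_equal(unname(sl$input_slacks), c(0, 0))
  expect_equal(unname(sl$output_slacks), c(0, 0))
})

test_that("every in-sample DMU has theta <= 1 (self-feasibility)", {
  p <- simulate_panel(simulation_config(seed = 12))$panel
  for (tech in c("CRS", "VRS")) {
    pr <- dea_problem_year(p, 2013, tech)
    th <- sapply(seq_along(pr$dmus), function(j) solve_radial(pr, j)$theta)
    expect_true(all(th <= 1 + 1e-9))
    expect_true(all(th > 0))
  }
})

test_that("LP scores equal convex-hull enumeration on 1-in/1-out VRS", {
  set.seed(77)
  for (k in 1:60) {
    n <- sample(2:6, 1)
    x <- round(runif(n, 1, 20), 2)
    y <- round(runif(n, 1, 20), 2)
    pr <- suppressWarnings(simple_problem(x, y))
    j <- sample(n, 1)
    expect_equal(solve_radial(pr, j)$theta, vrs_hull_oracle(x, y, j),
                 tolerance = 1e-9)
  }
})

test_that("duplicating an efficient DMU changes no score", {
  p <- simulate_panel(simulation_config(seed = 21))$panel
  pr <- dea_problem_year(p, 2014, "VRS")
  th <- sapply(seq_along(pr$dmus), function(j) solve_radial(pr, j)$theta)
  eff <- which(th >= 1 - 1e-9)[1]
  X2 <- rbind(pr$X, pr$X[eff, ])
  Y2 <- rbind(pr$Y, pr$Y[eff, ])
  pr2 <- suppressWarnings(dea_problem(X2, Y2, technology = "VRS"))
  th2 <- sapply(seq_len(nrow(X2)), function(j) solve_radial(pr2, j)$theta)
  expect_equal(th2[seq_along(th)], th, tolerance = 1e-8)
  expect_equal(th2[length(th2)], 1, tolerance = 1e-9)
})

test_that("scores are invariant to rescaling any single column", {
  p <- simulate_panel(simulation_config(seed = 30))$panel
  yr <- panel_year(p, 2015)
  X <- as.matrix(yr[c("institutions", "beds", "health_workers")])
  Y <- as.matrix(yr[c("visits_avg", "hosp_rate")])
  base <- dea_problem(X, Y, technology = "VRS")
  th <- sapply(seq_len(nrow(X)), function(j) solve_radial(base, j)$theta)
  Xs <- X
  Xs[, 2] <- Xs[, 2] * 1000
  Ys <- Y
  Ys[, 1] <- Ys[, 1] / 500
  scaled <- dea_problem(Xs, Ys, technology = "VRS")
  th2 <- sapply(seq_len(nrow(X)), function(j) solve_radial(scaled, j)$theta)
  expect_equal(th2, th, tolerance = 1e-9)
})

test_that("inflating a DMU's input never raises its score", {
  p <- simulate_panel(simulation_config(seed = 31))$panel
  yr <- panel_year(p, 2016)
  X <- as.matrix(yr[c("institutions", "beds", "health_workers")])
  Y <- as.matrix(yr[c("visits_avg", "hosp_rate")])
  for (j in c(3, 11, 25)) {
    th0 <- solve_radial(dea_problem(X, Y, technology = "VRS"), j)$theta
    X2 <- X
    X2[j, 1] <- X2[j, 1] * 1.5
    th1 <- solve_radial(dea_problem(X2, Y, technology = "VRS"), j)$theta
    expect_lte(th1, th0 + 1e-9)
  }
})

test_that("efficiency suite: TE <= PTE, SE in (0,1], sensible RTS", {
  p <- simulate_panel(simulation_config(seed = 40))$panel
  es <- efficiency_suite(p, 2016)
  expect_true(all(es$te <= es$pte + 1e-9))
  expect_true(all(es$se > 0 & es$se <= 1 + 1e-9))
  expect_true(all(es$rts_class %in% c("constant", "increasing", "decreasing")))
  expect_true(all(es$rts_class[es$te == 1] == "constant"))
  # identical DMUs: everyone efficient
  ident <- suppressWarnings(dea_problem(matrix(5, 4, 1), matrix(3, 4, 1),
                                        technology = "CRS"))
  thi <- sapply(1:4, function(j) solve_radial(ident, j)$theta)
  expect_equal(thi, rep(1, 4))
})

test_that("efficient DMUs carry zero slack; dominated DMUs project onto the frontier", {
  p <- two_point_panel()
  es <- suppressWarnings(efficiency_suite(p, 2015))  # 4-DMU toy panel
  alpha <- es[es$dmu == "Alpha", ]
  bravo <- es[es$dmu == "Bravo", ]
  expect_equal(alpha$pte, 1)
  expect_true(all(as.numeric(alpha[grep("^slack_", names(es))]) == 0))
  expect_lt(bravo$pte, 1)  # Bravo is dominated by construction
  # adjustments: negative input deltas, non-negative output deltas
  adj_in <- as.matrix(es[grep("^adj_(institutions|beds|health_workers)",
                              names(es))])
  adj_out <- as.matrix(es[grep("^adj_(visits_avg|hosp_rate)", names(es))])
  expect_true(all(adj_in <= 0))
  expect_true(all(adj_out >= 0))
  # replacing a DMU by its projection target makes it fully efficient
  yr <- panel_year(p, 2015)
  X <- as.matrix(yr[c("institutions", "beds", "health_workers")])
  Y <- as.matrix(yr[c("visits_avg", "hosp_rate")])
  jb <- which(yr$province == "Bravo")
  X[jb, ] <- as.numeric(bravo[paste0("target_", colnames(X))])
  Y[jb, ] <- as.numeric(bravo[paste0("target_", colnames(Y))])
  pr <- suppressWarnings(dea_problem(X, Y, technology = "VRS"))
  rt <- solve_radial(pr, jb)
  expect_equal(rt$theta, 1, tolerance = 1e-7)
  sl <- max_slacks(pr, jb, rt$theta)
  expect_equal(max(abs(c(sl$input_slacks / colMeans(X),
                         sl$output_slacks / colMeans(Y)))), 0,
               tolerance = 1e-6)
})

test_that("summaries report the mean of ratios, not the ratio of means", {
  p <- simulate_panel(simulation_config(seed = 50))$panel
  es <- efficiency_suite(p, 2012)
  sm <- summarize_efficiency(es)
  mm <- sm[sm$statistic == "mean", ]
  expect_equal(mm$se, mean(es$te / es$pte))
  expect_false(isTRUE(all.equal(mm$se, mm$te / mm$pte)))
  expect_equal(sm$te[sm$statistic == "max"], 1)  # someone is efficient
  expect_true(mm$te >= sm$te[sm$statistic == "min"] &&
                mm$te <= sm$te[sm$statistic == "max"])
})

test_that("small samples trigger the DMU-adequacy warning, not an error", {
  expect_warning(simple_problem(c(1, 2, 3), c(1, 2, 3)),
                 "fewer than 3 x \\(m \\+ s\\)")
  expect_error(dea_problem(matrix(c(1, 0), 2, 1), matrix(1, 2, 1)),
               "strictly positive")
  expect_error(dea_problem(matrix(1, 2, 1), matrix(0, 2, 1)),
               "at least one strictly positive output")
})
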