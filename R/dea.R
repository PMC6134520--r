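# Input-oriented radial DEA: CCR (constant returns) and BCC (variable
# returns) envelopment models, two-phase slack maximisation, TE/PTE/SE,
# returns-to-scale classification and projection targets.
#
# All envelopment programs are solved on column-rescaled data (each input and
# output column divided by its mean) -- radial scores are invariant to units,
# and rescaling protects LP conditioning given the magnitude gap between
# resource stocks (~1e5) and service outputs (~3). Slacks are mapped back to
# original units on output.

#' Construct a DEA problem
#'
#' @param inputs numeric matrix, one row per DMU, one column per input; all
#'   entries strictly positive.
#' @param outputs numeric matrix, one row per DMU, one column per output;
#'   every DMU needs at least one strictly positive output.
#' @param dmus DMU names; defaults to row names or `DMU1..n`.
#' @param technology `"VRS"` (BCC, variable returns to scale) or `"CRS"`
#'   (CCR, constant returns).
#' @return object of class `dea_problem`.
#' @export
dea_problem <- function(inputs, outputs, dmus = NULL,
                        technology = c("VRS", "CRS")) {
  technology <- match.arg(technology)
  X <- as.matrix(inputs)
  Y <- as.matrix(outputs)
  if (nrow(X) != nrow(Y)) stop("inputs and outputs disagree on DMU count",
                               call. = FALSE)
  if (any(X <= 0)) stop("all inputs must be strictly positive", call. = FALSE)
  if (any(Y < 0)) stop("outputs must be non-negative", call. = FALSE)
  if (any(rowSums(Y > 0) == 0)) {
    stop("every DMU needs at least one strictly positive output",
         call. = FALSE)
  }
  if (is.null(dmus)) dmus <- rownames(X)
  if (is.null(dmus)) dmus <- paste0("DMU", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("I", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("O", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < 3 * (ncol(X) + ncol(Y))) {
    warning(sprintf(
      "only %d DMUs for %d inputs + %d outputs; fewer than 3 x (m + s) DMUs weakens discrimination",
      n, ncol(X), ncol(Y)), call. = FALSE)
  }
  sx <- colMeans(X)
  sy <- colMeans(Y)
  sy[sy == 0] <- 1
  structure(list(X = X, Y = Y, dmus = dmus, technology = technology,
                 Xs = sweep(X, 2, sx, "/"), Ys = sweep(Y, 2, sy, "/"),
                 scale_x = sx, scale_y = sy),
            class = "dea_problem")
}

#' Build a DEA problem from one panel year
#'
#' Inputs are the three resource stocks (institutions, beds, health workers);
#' outputs are the average number of visits and the annual hospitalization
#' rate (percent, used directly as an output level).
#'
#' @param panel a [resource_panel()].
#' @param year calendar year present in the panel.
#' @inheritParams dea_problem
#' @return a [dea_problem()].
#' @export
dea_problem_year <- function(panel, year, technology = c("VRS", "CRS")) {
  yr <- panel_year(panel, year)
  dea_problem(as.matrix(yr[.panel_resources]),
              as.matrix(yr[c("visits_avg", "hosp_rate")]),
              dmus = yr$province, technology = match.arg(technology))
}

# scaled evaluated point for DMU j or an external point
.eval_point <- function(problem, dmu_index = NULL, point = NULL) {
  if (is.null(point)) {
    list(x = problem$Xs[dmu_index, ], y = problem$Ys[dmu_index, ])
  } else {
    list(x = point$x / problem$scale_x, y = point$y / problem$scale_y)
  }
}

#' Phase-1 radial envelopment score of one DMU
#'
#' Solves `min theta` s.t. `sum_j lambda_j x_j <= theta * x_0`,
#' `sum_j lambda_j y_j >= y_0`, `lambda >= 0`, plus `sum lambda = 1` under
#' VRS. With `point` given, an external point (e.g. another period's
#' observation) is evaluated against this problem's frontier; the score may
#' then exceed 1, and under VRS the program can be infeasible (returns
#' `theta = NA` with `status = "infeasible"`).
#'
#' @param problem a [dea_problem()].
#' @param dmu_index index of the DMU to evaluate (ignored if `point` given).
#' @param point optional list with `x` (input vector) and `y` (output
#'   vector) in original units.
#' @return list with `theta`, `lambda` (intensity weights over the
#'   problem's DMUs) and `status`.
#' @export
solve_radial <- function(problem, dmu_index = NULL, point = NULL) {
  stopifnot(inherits(problem, "dea_problem"))
  ev <- .eval_point(problem, dmu_index, point)
  n <- nrow(problem$Xs)
  m <- ncol(problem$Xs)
  s <- ncol(problem$Ys)
  # vars: theta, lambda_1..n
  A <- rbind(cbind(-ev$x, t(problem$Xs)),            # lX - theta x0 <= 0
             cbind(rep(0, s), -t(problem$Ys)))       # -lY <= -y0
  dir <- rep("<=", m + s)
  rhs <- c(rep(0, m), -ev$y)
  if (problem$technology == "VRS") {
    A <- rbind(A, c(0, rep(1, n)))
    dir <- c(dir, "==")
    rhs <- c(rhs, 1)
  }
  res <- lp_solve(c(1, rep(0, n)), A, dir, rhs)
  if (res$status != "optimal") {
    if (res$status == "infeasible") {
      return(list(theta = NA_real_, lambda = rep(NA_real_, n),
                  status = "infeasible"))
    }
    stop("radial envelopment LP failed (", res$status, ") for ",
         if (is.null(point)) problem$dmus[dmu_index] else "external point",
         call. = FALSE)
  }
  list(theta = res$solution[1], lambda = res$solution[-1], status = "optimal")
}

#' Phase-2 slack maximisation at a fixed radial score
#'
#' With `theta` fixed at its phase-1 optimum, maximises the sum of input and
#' output slacks subject to the envelopment constraints written with
#' explicit slacks (slack sums are taken on mean-rescaled data so the
#' objective is units-free; returned slacks are in original units).
#'
#' @inheritParams solve_radial
#' @param theta phase-1 radial score for this DMU.
#' @return list with `input_slacks`, `output_slacks` (original units),
#'   `lambda`.
#' @export
max_slacks <- function(problem, dmu_index = NULL, theta, point = NULL) {
  stopifnot(inherits(problem, "dea_problem"))
  ev <- .eval_point(problem, dmu_index, point)
  n <- nrow(problem$Xs)
  m <- ncol(problem$Xs)
  s <- ncol(problem$Ys)
  # vars: lambda_1..n, s_minus (m), s_plus (s)
  A <- rbind(cbind(t(problem$Xs), diag(m), matrix(0, m, s)),
             cbind(t(problem$Ys), matrix(0, s, m), -diag(s)))
  dir <- rep("==", m + s)
  rhs <- c(theta * ev$x, ev$y)
  if (problem$technology == "VRS") {
    A <- rbind(A, c(rep(1, n), rep(0, m + s)))
    dir <- c(dir, "==")
    rhs <- c(rhs, 1)
  }
  res <- lp_solve(c(rep(0, n), rep(1, m + s)), A, dir, rhs, maximize = TRUE)
  if (res$status != "optimal") {
    stop("slack-maximisation LP failed (", res$status, ") for ",
         if (is.null(point)) problem$dmus[dmu_index] else "external point",
         call. = FALSE)
  }
  sm <- res$solution[n + seq_len(m)]
  sp <- res$solution[n + m + seq_len(s)]
  sm[sm < 1e-6] <- 0
  sp[sp < 1e-6] <- 0
  list(input_slacks = sm * problem$scale_x,
       output_slacks = sp * problem$scale_y,
       lambda = res$solution[seq_len(n)])
}

# range of sum(lambda) over alternate optima of the CRS phase-1 LP
.rts_lambda_range <- function(problem, dmu_index, theta) {
  n <- nrow(problem$Xs)
  m <- ncol(problem$Xs)
  s <- ncol(problem$Ys)
  ev <- .eval_point(problem, dmu_index)
  A <- rbind(t(problem$Xs), -t(problem$Ys))
  dir <- rep("<=", m + s)
  rhs <- c(theta * ev$x, -ev$y)
  obj <- rep(1, n)
  lo <- lp_solve(obj, A, dir, rhs, maximize = FALSE)
  hi <- lp_solve(obj, A, dir, rhs, maximize = TRUE)
  c(lo = lo$value, hi = hi$value)
}

.snap_one <- function(v, tol = 1e-6) ifelse(abs(v - 1) <= tol, 1, v)

#' Full efficiency suite for one panel year
#'
#' Runs the CCR (CRS) model for overall technical efficiency (TE) and the
#' BCC (VRS) model for pure technical efficiency (PTE) on every province,
#' computes scale efficiency SE = TE/PTE, classifies returns to scale from
#' the range of `sum(lambda)` over alternate optima of the CRS program
#' (constant iff 1 lies in the range, increasing if the whole range is below
#' 1, decreasing if above), and derives BCC projection targets and
#' adjustments from the two-phase solution: input adjustment
#' `theta * x - slack_in - x` (non-positive), output adjustment `+slack_out`
#' (non-negative). Scores within 1e-6 of 1 are reported as exactly 1.
#'
#' @param panel a [resource_panel()].
#' @param year calendar year present in the panel.
#' @return data frame, one row per province: `dmu`, `te`, `pte`, `se`,
#'   `rts_class`, input/output slack and adjustment columns, plus the year.
#' @export
efficiency_suite <- function(panel, year) {
  crs <- dea_problem_year(panel, year, "CRS")
  vrs <- dea_problem_year(panel, year, "VRS")
  n <- length(crs$dmus)
  m <- ncol(crs$X)
  s <- ncol(crs$Y)
  te <- pte <- numeric(n)
  rts <- character(n)
  sl_in <- matrix(0, n, m, dimnames = list(NULL, colnames(crs$X)))
  sl_out <- matrix(0, n, s, dimnames = list(NULL, colnames(crs$Y)))
  for (j in seq_len(n)) {
    rc <- solve_radial(crs, j)
    rv <- solve_radial(vrs, j)
    te[j] <- .snap_one(rc$theta)
    pte[j] <- .snap_one(rv$theta)
    rng <- .rts_lambda_range(crs, j, rc$theta)
    rts[j] <- if (rng["lo"] <= 1 + 1e-6 && rng["hi"] >= 1 - 1e-6) {
      "constant"
    } else if (rng["hi"] < 1) "increasing" else "decreasing"
    ph2 <- max_slacks(vrs, j, rv$theta)
    sl_in[j, ] <- ph2$input_slacks
    sl_out[j, ] <- ph2$output_slacks
  }
  se <- pmin(te / pte, 1)
  X <- crs$X
  Y <- crs$Y
  tgt_in <- pte * X - sl_in
  adj_in <- tgt_in - X
  adj_in[abs(adj_in) < 1e-6] <- 0
  out <- data.frame(dmu = crs$dmus, year = year, te = te, pte = pte,
                    se = .snap_one(se), rts_class = rts,
                    stringsAsFactors = FALSE)
  colnames(sl_in) <- paste0("slack_", colnames(X))
  colnames(sl_out) <- paste0("slack_", colnames(Y))
  colnames(adj_in) <- paste0("adj_", colnames(X))
  adj_out <- sl_out
  colnames(adj_out) <- paste0("adj_", colnames(Y))
  tgt <- cbind(tgt_in, Y + sl_out)
  colnames(tgt) <- paste0("target_", c(colnames(X), colnames(Y)))
  cbind(out, as.data.frame(adj_in), as.data.frame(adj_out),
        as.data.frame(sl_in), as.data.frame(sl_out), as.data.frame(tgt))
}

#' Input/output adjustments needed by inefficient provinces
#'
#' The BCC projection deltas: for each province, how much each input must
#' shrink (negative numbers) and each output grow (non-negative) to reach
#' the efficient frontier.
#'
#' @inheritParams efficiency_suite
#' @return data frame of adjustment columns per province.
#' @export
dea_adjustments <- function(panel, year) {
  suite <- efficiency_suite(panel, year)
  keep <- c("dmu", "year", grep("^adj_", names(suite), value = TRUE))
  suite[keep]
}

#' Mean / max / min of TE, PTE and SE per year
#'
#' @param suites a data frame from [efficiency_suite()] or a list of them
#'   (several years), row-bound.
#' @return data frame with one row per (year, statistic).
#' @export
summarize_efficiency <- function(suites) {
  if (is.list(suites) && !is.data.frame(suites)) {
    suites <- do.call(rbind, suites)
  }
  res <- lapply(split(suites, suites$year), function(d) {
    data.frame(year = d$year[1],
               statistic = c("mean", "max", "min"),
               te = c(mean(d$te), max(d$te), min(d$te)),
               pte = c(mean(d$pte), max(d$pte), min(d$pte)),
               se = c(mean(d$se), max(d$se), min(d$se)),
               n_efficient = sum(d$te == 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
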