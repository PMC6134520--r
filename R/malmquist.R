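# Adjacent-period Malmquist productivity index with full decomposition
# TFPC = TEC x TC and TEC = PTEC x SEC.

#' Radial distance of a point against a reference-period frontier
#'
#' Input-oriented Farrell score of an arbitrary (x, y) point against the
#' frontier spanned by a reference data set. Within-period this equals the
#' ordinary DEA score; cross-period the score may exceed 1 (the point lies
#' beyond the reference frontier). Under CRS the program is always feasible;
#' under VRS a cross-period point can fall outside the attainable output set,
#' in which case `NA` is returned with a warning.
#'
#' @param reference a [dea_problem()] built from the reference period.
#' @param x,y input and output vectors of the evaluated point (original
#'   units).
#' @return the radial score (positive scalar, may exceed 1), or `NA` if the
#'   VRS program is infeasible.
#' @export
cross_period_distance <- function(reference, x, y) {
  res <- solve_radial(reference, point = list(x = x, y = y))
  if (res$status == "infeasible") {
    warning("cross-period VRS program infeasible for evaluated point",
            call. = FALSE)
    return(NA_real_)
  }
  res$theta
}

#' Malmquist productivity index between two adjacent years
#'
#' For each province, with `D_t(s)` the CRS radial score of the period-s
#' observation against the period-t frontier:
#' technical efficiency change `TEC = D_{t+1}(t+1) / D_t(t)`; technological
#' change `TC = sqrt( (D_t(t+1)/D_{t+1}(t+1)) * (D_t(t)/D_{t+1}(t)) )`
#' (the adjacent-period geometric-mean construction); total factor
#' productivity change `TFPC = TEC * TC`. Pure technical efficiency change
#' `PTEC` is the ratio of the two within-period VRS scores and scale
#' efficiency change `SEC = TEC / PTEC`. All identities hold exactly by
#' construction; the decomposition needs no cross-period VRS program.
#'
#' @param panel a balanced [resource_panel()].
#' @param year_t,year_t1 the two years (must share the same province set).
#' @return object of class `malmquist_result`: data frame per province with
#'   columns `tec`, `tc`, `ptec`, `sec`, `tfpc` and the four CRS distances.
#' @export
malmquist <- function(panel, year_t, year_t1) {
  yr0 <- panel_year(panel, year_t)
  yr1 <- panel_year(panel, year_t1)
  if (!identical(yr0$province, yr1$province)) {
    only0 <- setdiff(yr0$province, yr1$province)
    only1 <- setdiff(yr1$province, yr0$province)
    stop("DMU sets differ between years: ",
         paste(c(only0, only1), collapse = ", "), call. = FALSE)
  }
  crs0 <- dea_problem_year(panel, year_t, "CRS")
  crs1 <- dea_problem_year(panel, year_t1, "CRS")
  vrs0 <- dea_problem_year(panel, year_t, "VRS")
  vrs1 <- dea_problem_year(panel, year_t1, "VRS")
  n <- length(crs0$dmus)
  d00 <- d01 <- d10 <- d11 <- v00 <- v11 <- numeric(n)
  for (j in seq_len(n)) {
    p0 <- list(x = crs0$X[j, ], y = crs0$Y[j, ])
    p1 <- list(x = crs1$X[j, ], y = crs1$Y[j, ])
    d00[j] <- solve_radial(crs0, j)$theta          # D_t(t)
    d11[j] <- solve_radial(crs1, j)$theta          # D_{t+1}(t+1)
    d01[j] <- solve_radial(crs0, point = p1)$theta # D_t(t+1)
    d10[j] <- solve_radial(crs1, point = p0)$theta # D_{t+1}(t)
    v00[j] <- solve_radial(vrs0, j)$theta
    v11[j] <- solve_radial(vrs1, j)$theta
  }
  tec <- d11 / d00
  tc <- sqrt((d01 / d11) * (d00 / d10))
  ptec <- v11 / v00
  out <- data.frame(dmu = crs0$dmus, pair = paste0(year_t, "-", year_t1),
                    tec = tec, tc = tc, ptec = ptec, sec = tec / ptec,
                    tfpc = tec * tc,
                    d_tt = d00, d_t1t1 = d11, d_tt1 = d01, d_t1t = d10,
                    stringsAsFactors = FALSE)
  class(out) <- c("malmquist_result", "data.frame")
  out
}

#' Malmquist indices for every adjacent pair of years in a panel
#'
#' @param panel a balanced [resource_panel()].
#' @return row-bound [malmquist()] results for each adjacent year pair.
#' @export
malmquist_all <- function(panel) {
  yrs <- attr(panel, "years")
  if (length(yrs) < 2) stop("need at least two years", call. = FALSE)
  res <- lapply(seq_len(length(yrs) - 1),
                function(i) malmquist(panel, yrs[i], yrs[i + 1]))
  out <- do.call(rbind, res)
  class(out) <- c("malmquist_result", "data.frame")
  out
}

.mpi_components <- c("tec", "tc", "ptec", "sec", "tfpc")

#' Summaries of Malmquist results
#'
#' All means are geometric: annual rows average over provinces, province
#' rows average over period pairs, and the grand mean averages the annual
#' geometric means (equal province counts make this identical to the
#' geometric mean over all cells). Frequency tables count, per period pair
#' and component, the DMUs with an index above, at (within 1e-6) and below
#' 1.
#'
#' @param results a `malmquist_result` (one or more period pairs).
#' @return list with `by_year` (geometric means per pair plus a `mean`
#'   row), `by_province` (geometric means per DMU plus a `mean` row),
#'   `grand_mean` (named vector) and `frequency` (long data frame with
#'   counts `gt_1`, `eq_1`, `lt_1`).
#' @export
summarize_malmquist <- function(results) {
  stopifnot(all(.mpi_components %in% names(results)))
  gm_block <- function(d) sapply(.mpi_components,
                                 function(cc) geometric_mean(d[[cc]]))
  by_year <- do.call(rbind, lapply(split(results, results$pair), gm_block))
  by_year <- data.frame(pair = rownames(by_year), by_year, row.names = NULL,
                        stringsAsFactors = FALSE)
  grand <- sapply(.mpi_components, function(cc) geometric_mean(by_year[[cc]]))
  by_year <- rbind(by_year,
                   data.frame(pair = "mean", t(grand), row.names = NULL))
  by_prov <- do.call(rbind, lapply(split(results, results$dmu), gm_block))
  by_prov <- data.frame(dmu = rownames(by_prov), by_prov, row.names = NULL,
                        stringsAsFactors = FALSE)
  by_prov <- by_prov[order(by_prov$dmu), ]
  prov_grand <- sapply(.mpi_components,
                       function(cc) geometric_mean(results[[cc]]))
  by_prov <- rbind(by_prov,
                   data.frame(dmu = "mean", t(prov_grand), row.names = NULL))
  freq <- do.call(rbind, lapply(split(results, results$pair), function(d) {
    do.call(rbind, lapply(.mpi_components, function(cc) {
      v <- d[[cc]]
      eq <- abs(v - 1) <= 1e-6
      data.frame(pair = d$pair[1], component = cc,
                 gt_1 = sum(v > 1 & !eq), eq_1 = sum(eq),
                 lt_1 = sum(v < 1 & !eq), stringsAsFactors = FALSE)
    }))
  }))
  rownames(freq) <- NULL
  list(by_year = by_year, by_province = by_prov, grand_mean = grand,
       frequency = freq)
}
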