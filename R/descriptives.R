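# Densities, compound growth and input/output descriptive statistics.

#' Resource density per 1000 persons or per km2
#'
#' Densities are ratios of aggregated totals: `per_1000_persons` divides the
#' resource total by the total population in thousands (so the quotient is a
#' per-1000-person rate); `per_km2` divides by total land area.
#'
#' @param panel a [resource_panel()].
#' @param resource one of `"institutions"`, `"beds"`, `"health_workers"`.
#' @param basis `"per_1000_persons"` or `"per_km2"`.
#' @param scope aggregation level: `"national"`, `"by_region"` or
#'   `"by_province"`.
#' @param year calendar year present in the panel.
#' @param partition a [region_partition()] for `scope = "by_region"`;
#'   defaults to the panel's own region column.
#' @return data frame with columns `unit`, `resource`, `basis`, `total`,
#'   `denominator`, `density`.
#' @export
phc_density <- function(panel, resource = .panel_resources,
                        basis = c("per_1000_persons", "per_km2"),
                        scope = c("national", "by_region", "by_province"),
                        year, partition = NULL) {
  resource <- match.arg(resource)
  basis <- match.arg(basis)
  scope <- match.arg(scope)
  yr <- panel_year(panel, year)
  denom_col <- if (basis == "per_1000_persons") "population" else "area"
  grp <- switch(scope,
    national = rep("nation", nrow(yr)),
    by_region = {
      if (is.null(partition)) partition <- panel_partition(panel)
      as.character(.partition_groups(partition, yr$province))
    },
    by_province = yr$province
  )
  tot <- tapply(yr[[resource]], grp, sum)
  den <- tapply(yr[[denom_col]], grp, sum)
  out <- data.frame(unit = names(tot), resource = resource, basis = basis,
                    total = as.numeric(tot), denominator = as.numeric(den),
                    density = as.numeric(tot) / as.numeric(den),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$unit), , drop = FALSE]
}

#' Average annual growth rate (compound)
#'
#' The compound (geometric) per-period growth rate
#' `((end/start)^(1/n) - 1) * 100`, in percent per period. Vectorised over
#' its arguments.
#'
#' @param start_value,end_value positive start and end levels.
#' @param n_periods number of periods between them (>= 1).
#' @return growth rate(s) in percent per period.
#' @examples
#' aagr(912620, 926518, 4)  # ~0.379 % per year
#' @export
aagr <- function(start_value, end_value, n_periods) {
  if (any(start_value <= 0) || any(end_value <= 0)) {
    stop("aagr() requires positive start and end values", call. = FALSE)
  }
  if (any(n_periods < 1)) stop("n_periods must be >= 1", call. = FALSE)
  ((end_value / start_value)^(1 / n_periods) - 1) * 100
}

#' Descriptive statistics of DEA inputs and outputs for one year
#'
#' Mean, maximum and minimum across provinces of the three inputs
#' (institutions, beds, health workers) and the two outputs (average number
#' of visits, annual hospitalization rate).
#'
#' @param panel a [resource_panel()].
#' @param year calendar year present in the panel.
#' @return data frame with rows `mean`, `max`, `min`.
#' @export
describe_io <- function(panel, year) {
  yr <- panel_year(panel, year)
  cols <- c(.panel_resources, "visits_avg", "hosp_rate")
  m <- sapply(yr[cols], function(v) c(mean = mean(v), max = max(v),
                                      min = min(v)))
  out <- data.frame(statistic = rownames(m), m, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$year <- year
  out
}

#' Geometric mean
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  if (any(x <= 0)) stop("geometric_mean() requires positive values",
                        call. = FALSE)
  exp(mean(log(x)))
}
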