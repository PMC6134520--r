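# Lorenz/Gini, Theil decomposition and the health resource density index.

.gini_bands <- c("absolute equality", "relative equality", "proper equality",
                 "relative inequality", "severe inequality")

#' Classify a Gini coefficient into the conventional five equity bands
#'
#' Bands are left-closed: `[0, 0.2)` absolute equality, `[0.2, 0.3)` relative
#' equality, `[0.3, 0.4)` proper equality, `[0.4, 0.5)` relative inequality
#' and `[0.5, 1]` severe inequality.
#'
#' @param g Gini coefficient in `[0, 1]`.
#' @return one of the five band labels.
#' @export
classify_gini <- function(g) {
  if (any(g < -1e-12 | g > 1 + 1e-12)) {
    stop("Gini coefficient must lie in [0, 1]", call. = FALSE)
  }
  g <- pmin(pmax(g, 0), 1)
  .gini_bands[findInterval(g, c(0.2, 0.3, 0.4, 0.5)) + 1L]
}

#' Lorenz curve and weighted Gini coefficient of a resource allocation
#'
#' Provinces are sorted ascending by resource per unit of the chosen
#' dimension (per capita for `dimension = "population"`, per km2 for
#' `"area"`; ties broken by province name), cumulative shares are
#' accumulated in that order, and the Gini coefficient is obtained from the
#' trapezoid rule `G = 1 - sum((Y[i+1] + Y[i]) * (X[i+1] - X[i]))` where `X`
#' is the cumulative population (or area) share and `Y` the cumulative
#' resource share, both starting at (0, 0).
#'
#' @param panel a [resource_panel()].
#' @param year calendar year present in the panel.
#' @param resource `"institutions"`, `"beds"` or `"health_workers"`.
#' @param dimension ranking/weighting dimension: `"population"` or `"area"`.
#' @return object of class `lorenz_gini`: list with `points` (data frame of
#'   cumulative shares `x`, `y` including the origin), `gini`, `band`,
#'   `resource`, `dimension`, `year`.
#' @export
lorenz_gini <- function(panel, year, resource = .panel_resources,
                        dimension = c("population", "area")) {
  resource <- match.arg(resource)
  dimension <- match.arg(dimension)
  yr <- panel_year(panel, year)
  if (nrow(yr) < 2) stop("Lorenz/Gini needs at least 2 provinces",
                         call. = FALSE)
  w <- yr[[dimension]]
  v <- yr[[resource]]
  if (sum(v) <= 0) stop("total resource is zero; Gini undefined",
                        call. = FALSE)
  ord <- order(v / w, yr$province)
  w <- w[ord] / sum(w)
  v <- v[ord] / sum(v)
  x <- c(0, cumsum(w))
  y <- c(0, cumsum(v))
  g <- 1 - sum((y[-1] + y[-length(y)]) * diff(x))
  g <- min(max(g, 0), 1)
  structure(list(points = data.frame(province = c(NA, yr$province[ord]),
                                     x = x, y = y),
                 gini = g, band = classify_gini(g), resource = resource,
                 dimension = dimension, year = year),
            class = "lorenz_gini")
}

#' @export
print.lorenz_gini <- function(x, ...) {
  cat(sprintf("Lorenz/Gini of %s by %s, %d: G = %.4f (%s)\n",
              x$resource, x$dimension, x$year, x$gini, x$band))
  invisible(x)
}

#' Theil index with within/between-region decomposition
#'
#' The population-weighted Theil index
#' `T = sum(P_i * log(P_i / Y_i))` with `P_i` the province's share of the
#' chosen weighting dimension and `Y_i` its share of the resource (natural
#' logarithm). For a partition into groups g, `T` decomposes exactly as
#' `T = T_within + T_between`, with `T_within = sum(P_g * T_g)` (each `T_g`
#' the Theil index computed on within-group shares) and
#' `T_between = sum(P_g * log(P_g / Y_g))`. Contribution rates are the two
#' components divided by `T`.
#'
#' @inheritParams lorenz_gini
#' @param partition a [region_partition()]; defaults to the panel's own
#'   region column.
#' @param dimension weighting dimension for the shares `P_i`; the
#'   conventional demographic index uses `"population"`.
#' @return object of class `theil_decomposition`: list with `total`,
#'   `within`, `between`, `per_group` (data frame of `group`, `P_g`, `Y_g`,
#'   `T_g`), `contrib_within`, `contrib_between`.
#' @export
theil_decomp <- function(panel, year, resource = .panel_resources,
                         partition = NULL,
                         dimension = c("population", "area")) {
  resource <- match.arg(resource)
  dimension <- match.arg(dimension)
  yr <- panel_year(panel, year)
  if (is.null(partition)) partition <- panel_partition(panel)
  grp <- .partition_groups(partition, yr$province)
  if (any(tabulate(grp, nbins = nlevels(grp)) == 0)) {
    stop("partition has empty group(s) on this panel", call. = FALSE)
  }
  v <- yr[[resource]]
  if (any(v <= 0)) {
    stop("province with zero resource: ",
         paste(yr$province[v <= 0], collapse = ", "),
         " (Theil log-share undefined)", call. = FALSE)
  }
  P <- yr[[dimension]] / sum(yr[[dimension]])
  Y <- v / sum(v)
  total <- sum(P * log(P / Y))

  Pg <- as.numeric(tapply(P, grp, sum))
  Yg <- as.numeric(tapply(Y, grp, sum))
  Tg <- sapply(levels(grp), function(g) {
    i <- grp == g
    p <- P[i] / sum(P[i])
    y <- Y[i] / sum(Y[i])
    sum(p * log(p / y))
  })
  within <- sum(Pg * Tg)
  between <- sum(Pg * log(Pg / Yg))
  structure(list(total = total, within = within, between = between,
                 per_group = data.frame(group = levels(grp), P_g = Pg,
                                        Y_g = Yg, T_g = as.numeric(Tg)),
                 contrib_within = if (total > 0) within / total else NA_real_,
                 contrib_between = if (total > 0) between / total else NA_real_,
                 resource = resource, dimension = dimension, year = year),
            class = "theil_decomposition")
}

#' @export
print.theil_decomposition <- function(x, ...) {
  cat(sprintf(
    "Theil index of %s by %s, %d: T = %.4f (within %.4f, between %.4f)\n",
    x$resource, x$dimension, x$year, x$total, x$within, x$between))
  if (!is.na(x$contrib_within)) {
    cat(sprintf("  contribution rates: within %.2f%%, between %.2f%%\n",
                100 * x$contrib_within, 100 * x$contrib_between))
  }
  invisible(x)
}

#' Health resource density index (HRDI)
#'
#' The geometric mean of a resource's per-1000-person and per-km2 densities,
#' balancing the demographic and geographic views of allocation in one
#' number.
#'
#' @inheritParams phc_density
#' @return data frame with columns `unit`, `resource`, `per_1000_persons`,
#'   `per_km2`, `hrdi`.
#' @export
hrdi <- function(panel, year, resource = .panel_resources,
                 scope = c("national", "by_region", "by_province"),
                 partition = NULL) {
  resource <- match.arg(resource)
  scope <- match.arg(scope)
  pc <- phc_density(panel, resource, "per_1000_persons", scope, year,
                    partition)
  pa <- phc_density(panel, resource, "per_km2", scope, year, partition)
  stopifnot(identical(pc$unit, pa$unit))
  data.frame(unit = pc$unit, resource = resource,
             per_1000_persons = pc$density, per_km2 = pa$density,
             hrdi = hrdi_index(pc$density, pa$density),
             stringsAsFactors = FALSE)
}

#' HRDI from two pre-computed densities
#'
#' @param per_capita density per 1000 persons (>= 0).
#' @param per_area density per km2 (>= 0).
#' @return `sqrt(per_capita * per_area)`, vectorised.
#' @export
hrdi_index <- function(per_capita, per_area) {
  if (any(per_capita < 0) || any(per_area < 0)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  sqrt(per_capita * per_area)
}
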