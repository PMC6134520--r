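# Bundled reference aggregates: national yearbook totals/densities and
# published provincial productivity estimates, used as fixtures for
# cross-checks and worked examples (the provincial raw panel itself is not
# redistributable).

.ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "equidea", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' National primary-care resource totals and densities, 2012-2016
#'
#' Statistical-yearbook national aggregates: total institutions, beds and
#' health workers with their per-1000-person and per-km2 densities.
#'
#' @return data frame, one row per year.
#' @export
phc_national_totals <- function() .ref_csv("phc_national_totals.csv")

#' Urban/rural split of population and primary-care resources, 2012-2016
#'
#' National urban and rural population (thousands) and resource counts.
#'
#' @return data frame, one row per year.
#' @export
phc_urban_rural <- function() .ref_csv("phc_urban_rural.csv")

#' Published health-resource-density-index reference values, 2012-2016
#'
#' Regional and national HRDI values from a published national analysis of
#' primary-care resource allocation; used to cross-check [hrdi_index()].
#'
#' @return data frame with columns `year`, `resource`, `east`, `central`,
#'   `west`, `nation`.
#' @export
phc_hrdi_reference <- function() .ref_csv("phc_hrdi_reference.csv")

#' Published Malmquist-index reference estimates, 2012-2016
#'
#' Per-adjacent-year-pair and per-province component estimates (TEC, TC,
#' PTEC, SEC, TFPC) from a published national analysis of primary-care
#' productivity; used to cross-check aggregation rules and decomposition
#' identities.
#'
#' @param level `"annual"` (one row per adjacent year pair) or
#'   `"province"` (one row per province, period-geometric means).
#' @return data frame.
#' @export
mpi_reference <- function(level = c("annual", "province")) {
  level <- match.arg(level)
  .ref_csv(paste0("mpi_", level, "_reference.csv"))
}
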