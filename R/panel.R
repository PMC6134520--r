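#' @importFrom stats setNames rbeta rlnorm runif plogis qnorm pnorm
#' @importFrom utils read.csv write.csv
NULL

# canonical column sets ------------------------------------------------------

.panel_required <- c("province", "region", "year", "population", "area",
                     "institutions", "beds", "health_workers",
                     "visits_avg", "hosp_rate")

.panel_resources <- c("institutions", "beds", "health_workers")

.panel_split_fields <- c("population", "institutions", "beds", "health_workers")

.panel_split_cols <- as.vector(outer(.panel_split_fields,
                                     c("urban", "rural"), paste, sep = "_"))

#' Construct a validated province-by-year resource panel
#'
#' A resource panel is a data frame with one row per (province, year) holding
#' the province's resident population (in thousands), land area (km2), the
#' three primary-care resource stocks used as DEA inputs (institutions, beds,
#' health workers), the two service outputs (average number of visits per
#' person per year and the annual hospitalization rate in percent) and a
#' region label. Optional urban/rural splits of population and the three
#' resource stocks may be present as `<field>_urban` / `<field>_rural`
#' columns and must sum to the totals.
#'
#' @param df data frame containing at least the columns `province`, `region`,
#'   `year`, `population` (thousands of persons), `area` (km2),
#'   `institutions`, `beds`, `health_workers` (counts), `visits_avg`
#'   (visits/person/year) and `hosp_rate` (percent).
#' @return the validated data frame with class `resource_panel` and
#'   attributes `years`, `provinces` and `balanced`.
#' @export
resource_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(.panel_required, names(df))
  if (length(missing) > 0) {
    stop("panel is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(.panel_required, c("province", "region"))
  num_cols <- c(num_cols, intersect(.panel_split_cols, names(df)))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in column '%s' at row %d", cl, bad[1]),
             call. = FALSE)
      }
      df[[cl]] <- conv
    }
  }
  df$province <- as.character(df$province)
  df$region <- as.character(df$region)
  df$year <- as.integer(df$year)

  key <- paste(df$province, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate record for province '%s', year %d",
                 d$province, d$year), call. = FALSE)
  }
  if (any(df$population <= 0)) stop("population must be > 0", call. = FALSE)
  if (any(df$area <= 0)) stop("area must be > 0", call. = FALSE)
  for (r in .panel_resources) {
    if (any(df[[r]] < 0)) stop(r, " must be >= 0", call. = FALSE)
  }
  for (f in .panel_split_fields) {
    u <- paste0(f, "_urban")
    rr <- paste0(f, "_rural")
    if (u %in% names(df) && rr %in% names(df)) {
      gap <- abs(df[[u]] + df[[rr]] - df[[f]])
      tol <- if (f == "population") 1e-6 * pmax(df[[f]], 1) else 0.5
      if (any(gap > tol)) {
        stop(sprintf("urban + rural does not equal total for '%s'", f),
             call. = FALSE)
      }
    }
  }

  years <- sort(unique(df$year))
  provinces <- sort(unique(df$province))
  tab <- table(df$province)
  balanced <- length(df$year) == length(years) * length(provinces) &&
    all(tab == length(years))
  attr(df, "years") <- years
  attr(df, "provinces") <- provinces
  attr(df, "balanced") <- balanced
  class(df) <- c("resource_panel", "data.frame")
  df
}

#' @export
print.resource_panel <- function(x, ...) {
  cat(sprintf("resource_panel: %d provinces x %d years (%s)%s\n",
              length(attr(x, "provinces")), length(attr(x, "years")),
              paste(range(attr(x, "years")), collapse = "-"),
              if (attr(x, "balanced")) ", balanced" else ", UNBALANCED"))
  print(as.data.frame(head(x, 6)))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a resource panel from CSV
#'
#' @param path CSV file, one row per (province, year), UTF-8.
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(health_workers = "staff_total")`. Unmapped canonical names are looked
#'   up verbatim.
#' @param region_levels optional character vector of admissible region labels;
#'   defaults to `c("east", "central", "west")`. Use `NULL` to accept any.
#' @return a [resource_panel()].
#' @export
read_panel <- function(path, col_map = NULL,
                       region_levels = c("east", "central", "west")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' not present in file", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing <- setdiff(.panel_required, names(raw))
  if (length(missing) > 0) {
    stop("CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(region_levels)) {
    reg <- tolower(trimws(raw$region))
    bad <- setdiff(unique(reg), region_levels)
    if (length(bad) > 0) {
      stop("unknown region label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    raw$region <- reg
  }
  resource_panel(raw)
}

#' Write a resource panel to CSV
#'
#' @param panel a [resource_panel()].
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Subset one year of a panel
#' @param panel a [resource_panel()].
#' @param year calendar year present in the panel.
#' @return data frame of that year's records, ordered by province.
#' @export
panel_year <- function(panel, year) {
  if (!year %in% attr(panel, "years")) {
    stop("year ", year, " not present in panel", call. = FALSE)
  }
  out <- as.data.frame(panel[panel$year == year, , drop = FALSE])
  out[order(out$province), , drop = FALSE]
}

# region partitions ----------------------------------------------------------

#' Define a province-to-group partition
#'
#' @param mapping named character vector: names are provinces, values are
#'   group labels. At least two distinct groups are required for a Theil
#'   decomposition.
#' @return object of class `region_partition`.
#' @export
region_partition <- function(mapping) {
  mapping <- unlist(mapping)
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("mapping must be a named vector province -> group", call. = FALSE)
  }
  structure(list(mapping = setNames(as.character(mapping), names(mapping)),
                 groups = sort(unique(as.character(mapping)))),
            class = "region_partition")
}

#' The standard three-region partition of mainland China's 31 provinces
#'
#' The conventional statistical-yearbook grouping into eastern (11), central
#' (8) and western (12) provinces, autonomous regions and municipalities.
#'
#' @return a [region_partition()].
#' @export
china_region_partition <- function() {
  east <- c("Beijing", "Tianjin", "Hebei", "Liaoning", "Shanghai", "Jiangsu",
            "Zhejiang", "Fujian", "Shandong", "Guangdong", "Hainan")
  central <- c("Shanxi", "Jilin", "Heilongjiang", "Anhui", "Jiangxi", "Henan",
               "Hubei", "Hunan")
  west <- c("Inner Mongolia", "Chongqing", "Guangxi", "Sichuan", "Guizhou",
            "Yunnan", "Tibet", "Shaanxi", "Gansu", "Qinghai", "Ningxia",
            "Xinjiang")
  region_partition(c(setNames(rep("east", length(east)), east),
                     setNames(rep("central", length(central)), central),
                     setNames(rep("west", length(west)), west)))
}

#' Partition derived from a panel's own region column
#' @param panel a [resource_panel()].
#' @return a [region_partition()].
#' @export
panel_partition <- function(panel) {
  first <- !duplicated(panel$province)
  region_partition(setNames(panel$region[first], panel$province[first]))
}

# checks a partition against a province set; returns group factor
.partition_groups <- function(partition, provinces) {
  stopifnot(inherits(partition, "region_partition"))
  miss <- setdiff(provinces, names(partition$mapping))
  if (length(miss) > 0) {
    stop("partition does not cover province(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  factor(partition$mapping[provinces], levels = partition$groups)
}
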