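# Synthetic province panels with known inequality and known DEA
# inefficiency, so every downstream stage has a ground-truth recovery test.

#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the structure of the Chinese provincial primary-care
#' panel: 31 provinces in three regions (11 east / 8 central / 12 west),
#' five years, heavy-tailed (log-normal) populations, areas and per-capita
#' resource rates with regional means taken from observed 2012-2016 regional
#' averages, mild annual drift, and a Cobb-Douglas production frontier with
#' input-radial inefficiency drawn from a Beta law. A fixed set of
#' provinces is forced onto the frontier (true efficiency u = 1) in every
#' year, spread across the size distribution so the frontier is spanned.
#'
#' @param n_provinces number of provinces (>= 2).
#' @param n_years number of consecutive years.
#' @param start_year first calendar year.
#' @param seed integer seed; the generator is bit-deterministic given the
#'   full config.
#' @param group_labels region labels, largest to smallest per-km2 density.
#' @param group_shares share of provinces per region (sums to 1).
#' @param population_meanlog,population_sdlog per-group log-normal law for
#'   resident population in thousands.
#' @param area_meanlog,area_sdlog per-group log-normal law for land area in
#'   km2.
#' @param rate_means matrix (3 resources x groups) of mean per-1000-person
#'   rates for institutions, beds and health workers.
#' @param rate_sdlog per-resource log-scale dispersion of the rate laws
#'   (controls the demographic Gini of each resource).
#' @param drift per-resource annual multiplicative growth of per-capita
#'   rates.
#' @param pop_growth annual multiplicative population growth.
#' @param frontier_exponents Cobb-Douglas exponents (a1, a2, a3) on
#'   institutions, beds, health workers; their sum sets returns to scale
#'   (< 1 decreasing, = 1 constant).
#' @param frontier_ref reference input bundle normalising the frontier.
#' @param o1_scale frontier level of the first output (average visits).
#' @param o2_mode `"logistic"` squashes the second output (hospitalization
#'   rate, percent) into (0, o2_max) as a logistic function of the first;
#'   `"proportional"` sets it to `o2_prop * O1` (keeps the frontier
#'   homogeneous for constant-returns recovery studies).
#' @param o2_max,o2_b0,o2_b1,o2_prop parameters of the two modes.
#' @param u_shape1,u_shape2 Beta law for true input efficiency u in (0, 1].
#' @param n_frontier_dmus provinces forced to u = 1 in every year.
#' @param urban_split generate urban/rural split columns?
#' @return object of class `simulation_config` (a list).
#' @export
simulation_config <- function(
    n_provinces = 31L, n_years = 5L, start_year = 2012L, seed = 1L,
    group_labels = c("east", "central", "west"),
    group_shares = c(11, 8, 12) / 31,
    population_meanlog = log(c(48000, 45000, 22000)),
    population_sdlog = c(0.55, 0.45, 0.80),
    area_meanlog = log(c(120000, 180000, 420000)),
    area_sdlog = c(0.80, 0.45, 0.70),
    rate_means = rbind(institutions = c(0.588, 0.690, 0.786),
                       beds = c(0.804, 1.114, 1.218),
                       health_workers = c(2.553, 2.616, 2.680)),
    rate_sdlog = c(institutions = 0.34, beds = 0.32, health_workers = 0.13),
    drift = c(institutions = 0.999, beds = 1.016, health_workers = 1.012),
    pop_growth = 1.005,
    frontier_exponents = c(0.32, 0.16, 0.32),
    frontier_ref = c(30000, 45000, 120000),
    o1_scale = 6,
    o2_mode = c("logistic", "proportional"),
    o2_max = 7, o2_b0 = -1.4, o2_b1 = 0.9, o2_prop = 0.9,
    u_shape1 = 2, u_shape2 = 2.5,
    n_frontier_dmus = 5L,
    urban_split = TRUE) {
  o2_mode <- match.arg(o2_mode)
  k <- length(group_labels)
  stopifnot(n_provinces >= 2, n_years >= 1, k >= 1,
            length(group_shares) == k,
            abs(sum(group_shares) - 1) < 1e-8,
            all(frontier_exponents >= 0),
            nrow(rate_means) == 3, ncol(rate_means) == k,
            n_frontier_dmus >= 0, n_frontier_dmus <= n_provinces)
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# real province names when the default size is used, else synthetic names
.province_names <- function(cfg, groups) {
  if (cfg$n_provinces == 31L &&
      identical(cfg$group_labels, c("east", "central", "west"))) {
    part <- china_region_partition()$mapping
    unlist(lapply(cfg$group_labels,
                  function(g) sort(names(part)[part == g])),
           use.names = FALSE)
  } else {
    paste0("P", formatC(seq_len(cfg$n_provinces), width = 3, flag = "0"),
           "_", groups)
  }
}

#' Simulate a balanced province panel with known ground truth
#'
#' For each province, population and area are drawn from per-group
#' log-normal laws and per-capita resource rates from per-resource
#' per-group log-normal laws; rates drift multiplicatively each year.
#' Observed inputs are `x = population * rate * drift^t` (rounded counts).
#' True efficiency `u` is drawn per province-year (Beta law), frontier
#' provinces get `u = 1`; the efficient bundle is `x* = u * x` (input-radial
#' inefficiency, matching the input-oriented DEA model exactly) and outputs
#' sit on the Cobb-Douglas frontier evaluated at `x*`, so the recorded `u`
#' is exactly the radial distance of the observation to the true frontier.
#'
#' @param config a [simulation_config()].
#' @return list with `panel` (a [resource_panel()]), `truth` (data frame of
#'   province, year, group and true efficiency `u`), `group_rates` (the
#'   generating per-group mean rates) and `config`.
#' @export
simulate_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  k <- length(config$group_labels)
  sizes <- diff(round(cumsum(c(0, config$group_shares)) * config$n_provinces))
  sizes[k] <- config$n_provinces - sum(sizes[-k])
  if (any(sizes < 1)) stop("every group needs at least one province",
                           call. = FALSE)
  grp_idx <- rep(seq_len(k), sizes)
  groups <- config$group_labels[grp_idx]
  provinces <- .province_names(config, groups)
  n <- config$n_provinces

  pop0 <- rlnorm(n, config$population_meanlog[grp_idx],
                 config$population_sdlog[grp_idx])
  area <- rlnorm(n, config$area_meanlog[grp_idx],
                 config$area_sdlog[grp_idx])
  # base per-1000-person rates; meanlog chosen so the mean matches rate_means
  res_names <- rownames(config$rate_means)
  rate0 <- sapply(seq_along(res_names), function(r) {
    s <- config$rate_sdlog[r]
    if (s <= 0) {
      warning("degenerate (zero-variance) rate law for ", res_names[r],
              "; dispersion-recovery tests will be vacuous", call. = FALSE)
      s <- 0
    }
    mu <- log(config$rate_means[r, grp_idx]) - s^2 / 2
    rlnorm(n, mu, s)
  })
  colnames(rate0) <- res_names

  # frontier provinces: spread across the population-size order
  nf <- config$n_frontier_dmus
  frontier <- character(0)
  if (nf > 0) {
    ord <- order(pop0)
    pick <- ord[unique(round(seq(1, n, length.out = nf)))]
    frontier <- provinces[pick]
  }

  # urban split fractions per province (constant mix, drifting urban pop)
  if (config$urban_split) {
    urb_pop0 <- runif(n, 0.40, 0.70)
    urb_frac <- cbind(institutions = plogis(qnorm(runif(n)) * 0.3 + qnorm(0.15)),
                      beds = plogis(qnorm(runif(n)) * 0.3 + qnorm(0.11)),
                      health_workers = plogis(qnorm(runif(n)) * 0.3 + qnorm(0.24)))
  }

  a <- config$frontier_exponents
  rows <- vector("list", config$n_years * n)
  truth <- vector("list", config$n_years * n)
  idx <- 0L
  for (t in seq_len(config$n_years) - 1L) {
    year <- config$start_year + t
    pop <- pop0 * config$pop_growth^t
    u <- pmin(pmax(rbeta(n, config$u_shape1, config$u_shape2), 0.02), 1)
    u[provinces %in% frontier] <- 1
    X <- sapply(res_names, function(r) {
      pmax(round(pop * rate0[, r] * config$drift[r]^t), 1)
    })
    xstar <- X * u
    g <- exp((log(xstar) - matrix(log(config$frontier_ref), n, 3,
                                  byrow = TRUE)) %*% a)[, 1]
    o1 <- config$o1_scale * g
    o2 <- if (config$o2_mode == "logistic") {
      config$o2_max * plogis(config$o2_b0 + config$o2_b1 * log(o1))
    } else {
      config$o2_prop * o1
    }
    df <- data.frame(province = provinces, region = groups, year = year,
                     population = pop, area = area,
                     institutions = X[, 1], beds = X[, 2],
                     health_workers = X[, 3],
                     visits_avg = o1, hosp_rate = o2,
                     stringsAsFactors = FALSE)
    if (config$urban_split) {
      us <- pmin(urb_pop0 + 0.01 * t, 0.95)
      df$population_urban <- pop * us
      df$population_rural <- pop - df$population_urban
      for (r in res_names) {
        urb <- round(df[[r]] * urb_frac[, r])
        df[[paste0(r, "_urban")]] <- urb
        df[[paste0(r, "_rural")]] <- df[[r]] - urb
      }
    }
    idx <- idx + 1L
    rows[[idx]] <- df
    truth[[idx]] <- data.frame(province = provinces, year = year,
                               group = groups, u = u,
                               on_frontier = provinces %in% frontier,
                               stringsAsFactors = FALSE)
  }
  panel <- resource_panel(do.call(rbind, rows[seq_len(idx)]))
  list(panel = panel,
       truth = do.call(rbind, truth[seq_len(idx)]),
       group_rates = config$rate_means,
       config = config)
}

#' Tiny hand-written fixture panel for exact-arithmetic tests
#'
#' Four provinces over two years with small integer values. Province
#' `Bravo` is dominated (strictly more of every input, strictly less of
#' every output than `Alpha`), so it can never be DEA-efficient.
#'
#' @return a [resource_panel()] with 8 records.
#' @export
two_point_panel <- function() {
  df <- expand.grid(province = c("Alpha", "Bravo", "Charlie", "Delta"),
                    year = c(2015L, 2016L), stringsAsFactors = FALSE)
  df <- df[order(df$year, df$province), ]
  df$region <- rep(c("east", "east", "west", "west"), 2)
  df$population <- rep(c(1000, 1000, 2000, 500), 2)
  df$area <- rep(c(1000, 2000, 4000, 8000), 2)
  base <- data.frame(institutions = c(100, 200, 150, 50),
                     beds = c(200, 400, 300, 100),
                     health_workers = c(400, 800, 600, 200),
                     visits_avg = c(4, 3, 5, 2),
                     hosp_rate = c(4, 3, 5, 2))
  grow <- data.frame(institutions = c(110, 210, 160, 55),
                     beds = c(220, 420, 330, 110),
                     health_workers = c(440, 840, 660, 220),
                     visits_avg = c(4.4, 3.2, 5.5, 2.2),
                     hosp_rate = c(4.4, 3.2, 5.5, 2.2))
  resource_panel(cbind(df, rbind(base, grow)))
}
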