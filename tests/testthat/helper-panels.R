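# shared builders and independent oracles

# small random balanced panel, independent of the package's own generator
make_random_panel <- function(n_prov = 10, years = 2015:2016, seed = 1) {
  set.seed(seed)
  prov <- paste0("prov", sprintf("%02d", seq_len(n_prov)))
  reg <- sample(c("east", "central", "west"), n_prov, replace = TRUE)
  reg[1:3] <- c("east", "central", "west")  # every group non-empty
  rows <- lapply(years, function(y) {
    data.frame(province = prov, region = reg, year = y,
               population = runif(n_prov, 500, 90000),
               area = runif(n_prov, 1e4, 1e6),
               institutions = round(rlnorm(n_prov, 9, 0.6)) + 1,
               beds = round(rlnorm(n_prov, 10, 0.6)) + 1,
               health_workers = round(rlnorm(n_prov, 11, 0.5)) + 1,
               visits_avg = runif(n_prov, 1, 5),
               hosp_rate = runif(n_prov, 0.1, 6),
               stringsAsFactors = FALSE)
  })
  resource_panel(do.call(rbind, rows))
}

# population-weighted mean-absolute-difference Gini (brute-force double sum)
gini_pairwise_oracle <- function(weights, values) {
  p <- weights / sum(weights)
  r <- values / weights
  mu <- sum(p * r)
  sum(outer(p, p) * abs(outer(r, r, "-"))) / (2 * mu)
}

# input-oriented VRS score for 1-input/1-output data by direct enumeration of
# convex-hull frontier segments (singletons and interpolated pairs)
vrs_hull_oracle <- function(x, y, j) {
  x0 <- x[j]
  y0 <- y[j]
  cand <- x[y >= y0 - 1e-12]
  for (i in seq_along(x)) {
    for (k in seq_along(x)) {
      if (y[i] < y0 && y[k] > y0) {
        lam <- (y[k] - y0) / (y[k] - y[i])
        cand <- c(cand, lam * x[i] + (1 - lam) * x[k])
      }
    }
  }
  min(cand) / x0
}

# direct (ungrouped) Theil index from weight and resource vectors
theil_direct <- function(weights, values) {
  P <- weights / sum(weights)
  Y <- values / sum(values)
  sum(P * log(P / Y))
}
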