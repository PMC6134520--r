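# Lorenz/Gini, Theil decomposition and HRDI

make_two_prov <- function(pop, res) {
  resource_panel(data.frame(
    province = c("A", "B"), region = c("east", "west"), year = 2016,
    population = pop, area = c(1, 1), institutions = res, beds = res,
    health_workers = res, visits_avg = 1, hosp_rate = 1))
}

test_that("Gini matches hand evaluations of the trapezoid formula", {
  # equal shares -> 0
  expect_equal(lorenz_gini(make_two_prov(c(1000, 1000), c(50, 50)),
                           2016, "beds", "population")$gini, 0)
  # population shares (0.5, 0.5), resource shares (0, 1) -> 0.5
  # (zero-resource province is fine for Gini; only Theil forbids it)
  g <- lorenz_gini(make_two_prov(c(1000, 1000), c(0, 100)),
                   2016, "beds", "population")
  expect_equal(g$gini, 0.5)
  expect_equal(g$points$x, c(0, 0.5, 1))
  expect_equal(g$points$y, c(0, 0, 1))
  expect_error(lorenz_gini(make_two_prov(c(1, 1), c(0, 0)), 2016, "beds",
                           "population"), "total resource is zero")
})

test_that("Lorenz curve is a valid curve below the diagonal", {
  for (s in 1:10) {
    p <- make_random_panel(n_prov = 31, seed = s)
    for (dm in c("population", "area")) {
      lg <- lorenz_gini(p, 2015, "institutions", dm)
      pts <- lg$points
      expect_equal(pts$x[1], 0)
      expect_equal(pts$y[1], 0)
      expect_equal(pts$x[nrow(pts)], 1)
      expect_equal(pts$y[nrow(pts)], 1)
      expect_true(all(diff(pts$x) >= -1e-12))
      expect_true(all(diff(pts$y) >= -1e-12))
      expect_true(all(pts$y <= pts$x + 1e-12))
      expect_gte(lg$gini, 0)
    }
  }
})

test_that("Gini equals the pairwise mean-absolute-difference oracle", {
  for (s in 1:30) {
    p <- make_random_panel(n_prov = sample(5:31, 1), seed = 100 + s)
    yr <- panel_year(p, 2015)
    for (dm in c("population", "area")) {
      g <- lorenz_gini(p, 2015, "beds", dm)$gini
      o <- gini_pairwise_oracle(yr[[dm]], yr$beds)
      expect_equal(g, o, tolerance = 1e-10)
    }
  }
})

test_that("Gini is scale-invariant and relabeling-invariant", {
  p <- make_random_panel(n_prov = 20, seed = 5)
  g0 <- lorenz_gini(p, 2015, "health_workers", "population")$gini
  df <- as.data.frame(p)
  df$health_workers <- df$health_workers * 1000
  expect_equal(lorenz_gini(resource_panel(df), 2015, "health_workers",
                           "population")$gini, g0, tolerance = 1e-12)
  df2 <- as.data.frame(p)
  df2$province <- paste0("Z", rev(df2$province))
  expect_equal(lorenz_gini(resource_panel(df2), 2015, "health_workers",
                           "population")$gini, g0, tolerance = 1e-12)
})

test_that("gini bands use left-closed intervals", {
  expect_equal(classify_gini(0.0730), "absolute equality")
  expect_equal(classify_gini(0.6176), "severe inequality")
  expect_equal(classify_gini(0.2), "relative equality")
  expect_equal(classify_gini(c(0, 0.19999, 0.3, 0.4, 0.5, 1)),
               c("absolute equality", "absolute equality", "proper equality",
                 "relative inequality", "severe inequality",
                 "severe inequality"))
  expect_error(classify_gini(1.2), "\\[0, 1\\]")
})

test_that("Theil matches the hand value and decomposes exactly", {
  # two equal-population provinces in one group, Y = (0.25, 0.75)
  p <- make_two_prov(c(1000, 1000), c(25, 75))
  df <- as.data.frame(p)
  df$region <- "east"
  p1 <- resource_panel(df)
  td <- theil_decomp(p1, 2016, "beds")
  expect_equal(td$total, 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(td$within, td$total, tolerance = 1e-12)
  expect_equal(td$between, 0, tolerance = 1e-12)

  # perfect equality: Y_i = P_i -> all components zero
  peq <- make_two_prov(c(1000, 3000), c(10, 30))
  tdeq <- theil_decomp(peq, 2016, "beds")
  expect_equal(tdeq$total, 0, tolerance = 1e-12)
  expect_equal(tdeq$within, 0, tolerance = 1e-12)
  expect_true(is.na(tdeq$contrib_within))
})

test_that("Theil decomposition identity holds for arbitrary partitions", {
  for (s in 1:15) {
    p <- make_random_panel(n_prov = sample(6:31, 1), seed = 200 + s)
    yr <- panel_year(p, 2016)
    direct <- theil_direct(yr$population, yr$institutions)
    provs <- attr(p, "provinces")
    parts <- list(
      panel_partition(p),
      region_partition(setNames(rep("all", length(provs)), provs)),
      region_partition(setNames(provs, provs)),  # singletons
      region_partition(setNames(sample(c("g1", "g2", "g3", "g4"),
                                       length(provs), replace = TRUE),
                                provs))
    )
    for (pa in parts) {
      if (any(table(factor(pa$mapping[provs], pa$groups)) == 0)) next
      td <- theil_decomp(p, 2016, "institutions", pa)
      expect_equal(td$within + td$between, td$total, tolerance = 1e-10)
      expect_equal(td$total, direct, tolerance = 1e-10)
      expect_true(all(td$per_group$T_g >= -1e-12))
      if (td$total > 0) {
        expect_equal(td$contrib_within + td$contrib_between, 1,
                     tolerance = 1e-9)
      }
    }
    # 1-group partition: between must vanish; singleton: within must vanish
    td_all <- theil_decomp(p, 2016, "institutions", parts[[2]])
    expect_equal(td_all$between, 0, tolerance = 1e-12)
    td_sing <- theil_decomp(p, 2016, "institutions", parts[[3]])
    expect_equal(td_sing$within, 0, tolerance = 1e-12)
  }
})

test_that("Theil errors name zero-resource provinces and empty groups", {
  p <- make_two_prov(c(1000, 1000), c(0, 100))
  expect_error(theil_decomp(p, 2016, "beds"), "zero resource: A")
  p2 <- make_random_panel(n_prov = 5, seed = 3)
  part <- region_partition(setNames(c(rep("g1", 5), "g2"),
                                    c(attr(p2, "provinces"), "ghost")))
  expect_error(theil_decomp(p2, 2016, "institutions", part), "empty group")
})

test_that("merging identical-rate provinces changes neither Gini nor Theil", {
  for (s in 1:5) {
    p <- make_random_panel(n_prov = 12, seed = 300 + s)
    yr <- panel_year(p, 2015)
    orig <- yr
    # split province 1 into two with the same per-capita and per-km2 rates
    half <- yr[1, ]
    for (cl in c("population", "area", "institutions", "beds",
                 "health_workers")) {
      half[[cl]] <- half[[cl]] * 0.35
      yr[1, cl] <- yr[1, cl] * 0.65
    }
    half$province <- "prov01b"
    split_panel <- resource_panel(rbind(yr, half))
    merged_panel <- resource_panel(orig)
    expect_equal(lorenz_gini(split_panel, 2015, "beds", "population")$gini,
                 lorenz_gini(merged_panel, 2015, "beds", "population")$gini,
                 tolerance = 1e-10)
    part <- panel_partition(split_panel)
    expect_equal(theil_decomp(split_panel, 2015, "beds", part)$total,
                 theil_decomp(merged_panel, 2015, "beds",
                              panel_partition(merged_panel))$total,
                 tolerance = 1e-10)
  }
})

test_that("HRDI is the geometric mean of the two densities", {
  expect_equal(hrdi_index(4, 1), 2)
  expect_equal(hrdi_index(0, 5), 0)
  expect_error(hrdi_index(-1, 1), "non-negative")
  p <- make_random_panel(n_prov = 15, seed = 8)
  h <- hrdi(p, 2015, "beds", "by_region")
  expect_equal(h$hrdi^2, h$per_1000_persons * h$per_km2, tolerance = 1e-12)
  # homogeneity of degree 1 in the resource
  df <- as.data.frame(p)
  df$beds <- df$beds * 9
  h9 <- hrdi(resource_panel(df), 2015, "beds", "by_region")
  expect_equal(h9$hrdi, 9 * h$hrdi, tolerance = 1e-9)
})
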