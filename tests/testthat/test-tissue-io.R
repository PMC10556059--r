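test_that("tissue tables read with per-row validation and missing-value retention", {
  path <- writeTissueFixture(c(
    tissueRow("a"), tissueRow("b", lat = 10, lon = -55), tissueRow("c", lat = 33)
  ))
  tab <- readTissueTable(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "nRejected"), 0L)

  # missing %P retained as NA, not dropped
  path2 <- writeTissueFixture(c(
    tissueRow("a"),
    sub("0.05", "NA", tissueRow("b"))
  ))
  tab2 <- readTissueTable(path2)
  expect_equal(nrow(tab2), 2L)
  expect_true(is.na(tab2$pct_P[2]))

  # out-of-range latitude rejected with a logged reason
  path3 <- writeTissueFixture(c(tissueRow("a"), tissueRow("bad", lat = 95)))
  expect_message(tab3 <- readTissueTable(path3), "rejected 1")
  expect_equal(attr(tab3, "nRejected"), 1L)
  expect_match(attr(tab3, "rejectLog")$reason, "coordinates")

  # schema errors are explicit
  noP <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,latitude", "x,1"), noP)
  expect_error(readTissueTable(noP), "pct_P")
  empty <- writeTissueFixture(character())
  expect_error(readTissueTable(empty), "empty")
})

test_that("region assignment is deterministic, total, and precedence-ordered", {
  scheme <- defaultRegionScheme()
  # oracle: the default regions are axis-aligned boxes
  boxOracle <- function(lon, lat) {
    for (code in scheme$precedence) {
      p <- scheme$regions[[code]]
      if (lon >= min(p[, 1]) && lon <= max(p[, 1]) &&
          lat >= min(p[, 2]) && lat <= max(p[, 2])) {
        return(code)
      }
    }
    "other"
  }
  expect_equal(as.character(assignRegion(-66, 25)), "SS")
  expect_equal(as.character(assignRegion(-52, 9)), "WTA")
  expect_equal(as.character(assignRegion(0, 0)), "other")
  set.seed(11)
  lon <- runif(300, -100, -30)
  lat <- runif(300, -5, 45)
  got <- as.character(assignRegion(lon, lat))
  want <- mapply(boxOracle, lon, lat)
  # ray casting treats right/top edges as exterior; skip exact-boundary points
  onEdge <- lon %in% c(-90, -70, -64, -63, -45, -40) |
    lat %in% c(0, 8, 12, 22, 30, 40)
  expect_equal(got[!onEdge], unname(want[!onEdge]))
  expect_identical(got, as.character(assignRegion(lon, lat)))  # deterministic
  expect_false(anyNA(got))                                     # total
})

test_that("region schemes round-trip through YAML", {
  scheme <- defaultRegionScheme()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    precedence = scheme$precedence,
    regions = lapply(scheme$regions, function(p) {
      list(lon = as.numeric(p[, 1]), lat = as.numeric(p[, 2]))
    })
  ), path)
  rt <- readRegionScheme(path)
  expect_equal(rt$precedence, scheme$precedence)
  pts <- data.frame(lon = c(-66, -52, -80, -50), lat = c(25, 9, 15, 35))
  expect_equal(assignRegion(pts$lon, pts$lat, rt),
               assignRegion(pts$lon, pts$lat, scheme))
})

test_that("elemental ratios convert between weight and molar bases exactly", {
  s <- data.frame(pct_C = 30, pct_N = 1, pct_P = 0.05, as_ug_g = 100)
  w <- elementalRatios(s, "weight")
  m <- elementalRatios(s, "molar")
  expect_equal(w$c_to_n, 30)
  expect_equal(w$as_to_p, (100 / 1e4) / 0.05)       # 0.2
  expect_equal(m$c_to_n, (30 / 12.011) / (1 / 14.007))  # ~34.98
  # exact interconversion via atomic masses
  expect_equal(m$c_to_n * 12.011 / 14.007, w$c_to_n, tolerance = 1e-12)
  expect_equal(m$as_to_p * 74.922 / 30.974, w$as_to_p, tolerance = 1e-12)
  # undefined-ratio flag, not an exception
  s0 <- data.frame(pct_C = 30, pct_N = 0, pct_P = NA, as_ug_g = 100)
  r0 <- elementalRatios(s0)
  expect_true(is.na(r0$c_to_n) && is.na(r0$as_to_p))
})

test_that("group summaries report n/mean/SD and recover generator means", {
  s <- data.frame(
    region = rep(c("A", "B"), each = 4), pct_N = c(rep(2, 4), rep(5, 4)),
    stringsAsFactors = FALSE
  )
  out <- summarizeByGroup(s, groupKeys = "region", variables = "pct_N")
  expect_equal(out$mean, c(2, 5))
  expect_equal(out$sd, c(0, 0))
  expect_equal(out$n, c(4L, 4L))

  tab <- genTissueDataset(tissueGenConfig(seed = 3L))
  summ <- summarizeByGroup(tab, groupKeys = "region", variables = "pct_N")
  cfg <- tissueGenConfig()
  for (i in seq_len(nrow(summ))) {
    reg <- as.character(summ$region[i])
    truth <- cfg$region_offsets[[reg]]$meanN
    se <- summ$sd[i] / sqrt(summ$n[i])
    expect_lt(abs(summ$mean[i] - truth), 3 * se + 1e-9)
  }
})

test_that("group comparisons use labeled Welch tests with Holm follow-ups", {
  set.seed(21)
  s <- data.frame(
    region = rep(c("A", "B"), each = 40),
    pct_P = c(rnorm(40, 0.05, 0.01), rnorm(40, 0.05 + 5 * 0.01, 0.01))
  )
  res <- compareGroups(s, "pct_P", "region")
  expect_true(res$testable)
  expect_match(res$method, "welch")
  expect_lt(res$p_value, 1e-6)                      # 5 SD separation rejects
  expect_lt(res$pairwise$p_holm[1], 1e-6)

  const <- data.frame(region = rep(c("A", "B"), each = 5), pct_P = 1)
  resC <- compareGroups(const, "pct_P", "region")
  expect_equal(resC$pairwise$cohens_d, 0)            # zero effect size

  tiny <- data.frame(region = c("A", "A", "B"), pct_P = c(1, 2, 3))
  expect_false(compareGroups(tiny, "pct_P", "region")$testable)
})

test_that("same-distribution groups are rejected at about the nominal rate", {
  rejections <- vapply(1:60, function(s) {
    set.seed(s)
    d <- data.frame(g = rep(c("A", "B"), each = 50), x = rnorm(100))
    compareGroups(d, "x", "g")$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.15)  # ~5% type-I, generous Monte-Carlo margin
})
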