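test_that("single advective steps match tangent-plane arithmetic", {
  cur <- genField("uniform", u0 = 1, v0 = 0)$field
  cfg <- backtrackConfig(D = 0, windage = 0, dt = 3600, duration = 3600,
                         nParticles = 1L, direction = "forward")
  stp <- stepParticles(-55, 0, 0, cur, NULL, cfg)
  expect_equal(stp$lon - (-55), 3600 / (6371000 * pi / 180), tolerance = 1e-12)
  expect_equal(stp$lat, 0)
  # 2% windage on a 10 m/s northward wind: 720 m per hour
  calm <- genField("uniform", u0 = 0, v0 = 0)$field
  wind <- genField("uniform", u0 = 0, v0 = 10)$field
  cfgW <- backtrackConfig(D = 0, windage = 0.02, dt = 3600, duration = 3600,
                          nParticles = 1L, direction = "forward")
  stpW <- stepParticles(-55, 20, 0, calm, wind, cfgW)
  dy <- (stpW$lat - 20) * pi / 180 * 6371000
  expect_equal(dy, 0.02 * 10 * 3600, tolerance = 1e-9)   # 720 m
  # diffusion-only steps are zero-mean with 2-D variance 4*D*dt
  cfgD <- backtrackConfig(D = 4000, windage = 0, dt = 21600, duration = 21600,
                          nParticles = 1L, direction = "forward")
  set.seed(5)
  n <- 4000
  stpD <- stepParticles(rep(-55, n), rep(20, n), 0, calm, NULL, cfgD)
  dx <- (stpD$lon + 55) * pi / 180 * 6371000 * cos(20 * pi / 180)
  dy <- (stpD$lat - 20) * pi / 180 * 6371000
  expect_lt(abs(mean(dx)), 4 * sd(dx) / sqrt(n))
  expect_equal(mean(dx^2 + dy^2), 4 * 4000 * 21600, tolerance = 0.1)
})

test_that("null dynamics hold particles at the release site", {
  calm <- genField("uniform", u0 = 0, v0 = 0)$field
  st <- data.frame(station_id = "a", longitude = -55, latitude = 25)
  cfg <- backtrackConfig(D = 0, windage = 0, dt = 21600,
                         duration = 60 * 86400, nParticles = 5L)
  ens <- backtrackEnsemble(st, calm, config = cfg)[[1]]
  expect_true(all(trajLon(ens) == -55))
  expect_true(all(trajLat(ens) == 25))
  expect_true(all(trajActive(ens)))
})

test_that("solid-body rotation reproduces the closed-form orbit", {
  gen <- genField("solid_body", domain = c(-60, -50, 10, 20),
                  resolution = 1 / 3, center = c(-55, 15),
                  omega = 2 * pi / (30 * 86400))
  st <- data.frame(station_id = "orb", longitude = -54.1, latitude = 15)
  cfg <- backtrackConfig(D = 0, windage = 0, dt = 21600,
                         duration = 30 * 86400, nParticles = 1L,
                         direction = "forward", integrator = "rk4")
  ens <- backtrackEnsemble(st, gen$field, config = cfg)[[1]]
  k <- ncol(trajLon(ens))
  exact <- gen$trajectory(st$longitude, st$latitude, 30 * 86400)
  radius_m <- 0.9 * pi / 180 * 6371000 * cos(15 * pi / 180)
  err_m <- sqrt(((trajLon(ens)[1, k] - exact$lon) * cos(15 * pi / 180))^2 +
                  (trajLat(ens)[1, k] - exact$lat)^2) * pi / 180 * 6371000
  expect_lt(err_m / radius_m, 0.005)
  # radius is conserved along the whole orbit
  r_t <- sqrt(((trajLon(ens)[1, ] + 55) * cos(15 * pi / 180))^2 +
                (trajLat(ens)[1, ] - 15)^2)
  expect_lt(max(abs(r_t / r_t[1] - 1)), 0.005)
  # integrator convergence: halving dt cuts Euler error by ~2x or better
  errAt <- function(dt, integ) {
    cfg2 <- backtrackConfig(D = 0, windage = 0, dt = dt, duration = 10 * 86400,
                            nParticles = 1L, direction = "forward",
                            integrator = integ)
    e <- backtrackEnsemble(st, gen$field, config = cfg2)[[1]]
    kk <- ncol(trajLon(e))
    ex <- gen$trajectory(st$longitude, st$latitude, 10 * 86400)
    sqrt(((trajLon(e)[1, kk] - ex$lon) * cos(15 * pi / 180))^2 +
           (trajLat(e)[1, kk] - ex$lat)^2)
  }
  eulerErr <- c(errAt(43200, "euler"), errAt(21600, "euler"),
                errAt(10800, "euler"))
  expect_gt(eulerErr[1] / eulerErr[2], 1.8)
  expect_gt(eulerErr[2] / eulerErr[3], 1.8)
  expect_lt(errAt(21600, "rk4"), eulerErr[2] / 100)
})

test_that("forward-backward runs are reversible with D = 0", {
  gen <- genField("solid_body", domain = c(-60, -50, 10, 20),
                  resolution = 1 / 3, center = c(-55, 15))
  st <- data.frame(station_id = "f", longitude = -54.3, latitude = 15.4,
                   release_time = 0)
  cfg <- backtrackConfig(D = 0, windage = 0, dt = 21600,
                         duration = 20 * 86400, nParticles = 1L,
                         direction = "forward", integrator = "rk4")
  fwd <- backtrackEnsemble(st, gen$field, config = cfg)[[1]]
  k <- ncol(trajLon(fwd))
  endSt <- data.frame(station_id = "b", longitude = trajLon(fwd)[1, k],
                      latitude = trajLat(fwd)[1, k], release_time = 0)
  cfgB <- backtrackConfig(D = 0, windage = 0, dt = 21600,
                          duration = 20 * 86400, nParticles = 1L,
                          direction = "backward", integrator = "rk4")
  bwd <- backtrackEnsemble(endSt, gen$field, config = cfgB)[[1]]
  expect_equal(trajLon(bwd)[1, k], st$longitude, tolerance = 1e-4)
  expect_equal(trajLat(bwd)[1, k], st$latitude, tolerance = 1e-4)
})

test_that("ensembles are bit-identical under a fixed seed and conserve particles", {
  calm <- genField("uniform", u0 = 0.05, v0 = 0.02)$field
  st <- data.frame(station_id = c("a", "b"),
                   longitude = c(-55, -60), latitude = c(25, 15))
  cfg <- backtrackConfig(D = 2000, windage = 0, dt = 21600,
                         duration = 10 * 86400, nParticles = 20L, seed = 77L)
  e1 <- backtrackEnsemble(st, calm, config = cfg)
  e2 <- backtrackEnsemble(st, calm, config = cfg)
  expect_identical(trajLon(e1$a), trajLon(e2$a))
  expect_identical(trajLat(e1$b), trajLat(e2$b))
  expect_equal(nrow(trajLon(e1$a)), 20L)
  cfg2 <- backtrackConfig(D = 2000, windage = 0, dt = 21600,
                          duration = 10 * 86400, nParticles = 20L, seed = 78L)
  e3 <- backtrackEnsemble(st, calm, config = cfg2)
  expect_false(identical(trajLon(e1$a), trajLon(e3$a)))
})

test_that("beached and out-of-domain particles deactivate and freeze", {
  mask <- matrix(TRUE, 21, 21)
  mask[, 12:21] <- FALSE                      # land north of ~lat 21
  gen <- genField("uniform", domain = c(-60, -40, 10, 30), resolution = 1,
                  u0 = 0, v0 = 0.5, mask = mask)
  st <- data.frame(station_id = "n", longitude = -50, latitude = 19)
  cfg <- backtrackConfig(D = 0, windage = 0, dt = 21600,
                         duration = 20 * 86400, nParticles = 3L,
                         direction = "forward")
  ens <- backtrackEnsemble(st, gen$field, config = cfg)[[1]]
  expect_true(all(ens@reason == "beached"))
  k <- ncol(trajLon(ens))
  frozen <- trajLon(ens)[, k] == trajLon(ens)[, k - 1] &
    trajLat(ens)[, k] == trajLat(ens)[, k - 1]
  expect_true(all(frozen))
  expect_false(any(trajActive(ens)[, k]))
  # out of domain: eastward flow exits the box
  gen2 <- genField("uniform", domain = c(-60, -50, 10, 30), resolution = 1,
                   u0 = 1.5, v0 = 0)
  st2 <- data.frame(station_id = "e", longitude = -51, latitude = 20)
  ens2 <- backtrackEnsemble(st2, gen2$field, config = cfg)[[1]]
  expect_true(all(ens2@reason == "out-of-domain"))
  # a station on land is skipped with a message, not silently dropped
  stLand <- data.frame(station_id = "land", longitude = -50, latitude = 28)
  expect_message(res <- backtrackEnsemble(stLand, gen$field, config = cfg),
                 "skipped")
  expect_equal(attr(res, "skipped"), "land")
})

test_that("centroids average actives only and handle the dateline", {
  calm <- genField("uniform", u0 = 0, v0 = 0)$field
  st <- data.frame(station_id = "c", longitude = -55, latitude = 25)
  cfg <- backtrackConfig(D = 0, windage = 0, dt = 21600, duration = 2 * 86400,
                         nParticles = 4L)
  ens <- backtrackEnsemble(st, calm, config = cfg)[[1]]
  ctr <- ensembleCentroid(ens)
  expect_equal(ctr$lon, rep(-55, nrow(ctr)))
  expect_equal(ctr$n_active, rep(4L, nrow(ctr)))
  # symmetric pair averages to the midpoint; dateline straddle -> 180 not 0
  ens@lon[, ] <- rep(c(179.5, -179.5, 179.8, -179.8), ncol(ens@lon))
  ens@lat[, ] <- rep(c(10, 10, 12, 12), ncol(ens@lat))
  ctr2 <- ensembleCentroid(ens)
  expect_lt(abs(abs(ctr2$lon[1]) - 180), 1e-9)
  expect_equal(ctr2$lat[1], 11)
})

test_that("diffusivity is recovered from quiescent ensembles", {
  calm <- quiescentField()
  st <- data.frame(station_id = "d", longitude = -55, latitude = 25)
  cfg <- backtrackConfig(D = 4000, windage = 0, dt = 21600,
                         duration = 30 * 86400, nParticles = 400L, seed = 3L)
  ens <- backtrackEnsemble(st, calm, config = cfg)[[1]]
  dMsd <- estimateDiffusivity(ens, "msd")
  dInc <- estimateDiffusivity(ens, "increments")
  expect_equal(as.numeric(dMsd), 4000, tolerance = 0.15)
  expect_equal(as.numeric(dInc), 4000, tolerance = 0.15)
  expect_equal(as.numeric(dMsd), as.numeric(dInc), tolerance = 0.2)
  # D = 0 gives exactly 0; tiny ensembles warn
  cfg0 <- backtrackConfig(D = 0, windage = 0, dt = 21600,
                          duration = 5 * 86400, nParticles = 5L)
  ens0 <- backtrackEnsemble(st, calm, config = cfg0)[[1]]
  expect_warning(d0 <- estimateDiffusivity(ens0), "fewer than 10")
  expect_equal(as.numeric(d0), 0)
  # MSD grows linearly with slope 4D
  tRel <- abs(trajTimes(ens) - trajTimes(ens)[1])[-1]
  dlon <- trajLon(ens) + 55
  dlat <- trajLat(ens) - 25
  msd <- colMeans((dlon * pi / 180 * 6371000 * cos(25 * pi / 180))^2 +
                    (dlat * pi / 180 * 6371000)^2)[-1]
  fit <- lm(msd ~ tRel)
  expect_equal(unname(coef(fit)[2]), 4 * 4000, tolerance = 0.15)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("windage displacement is linear in the windage factor", {
  calm <- genField("uniform", u0 = 0, v0 = 0)$field
  st <- data.frame(station_id = "w", longitude = -55, latitude = 20)
  drift <- function(w, wind) {
    cfg <- backtrackConfig(D = 0, windage = w, dt = 21600,
                           duration = 5 * 86400, nParticles = 1L,
                           direction = "forward")
    ens <- backtrackEnsemble(st, calm, winds = wind, config = cfg)[[1]]
    k <- ncol(trajLon(ens))
    c(trajLon(ens)[1, k] + 55, trajLat(ens)[1, k] - 20)
  }
  # zonal wind keeps latitude (and the metre/degree factor) constant: exact
  zonal <- genField("uniform", u0 = 6, v0 = 0)$field
  expect_equal(drift(0.04, zonal), 2 * drift(0.02, zonal), tolerance = 1e-12)
  # meridional drift is exact in latitude regardless of the factor
  merid <- genField("uniform", u0 = 0, v0 = 8)$field
  expect_equal(drift(0.04, merid)[2], 2 * drift(0.02, merid)[2],
               tolerance = 1e-12)
})

test_that("trajectories round-trip through CSV and export valid GeoJSON", {
  calm <- genField("uniform", u0 = 0.1, v0 = 0.05)$field
  st <- data.frame(station_id = c("a", "b"),
                   longitude = c(-55, -58), latitude = c(25, 20))
  cfg <- backtrackConfig(D = 1000, windage = 0, dt = 21600,
                         duration = 5 * 86400, nParticles = 7L, seed = 9L)
  ens <- backtrackEnsemble(st, calm, config = cfg)
  path <- tempfile(fileext = ".csv")
  writeTrajectories(ens, path, "csv")
  rt <- readTrajectories(path)
  expect_equal(trajLon(rt$a), trajLon(ens$a), ignore_attr = TRUE)
  expect_equal(trajLat(rt$b), trajLat(ens$b), ignore_attr = TRUE)
  expect_equal(trajActive(rt$a), trajActive(ens$a), ignore_attr = TRUE)
  expect_equal(trajConfig(rt$a)@seed, 9L)
  # CSV row count = stations x particles x saved steps
  rows <- read.csv(path, comment.char = "#")
  expect_equal(nrow(rows), 2 * 7 * ncol(trajLon(ens$a)))
  # GeoJSON: one LineString per particle plus one centroid per station
  gj <- tempfile(fileext = ".geojson")
  writeTrajectories(ens, gj, "geojson")
  parsed <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  expect_equal(parsed$type, "FeatureCollection")
  roles <- vapply(parsed$features, function(f) f$properties$role, "")
  expect_equal(sum(roles == "trajectory"), 14L)
  expect_equal(sum(roles == "centroid"), 2L)
  expect_error(writeTrajectories(ens, tempfile(), "netcdf"))
})
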