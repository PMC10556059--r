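# Synthetic inputs: tissue tables with known power-law As:P structure,
# analytic velocity fields with closed-form trajectories, station lists.

#' Configuration for the synthetic tissue-table generator
#'
#' The generator emulates the schema and statistical structure of the real
#' tissue survey: log-uniform \%P, a power-law As:P versus \%P relation with
#' multiplicative lognormal noise, regional offsets in \%N, \%P and
#' delta-15N (the belt populations are N- and P-enriched relative to the
#' Sargasso Sea; the northern Sargasso Sea carries the heaviest delta-15N),
#' and an era/region/species factor design whose default sample sizes are
#' 200 (2021 survey), 20 (1983-1987) and 21 (2015-2018).
#'
#' @param groups data.frame with columns \code{era}, \code{region},
#'   \code{species}, \code{n}; defaults to the survey design above.
#' @param b_true true exponent of As:P versus \%P (default -1.3).
#' @param a_true true intercept, log10 of the weight-basis As:P at
#'   \%P = 1 (default -2.4, giving arsenic contents of order 30-150 ug/g
#'   over the default \%P range).
#' @param pP_range \%P sampling range, log-uniform (default 0.01-0.3 percent
#'   dry weight).
#' @param noise_sd lognormal noise SD of the As:P ratio, log10 units
#'   (default 0.15).
#' @param region_offsets named list per region with components
#'   \code{logP} (log10 \%P shift), \code{meanN} (\%N mean) and
#'   \code{d15N} (permil mean).
#' @param seed integer seed.
#' @return validated config list for [genTissueDataset()].
#' @export
tissueGenConfig <- function(groups = NULL, b_true = -1.3, a_true = -2.4,
                            pP_range = c(0.01, 0.3), noise_sd = 0.15,
                            region_offsets = NULL, seed = 1L) {
  if (is.null(groups)) {
    groups <- rbind(
      expand.grid(era = "y2021",
                  region = c("NSS", "SS", "WTA", "CAR"),
                  species = c("S_fluitans_III", "S_natans_I"),
                  stringsAsFactors = FALSE),
      expand.grid(era = "y1983_1987", region = "SS",
                  species = c("S_fluitans_III", "S_natans_I"),
                  stringsAsFactors = FALSE),
      expand.grid(era = "y2015_2018", region = c("WTA", "CAR"),
                  species = "S_fluitans_III", stringsAsFactors = FALSE)
    )
    # era totals 200 / 20 / 21
    groups$n <- c(rep(25L, 8L), rep(10L, 2L), 11L, 10L)
  }
  if (is.null(region_offsets)) {
    region_offsets <- list(
      NSS = list(logP = -0.20, meanN = 0.8, d15N = 2.0),
      SS  = list(logP = -0.25, meanN = 0.7, d15N = -1.0),
      WTA = list(logP = 0.15, meanN = 1.2, d15N = -0.5),
      CAR = list(logP = 0.15, meanN = 1.2, d15N = -0.5),
      other = list(logP = 0, meanN = 1.0, d15N = 0)
    )
  }
  stopifnot(
    all(c("era", "region", "species", "n") %in% names(groups)),
    all(groups$n >= 1), length(pP_range) == 2, all(pP_range > 0),
    pP_range[1] < pP_range[2], noise_sd >= 0
  )
  list(groups = groups, b_true = b_true, a_true = a_true,
       pP_range = pP_range, noise_sd = noise_sd,
       region_offsets = region_offsets, seed = as.integer(seed))
}

# Sampling boxes per region, matching the default region scheme but inset so
# generated points assign unambiguously.
.REGION_SAMPLE_BOX <- list(
  NSS = c(-68, -47, 30.5, 39),
  SS  = c(-68, -47, 22.5, 29.5),
  CAR = c(-88, -65, 9, 21),
  WTA = c(-63, -42, 1, 11.5),
  other = c(-40, -20, 41, 50)
)
.ERA_DATE <- c(y2021 = "2021-04-15", y1983_1987 = "1985-07-01",
               y2015_2018 = "2016-07-01")

#' Generate a synthetic tissue table
#'
#' Draws \%P log-uniform over the configured range (shifted per region in
#' log10 space), computes the weight-basis As:P ratio as
#' \code{10^(a_true + b_true * log10(pP))} times lognormal noise, converts to
#' arsenic in ug per g dry weight, and draws \%C, \%N and delta-15N with the
#' configured regional structure. Deterministic under the config seed; the
#' output uses exactly the tissue CSV schema of [readTissueTable()].
#'
#' @param config output of [tissueGenConfig()].
#' @return data.frame in the tissue-table schema (with an informative
#'   \code{region} column appended; [readTissueTable()] ignores it).
#' @export
genTissueDataset <- function(config = tissueGenConfig()) {
  set.seed(childSeed(config$seed, "tissue-table"))
  groups <- config$groups
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    n <- groups$n[g]
    region <- groups$region[g]
    era <- groups$era[g]
    off <- config$region_offsets[[region]] %||%
      list(logP = 0, meanN = 1, d15N = 0)
    lp <- runif(n, log10(config$pP_range[1]), log10(config$pP_range[2])) +
      off$logP
    pP <- 10^lp
    asp <- 10^(config$a_true + config$b_true * log10(pP) +
                 rnorm(n, 0, config$noise_sd))
    box <- .REGION_SAMPLE_BOX[[region]] %||% c(-60, -50, 20, 30)
    data.frame(
      sample_id = sprintf("%s_%s_%s_%03d", era, region, groups$species[g],
                          seq_len(n)),
      cruise = if (era == "y2021") sample(c("A20", "A22"), n, TRUE)
               else "historic",
      station_id = sprintf("%s_%s_st%02d", era, region,
                           sample.int(max(2L, n %/% 3L), n, TRUE)),
      latitude = runif(n, box[3], box[4]),
      longitude = runif(n, box[1], box[2]),
      date = .ERA_DATE[[era]],
      species = groups$species[g],
      replicate = sample.int(3L, n, TRUE),
      pct_C = rnorm(n, 30, 3),
      pct_N = pmax(0.05, rnorm(n, off$meanN, 0.15)),
      pct_P = pP,
      d15N = rnorm(n, off$d15N, 0.5),
      as_ug_g = asp * pP * 1e4,
      era = era,
      region = region,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate an analytic velocity field
#'
#' Three field kinds for validating the tracker against closed forms:
#' \describe{
#'   \item{uniform}{\code{u = u0, v = v0} everywhere; exact trajectory is a
#'     straight tangent-plane displacement.}
#'   \item{solid_body}{rotation at angular rate \code{omega} (rad/s) about
#'     \code{center}; velocities are defined on the tangent plane anchored at
#'     the center, so the exact trajectory is a circle in those coordinates.}
#'   \item{gyre}{a single sinusoidal recirculation cell over the domain
#'     (amplitude \code{u0}); no closed form is returned.}
#' }
#'
#' @param kind "uniform", "solid_body" or "gyre".
#' @param domain numeric \code{c(lonmin, lonmax, latmin, latmax)}.
#' @param resolution grid spacing, degrees (default 1/3).
#' @param times time grid (s), default a single steady slice.
#' @param u0,v0 uniform components or gyre amplitude (m/s).
#' @param center \code{c(lon, lat)} rotation center for solid_body.
#' @param omega angular rate for solid_body (rad/s).
#' @param mask optional logical mask (water TRUE) to overlay.
#' @return list with \code{field} (a [GriddedField-class]) and
#'   \code{trajectory}: for uniform and solid_body, a function
#'   \code{(lon0, lat0, elapsed)} returning the exact position after
#'   \code{elapsed} seconds of forward advection (NULL for gyre).
#' @export
genField <- function(kind = c("uniform", "solid_body", "gyre"),
                     domain = c(-75, -40, 0, 40), resolution = 1 / 3,
                     times = 0, u0 = 0.1, v0 = 0, center = NULL,
                     omega = 2 * pi / (30 * 86400), mask = NULL) {
  kind <- match.arg(kind)
  lon <- seq(domain[1], domain[2], by = resolution)
  lat <- seq(domain[3], domain[4], by = resolution)
  nlon <- length(lon); nlat <- length(lat); nt <- length(times)
  if (kind == "gyre" && (nlon < 9 || nlat < 9)) {
    stop("grid too coarse to resolve the gyre (need >= 8 nodes per wavelength)")
  }
  mkArr <- function(m) array(rep(m, nt), dim = c(nlon, nlat, nt))
  if (kind == "uniform") {
    u <- mkArr(matrix(u0, nlon, nlat))
    v <- mkArr(matrix(v0, nlon, nlat))
    traj <- function(lon0, lat0, elapsed) {
      d <- metersToDegrees(u0 * elapsed, v0 * elapsed, lat0)
      list(lon = lon0 + d$dlon, lat = lat0 + d$dlat)
    }
  } else if (kind == "solid_body") {
    if (is.null(center)) center <- c(mean(domain[1:2]), mean(domain[3:4]))
    cosc <- cos(center[2] * .DEG2RAD)
    x <- .R_EARTH * cosc * .DEG2RAD * outer(lon - center[1], rep(1, nlat))
    y <- .R_EARTH * .DEG2RAD * outer(rep(1, nlon), lat - center[2])
    # the zonal component carries the local cos(lat)/cos(lat_c) metric factor
    # so the tangent-plane circle solves the spherical advection equations
    # exactly, making the returned closed form a true trajectory oracle
    metric <- outer(rep(1, nlon), cos(lat * .DEG2RAD) / cosc)
    u <- mkArr(-omega * y * metric)
    v <- mkArr(omega * x)
    traj <- function(lon0, lat0, elapsed) {
      x0 <- .R_EARTH * cosc * .DEG2RAD * (lon0 - center[1])
      y0 <- .R_EARTH * .DEG2RAD * (lat0 - center[2])
      th <- omega * elapsed
      xt <- x0 * cos(th) - y0 * sin(th)
      yt <- x0 * sin(th) + y0 * cos(th)
      list(lon = center[1] + xt / (.R_EARTH * cosc * .DEG2RAD),
           lat = center[2] + yt / (.R_EARTH * .DEG2RAD))
    }
  } else {
    px <- (outer(lon, rep(1, nlat)) - domain[1]) / (domain[2] - domain[1])
    py <- (outer(rep(1, nlon), lat) - domain[3]) / (domain[4] - domain[3])
    u <- mkArr(-u0 * sin(pi * px) * cos(pi * py))
    v <- mkArr(u0 * cos(pi * px) * sin(pi * py))
    traj <- NULL
  }
  if (!is.null(mask)) {
    u[array(rep(!mask, nt), dim = dim(u))] <- NA_real_
    v[array(rep(!mask, nt), dim = dim(v))] <- NA_real_
  }
  field <- griddedField(lon, lat, times, u, v, mask = mask)
  list(field = field, trajectory = traj)
}

#' Generate a station list
#'
#' Uniform random release sites inside a lon/lat box, reproducible under the
#' seed. The default box spans the survey's transect region (70-52W,
#' 8-38N).
#'
#' @param n number of stations (0 gives a valid empty table).
#' @param box numeric \code{c(lonmin, lonmax, latmin, latmax)}.
#' @param seed integer seed.
#' @param release_time optional release time (s) recorded per station.
#' @return data.frame with columns \code{station_id}, \code{longitude},
#'   \code{latitude} (and \code{release_time} when given).
#' @export
genStations <- function(n, box = c(-70, -52, 8, 38), seed = 1L,
                        release_time = NULL) {
  set.seed(childSeed(seed, "stations"))
  out <- data.frame(
    station_id = if (n > 0) sprintf("st%03d", seq_len(n)) else character(),
    longitude = runif(n, box[1], box[2]),
    latitude = runif(n, box[3], box[4]),
    stringsAsFactors = FALSE
  )
  if (!is.null(release_time)) out$release_time <- rep(release_time, n)
  out
}
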