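# Lagrangian particle tracking: advection by currents + windage with
# random-walk horizontal diffusion, forward or backward in time.

configToList <- function(cfg) {
  list(
    D = cfg@D, windage = cfg@windage, dt = cfg@dt, duration = cfg@duration,
    n_particles = cfg@nParticles, direction = cfg@direction, seed = cfg@seed,
    integrator = cfg@integrator, sigma_scheme = cfg@sigmaScheme,
    save_stride = cfg@saveStride
  )
}

listToConfig <- function(x) {
  backtrackConfig(
    D = x$D, windage = x$windage, dt = x$dt, duration = x$duration,
    nParticles = x$n_particles, direction = x$direction, seed = x$seed,
    integrator = x$integrator, sigmaScheme = x$sigma_scheme,
    saveStride = x$save_stride
  )
}

# Advective velocity (currents + windage * wind) at points, m/s.
advVelocity <- function(lon, lat, t, currents, winds, windage) {
  cur <- interpCore(currents, lon, lat, t)
  u <- cur$u; v <- cur$v
  if (windage > 0 && !is.null(winds)) {
    w <- interpCore(winds, lon, lat, t)
    u <- u + windage * w$u
    v <- v + windage * w$v
  }
  list(u = u, v = v)
}

# Position derivative in degrees/s for the ODE integrators; dirsign = -1
# reverses advection (and windage) for backward tracking.
posDeriv <- function(lon, lat, t, currents, winds, windage, dirsign) {
  vel <- advVelocity(lon, lat, t, currents, winds, windage)
  cosphi <- cos(lat * .DEG2RAD)
  cosphi[abs(cosphi) < 1e-6] <- NA_real_
  list(
    dlon = dirsign * vel$u / (.R_EARTH * cosphi) / .DEG2RAD,
    dlat = dirsign * vel$v / .R_EARTH / .DEG2RAD
  )
}

#' Advance particles one time step
#'
#' One step of the tracker: advection by the interpolated current plus
#' \code{windage} times the interpolated 10-m wind (both negated for
#' backward runs), then a zero-mean Gaussian random-walk perturbation whose
#' per-component standard deviation is \code{sqrt(2 D dt)} under the default
#' scheme (total 2-D displacement variance \code{4 D dt}). Metre
#' displacements convert to degrees on the local tangent plane
#' (\code{dlat = dy / R}, \code{dlon = dx / (R cos(lat))}, R = 6371 km).
#' Particles stepping onto a masked cell beach; particles leaving the grid
#' or hitting an undefined velocity deactivate with that reason. The caller
#' owns the RNG state (seed it before stepping for reproducibility).
#'
#' @param lon,lat current particle positions (degrees).
#' @param t current time (s).
#' @param currents,winds [GriddedField-class] fields; \code{winds} may be
#'   NULL when \code{windage} is 0.
#' @param config a [BacktrackConfig-class].
#' @return list with \code{lon}, \code{lat} (new positions) and
#'   \code{reason} (character: "" where the step succeeded, else
#'   "beached", "out-of-domain" or "undefined-velocity").
#' @export
stepParticles <- function(lon, lat, t, currents, winds = NULL, config) {
  if (any(abs(cos(lat * .DEG2RAD)) < 1e-6)) {
    stop("particle too close to a pole for tangent-plane stepping")
  }
  dirsign <- if (config@direction == "backward") -1 else 1
  dt <- config@dt
  n <- length(lon)

  if (config@integrator == "euler") {
    d <- posDeriv(lon, lat, t, currents, winds, config@windage, dirsign)
    newLon <- lon + d$dlon * dt
    newLat <- lat + d$dlat * dt
    badVel <- !is.finite(d$dlon) | !is.finite(d$dlat)
  } else {
    h <- dt
    k1 <- posDeriv(lon, lat, t, currents, winds, config@windage, dirsign)
    k2 <- posDeriv(lon + k1$dlon * h / 2, lat + k1$dlat * h / 2,
                   t + dirsign * h / 2, currents, winds, config@windage,
                   dirsign)
    k3 <- posDeriv(lon + k2$dlon * h / 2, lat + k2$dlat * h / 2,
                   t + dirsign * h / 2, currents, winds, config@windage,
                   dirsign)
    k4 <- posDeriv(lon + k3$dlon * h, lat + k3$dlat * h,
                   t + dirsign * h, currents, winds, config@windage, dirsign)
    newLon <- lon + h / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
    newLat <- lat + h / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
    badVel <- !is.finite(newLon) | !is.finite(newLat)
  }

  if (config@D > 0) {
    sdComp <- if (config@sigmaScheme == "total") sqrt(2 * config@D * dt)
              else sqrt(4 * config@D * dt)
    dxy <- metersToDegrees(rnorm(n, 0, sdComp), rnorm(n, 0, sdComp), newLat)
    ok <- is.finite(newLon)
    newLon[ok] <- newLon[ok] + dxy$dlon[ok]
    newLat[ok] <- newLat[ok] + dxy$dlat[ok]
  }

  reason <- rep("", n)
  reason[badVel] <- "undefined-velocity"
  glon <- currents@lon; glat <- currents@lat
  out <- !badVel & (is.na(newLon) | is.na(newLat) |
    normalizeLon(newLon) < glon[1] | normalizeLon(newLon) > glon[length(glon)] |
    newLat < glat[1] | newLat > glat[length(glat)])
  reason[out] <- "out-of-domain"
  okIdx <- which(reason == "")
  if (length(okIdx)) {
    ni <- pmax(1L, pmin(length(glon),
                        round(approx(glon, seq_along(glon),
                                     xout = normalizeLon(newLon[okIdx]),
                                     rule = 2)$y)))
    nj <- pmax(1L, pmin(length(glat),
                        round(approx(glat, seq_along(glat),
                                     xout = newLat[okIdx], rule = 2)$y)))
    beached <- !currents@mask[cbind(ni, nj)]
    reason[okIdx[beached]] <- "beached"
  }
  failed <- reason != ""
  newLon[failed] <- lon[failed]
  newLat[failed] <- lat[failed]
  list(lon = newLon, lat = newLat, reason = reason)
}

#' Track particle ensembles from release sites
#'
#' Releases \code{nParticles} particles at each station and integrates them
#' through the current (and optional wind) field for the configured duration,
#' backward or forward in time. Backward mode negates the advective velocity
#' and steps earlier in time; the random-walk diffusion is applied with the
#' same magnitude each step in either direction. Identical (config, seed)
#' give bit-identical ensembles. Stations outside the field domain at release
#' are skipped with a message, not silently dropped.
#'
#' @param stations data.frame with columns \code{station_id},
#'   \code{longitude}, \code{latitude} and optionally \code{release_time}
#'   (s; defaults to the end of the field's time coverage for backward runs,
#'   the start for forward runs, 0 for steady fields).
#' @param currents a [GriddedField-class] of surface currents.
#' @param winds optional [GriddedField-class] of 10-m winds; required when
#'   \code{windage > 0}.
#' @param config a [BacktrackConfig-class].
#' @return list of [TrajectoryEnsemble-class], one per accepted station;
#'   attribute \code{skipped} lists stations outside the domain.
#' @export
backtrackEnsemble <- function(stations, currents, winds = NULL,
                              config = backtrackConfig()) {
  validObject(config)
  if (config@windage > 0 && is.null(winds)) {
    stop("windage > 0 requires a wind field")
  }
  dirsign <- if (config@direction == "backward") -1 else 1
  steady <- length(currents@time) == 1L
  if (is.null(stations$release_time)) {
    stations$release_time <- if (steady) 0
      else if (dirsign < 0) max(currents@time) else min(currents@time)
  }
  nsteps <- as.integer(round(config@duration / config@dt))
  savedSteps <- unique(c(seq(0L, nsteps, by = config@saveStride), nsteps))

  if (!steady) {
    tEnd <- stations$release_time + dirsign * config@duration
    if (any(pmin(stations$release_time, tEnd) < min(currents@time) - 1e-9) ||
        any(pmax(stations$release_time, tEnd) > max(currents@time) + 1e-9)) {
      stop("field time coverage does not span the tracking interval")
    }
  }

  skipped <- character()
  out <- list()
  for (s in seq_len(nrow(stations))) {
    sid <- as.character(stations$station_id[s])
    lon0 <- normalizeLon(stations$longitude[s])
    lat0 <- stations$latitude[s]
    t0 <- stations$release_time[s]
    probe <- interpCore(currents, lon0, lat0, t0)
    if (!is.finite(probe$u)) {
      message("backtrackEnsemble: station ", sid,
              " outside domain or on land at release; skipped")
      skipped <- c(skipped, sid)
      next
    }
    set.seed(childSeed(config@seed, paste0("station-", sid)))
    n <- config@nParticles
    lon <- rep(lon0, n); lat <- rep(lat0, n)
    reason <- rep("", n)
    nSaved <- length(savedSteps)
    lonM <- matrix(NA_real_, n, nSaved)
    latM <- matrix(NA_real_, n, nSaved)
    actM <- matrix(FALSE, n, nSaved)
    lonM[, 1] <- lon; latM[, 1] <- lat; actM[, 1] <- TRUE
    col <- 1L
    for (k in seq_len(nsteps)) {
      act <- reason == ""
      if (any(act)) {
        t_k <- t0 + dirsign * (k - 1) * config@dt
        stp <- stepParticles(lon[act], lat[act], t_k, currents, winds, config)
        lon[act] <- stp$lon
        lat[act] <- stp$lat
        reason[act] <- stp$reason
      }
      if (k %in% savedSteps) {
        col <- col + 1L
        lonM[, col] <- lon; latM[, col] <- lat
        actM[, col] <- reason == ""
      }
    }
    ens <- new("TrajectoryEnsemble",
      stationId = sid, release = c(lon = lon0, lat = lat0, time = t0),
      times = t0 + dirsign * savedSteps * config@dt,
      lon = lonM, lat = latM, active = actM, reason = reason,
      config = config
    )
    out[[sid]] <- ens
  }
  attr(out, "skipped") <- skipped
  out
}

#' Centroid path of a trajectory ensemble
#'
#' Per-saved-step mean position of the active particles. Longitudes are
#' averaged on the circle: each particle's longitude is unwrapped about the
#' ensemble's vector-mean direction before averaging, so ensembles straddling
#' the dateline average to about 180 degrees, never to 0. The path is
#' truncated at the first step with no active particle.
#'
#' @param ens a [TrajectoryEnsemble-class].
#' @return data.frame with columns \code{time}, \code{lon}, \code{lat},
#'   \code{n_active}.
#' @export
ensembleCentroid <- function(ens) {
  nSaved <- ncol(ens@lon)
  rows <- vector("list", nSaved)
  for (k in seq_len(nSaved)) {
    act <- ens@active[, k]
    if (!any(act)) break
    lons <- ens@lon[act, k]
    lats <- ens@lat[act, k]
    th <- lons * .DEG2RAD
    ref <- atan2(mean(sin(th)), mean(cos(th))) / .DEG2RAD
    dev <- ((lons - ref + 180) %% 360) - 180
    rows[[k]] <- data.frame(
      time = ens@times[k], lon = ref + mean(dev), lat = mean(lats),
      n_active = sum(act)
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Estimate horizontal diffusivity from a quiescent-field ensemble
#'
#' For two-dimensional Fickian diffusion the ensemble mean squared
#' displacement grows as \eqn{MSD(t) = 4 D t}. Given an ensemble tracked with
#' zero currents and wind, the estimator averages \eqn{MSD(t_k)/(4 t_k)} over
#' saved steps ("msd" method) or uses per-step increments
#' (\eqn{mean(\Delta x^2 + \Delta y^2)/(4 \Delta t)}, "increments" method).
#' Degree offsets convert to metres on the tangent plane at the release
#' latitude.
#'
#' @param ens a [TrajectoryEnsemble-class] from a zero-velocity run.
#' @param method "msd" (default) or "increments".
#' @return estimated diffusivity (m^2 s^-1), with attribute \code{method}.
#' @export
estimateDiffusivity <- function(ens, method = c("msd", "increments")) {
  method <- match.arg(method)
  if (nrow(ens@lon) < 10) {
    warning("fewer than 10 particles: diffusivity estimate has wide variance")
  }
  lat0 <- ens@release[["lat"]]
  tRel <- abs(ens@times - ens@times[1])
  dlon <- ((ens@lon - ens@release[["lon"]] + 180) %% 360) - 180
  dlat <- ens@lat - lat0
  m <- degreesToMeters(dlon, dlat, lat0)
  dx <- matrix(m$dx, nrow = nrow(ens@lon))
  dy <- matrix(m$dy, nrow = nrow(ens@lon))
  if (method == "msd") {
    ks <- which(tRel > 0)
    if (!length(ks)) return(structure(0, method = method))
    dHat <- mean(vapply(ks, function(k) {
      mean(dx[, k]^2 + dy[, k]^2) / (4 * tRel[k])
    }, numeric(1)))
  } else {
    nS <- ncol(dx)
    if (nS < 2) return(structure(0, method = method))
    stepDx <- dx[, -1, drop = FALSE] - dx[, -nS, drop = FALSE]
    stepDy <- dy[, -1, drop = FALSE] - dy[, -nS, drop = FALSE]
    dts <- abs(diff(ens@times))
    dHat <- mean(vapply(seq_along(dts), function(k) {
      mean(stepDx[, k]^2 + stepDy[, k]^2) / (4 * dts[k])
    }, numeric(1)))
  }
  structure(dHat, method = method)
}

#' Write and read trajectory ensembles
#'
#' CSV output is a long table (station_id, particle, step, time, lon, lat,
#' active, reason) preceded by one comment line per station carrying the
#' release point and full configuration (including the seed) as JSON, so a
#' write-read round trip is lossless. GeoJSON output is a FeatureCollection
#' with one LineString per particle plus one centroid LineString per station.
#'
#' @param ensembles list of [TrajectoryEnsemble-class] (as returned by
#'   [backtrackEnsemble()]).
#' @param path output file.
#' @param format "csv" or "geojson".
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(ensembles, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# trajectories v1", con)
    for (ens in ensembles) {
      meta <- list(station_id = ens@stationId,
                   release = as.list(ens@release),
                   reason = ens@reason,
                   config = configToList(ens@config))
      writeLines(paste0("# station: ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                        digits = NA)), con)
    }
    rows <- do.call(rbind, lapply(ensembles, function(ens) {
      n <- nrow(ens@lon); k <- ncol(ens@lon)
      data.frame(
        station_id = ens@stationId,
        particle = rep(seq_len(n), times = k),
        step = rep(seq_len(k) - 1L, each = n),
        time = rep(ens@times, each = n),
        lon = as.vector(ens@lon), lat = as.vector(ens@lat),
        active = as.vector(ens@active),
        stringsAsFactors = FALSE
      )
    }))
    write.csv(rows, con, row.names = FALSE, quote = FALSE)
  } else {
    feats <- list()
    for (ens in ensembles) {
      for (p in seq_len(nrow(ens@lon))) {
        feats[[length(feats) + 1L]] <- list(
          type = "Feature",
          properties = list(station_id = ens@stationId, particle = p,
                            role = "trajectory"),
          geometry = list(
            type = "LineString",
            coordinates = lapply(seq_len(ncol(ens@lon)), function(k) {
              c(ens@lon[p, k], ens@lat[p, k])
            })
          )
        )
      }
      ctr <- ensembleCentroid(ens)
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(station_id = ens@stationId, role = "centroid"),
        geometry = list(
          type = "LineString",
          coordinates = lapply(seq_len(nrow(ctr)), function(k) {
            c(ctr$lon[k], ctr$lat[k])
          })
        )
      )
    }
    jsonlite::write_json(
      list(type = "FeatureCollection", features = feats),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path) {
  hdr <- grep("^# station: ", readLines(path), value = TRUE)
  metas <- lapply(sub("^# station: ", "", hdr), jsonlite::fromJSON)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- list()
  for (meta in metas) {
    sid <- meta$station_id
    sub <- df[df$station_id == sid, , drop = FALSE]
    n <- max(sub$particle)
    k <- max(sub$step) + 1L
    ord <- order(sub$step, sub$particle)
    sub <- sub[ord, ]
    out[[sid]] <- new("TrajectoryEnsemble",
      stationId = as.character(sid),
      release = unlist(meta$release),
      times = unique(sub$time),
      lon = matrix(sub$lon, n, k), lat = matrix(sub$lat, n, k),
      active = matrix(sub$active, n, k),
      reason = as.character(meta$reason),
      config = listToConfig(meta$config)
    )
  }
  out
}
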