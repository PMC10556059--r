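#' GriddedField: a gridded surface vector field
#'
#' Holds u and v velocity components (m s^-1) on a lon x lat x time grid,
#' together with a land/missing mask. Longitudes are stored on
#' \code{[-180, 180)} ascending; masked cells are carried as \code{NA} in the
#' component arrays and \code{FALSE} in \code{mask}, and are never substituted
#' by zeros during interpolation.
#'
#' @slot lon ascending numeric vector of grid longitudes (degrees E).
#' @slot lat ascending numeric vector of grid latitudes (degrees N).
#' @slot time ascending numeric vector of grid times (seconds; epoch is the
#'   caller's choice, a single value marks a steady field).
#' @slot u,v numeric arrays, \code{dim = c(nlon, nlat, ntime)}, in m s^-1.
#' @slot mask logical \code{nlon x nlat} matrix, \code{TRUE} where the cell is
#'   water (valid), \code{FALSE} where it is land/missing.
#' @slot units character, velocity units as read ("m s-1").
#' @exportClass GriddedField
setClass("GriddedField",
  representation(
    lon = "numeric", lat = "numeric", time = "numeric",
    u = "array", v = "array", mask = "matrix", units = "character"
  )
)

setValidity("GriddedField", function(object) {
  msg <- character()
  d <- c(length(object@lon), length(object@lat), length(object@time))
  if (!identical(dim(object@u), as.integer(d))) {
    msg <- c(msg, "dim(u) must be (nlon, nlat, ntime)")
  }
  if (!identical(dim(object@v), as.integer(d))) {
    msg <- c(msg, "dim(v) must be (nlon, nlat, ntime)")
  }
  if (is.unsorted(object@lon, strictly = TRUE)) {
    msg <- c(msg, "lon grid must be strictly ascending")
  }
  if (is.unsorted(object@lat, strictly = TRUE)) {
    msg <- c(msg, "lat grid must be strictly ascending")
  }
  if (length(object@time) > 1 && is.unsorted(object@time, strictly = TRUE)) {
    msg <- c(msg, "time grid must be strictly ascending")
  }
  if (!identical(dim(object@mask), as.integer(d[1:2]))) {
    msg <- c(msg, "mask must be nlon x nlat")
  }
  if (any(object@lon < -180 | object@lon >= 180)) {
    msg <- c(msg, "lon must lie in [-180, 180)")
  }
  if (length(msg)) msg else TRUE
})

#' BacktrackConfig: particle-tracking configuration
#'
#' Parameters of the random-walk Lagrangian tracker. The diffusion step adds,
#' each time step, a Gaussian perturbation whose total two-dimensional
#' displacement variance is \eqn{4 D \Delta t} (i.e. variance \eqn{2 D \Delta t}
#' per horizontal component) under the default \code{sigmaScheme = "total"};
#' \code{sigmaScheme = "percomp"} instead puts variance \eqn{4 D \Delta t} on
#' each component, for comparison with codes that read the same formula that
#' way.
#'
#' @slot D horizontal diffusivity, m^2 s^-1 (default 4000).
#' @slot windage dimensionless fraction of the 10-m wind added to the surface
#'   current (default 0.02); must lie in [0, 0.1].
#' @slot dt time step, s (default 21600, i.e. 6 h).
#' @slot duration total tracked time, s; a positive multiple of \code{dt}
#'   (default 60 days).
#' @slot nParticles particles per release site (default 100).
#' @slot direction "backward" or "forward".
#' @slot seed integer master seed.
#' @slot integrator "euler" (fixed-step forward Euler, default) or "rk4".
#' @slot sigmaScheme "total" (default) or "percomp", see above.
#' @slot saveStride save every k-th step (default 1).
#' @exportClass BacktrackConfig
setClass("BacktrackConfig",
  representation(
    D = "numeric", windage = "numeric", dt = "numeric", duration = "numeric",
    nParticles = "integer", direction = "character", seed = "integer",
    integrator = "character", sigmaScheme = "character", saveStride = "integer"
  )
)

setValidity("BacktrackConfig", function(object) {
  msg <- character()
  if (object@D < 0) msg <- c(msg, "D must be >= 0")
  if (object@windage < 0 || object@windage > 0.1) {
    msg <- c(msg, "windage must be in [0, 0.1]")
  }
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  nsteps <- object@duration / object@dt
  if (object@duration <= 0 || abs(nsteps - round(nsteps)) > 1e-9) {
    msg <- c(msg, "duration must be a positive multiple of dt")
  }
  if (object@nParticles < 1L) msg <- c(msg, "nParticles must be >= 1")
  if (!object@direction %in% c("backward", "forward")) {
    msg <- c(msg, "direction must be 'backward' or 'forward'")
  }
  if (!object@integrator %in% c("euler", "rk4")) {
    msg <- c(msg, "integrator must be 'euler' or 'rk4'")
  }
  if (!object@sigmaScheme %in% c("total", "percomp")) {
    msg <- c(msg, "sigmaScheme must be 'total' or 'percomp'")
  }
  if (object@saveStride < 1L) msg <- c(msg, "saveStride must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TrajectoryEnsemble: tracked particles from one release site
#'
#' Positions of all particles of one release, saved every
#' \code{saveStride} steps. Deactivated particles (beached on a masked cell,
#' left the grid domain, or hit an undefined velocity) stay frozen at their
#' last position and are flagged inactive from that step on.
#'
#' @slot stationId release site identifier.
#' @slot release numeric \code{c(lon, lat, time)} of the release.
#' @slot times numeric vector of saved times (s), first element the release
#'   time; decreasing for backward runs.
#' @slot lon,lat numeric matrices, particles x saved steps (degrees).
#' @slot active logical matrix, particles x saved steps.
#' @slot reason character vector per particle: "" while active, else
#'   "beached", "out-of-domain" or "undefined-velocity".
#' @slot config the [BacktrackConfig-class] used.
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  representation(
    stationId = "character", release = "numeric", times = "numeric",
    lon = "matrix", lat = "matrix", active = "matrix",
    reason = "character", config = "BacktrackConfig"
  )
)

setValidity("TrajectoryEnsemble", function(object) {
  msg <- character()
  n <- nrow(object@lon)
  k <- ncol(object@lon)
  if (!identical(dim(object@lat), c(n, k)) ||
      !identical(dim(object@active), c(n, k))) {
    msg <- c(msg, "lon, lat and active must share dimensions")
  }
  if (length(object@times) != k) msg <- c(msg, "times must match saved steps")
  if (length(object@reason) != n) msg <- c(msg, "one reason per particle")
  if (any(!is.finite(object@lon[object@active])) ||
      any(!is.finite(object@lat[object@active]))) {
    msg <- c(msg, "active positions must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' PowerLawFit: a log10-log10 power-law regression
#'
#' Result of regressing \code{log10(y)} on \code{log10(x)}: the fitted
#' exponent (slope), its percentile bootstrap confidence interval, and t-tests
#' of the slope against 0 and against -1 (the value a pure hyperbolic
#' ratio-versus-denominator relation predicts).
#'
#' @slot slope,intercept OLS estimates in log10-log10 space.
#' @slot ciLow,ciHigh percentile pair-bootstrap CI for the slope (NA when
#'   \code{nBoot = 0}).
#' @slot rSquared coefficient of determination.
#' @slot n number of pairs used.
#' @slot pVsZero,pVsMinusOne two-sided t-test p-values for slope = 0 and
#'   slope = -1.
#' @slot seSlope standard error of the slope (OLS).
#' @slot nBoot bootstrap replicates used.
#' @slot seed seed used for the bootstrap.
#' @slot basis ratio basis label carried through ("weight", "molar" or "").
#' @slot excludedNonpositive pairs dropped because x or y was missing or
#'   non-positive.
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(
    slope = "numeric", intercept = "numeric",
    ciLow = "numeric", ciHigh = "numeric", rSquared = "numeric",
    n = "integer", pVsZero = "numeric", pVsMinusOne = "numeric",
    seSlope = "numeric", nBoot = "integer", seed = "integer",
    basis = "character", excludedNonpositive = "integer"
  )
)

setValidity("PowerLawFit", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh) {
    msg <- c(msg, "CI bounds must be ordered")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GriddedField", function(object) {
  cat(sprintf(
    "GriddedField: %d x %d x %d (lon x lat x time), %s\n",
    length(object@lon), length(object@lat), length(object@time), object@units
  ))
  cat(sprintf(
    "  lon [%.3f, %.3f]  lat [%.3f, %.3f]  %d masked cells\n",
    min(object@lon), max(object@lon), min(object@lat), max(object@lat),
    sum(!object@mask)
  ))
})

setMethod("show", "BacktrackConfig", function(object) {
  cat(sprintf(
    "BacktrackConfig: %s, %d particles, %.0f days at dt = %.0f s\n",
    object@direction, object@nParticles, object@duration / 86400, object@dt
  ))
  cat(sprintf(
    "  D = %g m^2/s (sigma scheme '%s'), windage = %g, %s, seed = %d\n",
    object@D, object@sigmaScheme, object@windage, object@integrator,
    object@seed
  ))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf(
    "TrajectoryEnsemble '%s': %d particles, %d saved steps (%s)\n",
    object@stationId, nrow(object@lon), ncol(object@lon),
    object@config@direction
  ))
  cat(sprintf(
    "  released at (%.3f, %.3f), %d still active at final step\n",
    object@release[1], object@release[2], sum(object@active[, ncol(object@active)])
  ))
})

setMethod("show", "PowerLawFit", function(object) {
  cat("Power-law fit (OLS in log10-log10 space)\n")
  cat(sprintf(
    "  slope = %.4f [%.4f, %.4f], intercept = %.4f, r^2 = %.3f, n = %d\n",
    object@slope, object@ciLow, object@ciHigh, object@intercept,
    object@rSquared, object@n
  ))
  cat(sprintf(
    "  H0 slope = 0: p = %.3g;  H0 slope = -1: p = %.3g  (t-tests, %d boot reps)\n",
    object@pVsZero, object@pVsMinusOne, object@nBoot
  ))
  if (object@excludedNonpositive > 0L) {
    cat(sprintf("  %d non-positive/missing pairs excluded\n",
                object@excludedNonpositive))
  }
})
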