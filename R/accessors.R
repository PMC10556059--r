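# Constructors and accessors for the S4 containers.

#' Construct a GriddedField
#'
#' @param lon,lat,time grid coordinate vectors (degrees, degrees, seconds).
#'   Longitudes on a 0-360 convention are normalized to \code{[-180, 180)}
#'   and the arrays re-ordered accordingly.
#' @param u,v velocity component arrays \code{(nlon, nlat, ntime)} in m s^-1;
#'   a matrix is accepted for a steady field (single time).
#' @param mask optional logical \code{nlon x nlat} water mask; defaults to
#'   cells with at least one finite u value over time.
#' @param units unit string, must denote m s^-1.
#' @return a [GriddedField-class].
#' @export
griddedField <- function(lon, lat, time, u, v, mask = NULL, units = "m s-1") {
  if (length(dim(u)) == 2L) u <- array(u, dim = c(dim(u), 1L))
  if (length(dim(v)) == 2L) v <- array(v, dim = c(dim(v), 1L))
  lon2 <- normalizeLon(lon)
  if (is.unsorted(lon2, strictly = TRUE)) {
    ord <- order(lon2)
    lon2 <- lon2[ord]
    u <- u[ord, , , drop = FALSE]
    v <- v[ord, , , drop = FALSE]
    if (!is.null(mask)) mask <- mask[ord, , drop = FALSE]
  }
  if (is.null(mask)) {
    mask <- apply(is.finite(u), c(1, 2), any)
  }
  new("GriddedField",
    lon = as.numeric(lon2), lat = as.numeric(lat), time = as.numeric(time),
    u = u, v = v, mask = mask, units = units
  )
}

#' Construct a tracking configuration
#'
#' Defaults follow the drift analysis this package implements: horizontal
#' diffusivity 4000 m^2 s^-1 (Argo-derived estimate for the subtropical
#' North Atlantic), 2 percent windage (mid-point of the 0.5-3 percent range
#' that best reproduces observed Sargassum drift), 6-hour steps, 60 days
#' backward, 100 particles per release site.
#'
#' @param D horizontal diffusivity (m^2 s^-1).
#' @param windage fraction of the 10-m wind added to the current, in [0, 0.1].
#' @param dt time step (s).
#' @param duration total tracked time (s), a positive multiple of \code{dt}.
#' @param nParticles particles per release site.
#' @param direction "backward" or "forward".
#' @param seed integer master seed for the random walk.
#' @param integrator "euler" or "rk4".
#' @param sigmaScheme "total" (2-D displacement variance 4*D*dt, default) or
#'   "percomp" (variance 4*D*dt on each component).
#' @param saveStride save every k-th step.
#' @return a [BacktrackConfig-class].
#' @export
backtrackConfig <- function(D = 4000, windage = 0.02, dt = 21600,
                            duration = 60 * 86400, nParticles = 100L,
                            direction = c("backward", "forward"),
                            seed = 1L, integrator = c("euler", "rk4"),
                            sigmaScheme = c("total", "percomp"),
                            saveStride = 1L) {
  new("BacktrackConfig",
    D = D, windage = windage, dt = dt, duration = duration,
    nParticles = as.integer(nParticles), direction = match.arg(direction),
    seed = as.integer(seed), integrator = match.arg(integrator),
    sigmaScheme = match.arg(sigmaScheme), saveStride = as.integer(saveStride)
  )
}

#' @rdname griddedField
#' @param x a GriddedField.
#' @export
fieldLon <- function(x) x@lon

#' @rdname griddedField
#' @export
fieldLat <- function(x) x@lat

#' @rdname griddedField
#' @export
fieldTime <- function(x) x@time

#' @rdname griddedField
#' @export
fieldMask <- function(x) x@mask

#' Accessors for TrajectoryEnsemble
#'
#' @param x a [TrajectoryEnsemble-class].
#' @return `trajLon`/`trajLat`: particles x steps matrices; `trajTimes`: saved
#'   times; `trajActive`: logical matrix; `trajConfig`: the config;
#'   `releaseSite`: c(lon, lat, time).
#' @export
trajLon <- function(x) x@lon

#' @rdname trajLon
#' @export
trajLat <- function(x) x@lat

#' @rdname trajLon
#' @export
trajTimes <- function(x) x@times

#' @rdname trajLon
#' @export
trajActive <- function(x) x@active

#' @rdname trajLon
#' @export
trajConfig <- function(x) x@config

#' @rdname trajLon
#' @export
releaseSite <- function(x) x@release

#' Extract a power-law fit report as a plain list
#'
#' The list mirrors the JSON fit report written by the pipeline:
#' slope, intercept, ci_low, ci_high, r_squared, n, p_vs_zero, p_vs_minus_one,
#' n_boot, seed, basis, excluded_nonpositive.
#'
#' @param fit a [PowerLawFit-class].
#' @return named list.
#' @export
fitReport <- function(fit) {
  stopifnot(is(fit, "PowerLawFit"))
  list(
    slope = fit@slope, intercept = fit@intercept,
    ci_low = fit@ciLow, ci_high = fit@ciHigh,
    r_squared = fit@rSquared, n = fit@n,
    p_vs_zero = fit@pVsZero, p_vs_minus_one = fit@pVsMinusOne,
    n_boot = fit@nBoot, seed = fit@seed, basis = fit@basis,
    excluded_nonpositive = fit@excludedNonpositive
  )
}

#' @rdname fitReport
#' @export
fitSlope <- function(fit) fit@slope

#' @rdname fitReport
#' @export
fitSlopeCI <- function(fit) c(fit@ciLow, fit@ciHigh)
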