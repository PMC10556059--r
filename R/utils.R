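# Shared constants and small numeric helpers.

# Atomic masses (g mol^-1) used for weight <-> molar ratio conversion.
.ATOMIC_MASS <- c(C = 12.011, N = 14.007, P = 30.974, As = 74.922)

# Mean Earth radius (m); local-tangent-plane metre <-> degree conversion.
.R_EARTH <- 6371000
.DEG2RAD <- pi / 180

#' Normalize longitudes to [-180, 180)
#'
#' All longitudes in the package live on the half-open interval
#' \code{[-180, 180)}; inputs on a 0-360 convention are wrapped on read.
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector in \code{[-180, 180)}.
#' @export
#' @examples
#' normalizeLon(c(0, 359.5, 180, -180))
normalizeLon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# Deterministic child seed derived from a master seed and an operation tag,
# kept below 2^31 so it is always a valid R integer seed.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Metres -> degrees at latitude phi (degrees). Vectorized.
metersToDegrees <- function(dx, dy, lat) {
  cosphi <- cos(lat * .DEG2RAD)
  if (any(cosphi < 1e-6, na.rm = TRUE)) {
    stop("latitude too close to a pole for tangent-plane conversion")
  }
  list(
    dlon = dx / (.R_EARTH * cosphi) / .DEG2RAD,
    dlat = dy / .R_EARTH / .DEG2RAD
  )
}

# Degrees -> metres displacement about a reference latitude.
degreesToMeters <- function(dlon, dlat, lat) {
  list(
    dx = dlon * .DEG2RAD * .R_EARTH * cos(lat * .DEG2RAD),
    dy = dlat * .DEG2RAD * .R_EARTH
  )
}

# Even-odd ray casting point-in-polygon test. `poly` is a two-column matrix
# of (lon, lat) vertices, not necessarily closed. Vertices and query points
# are assumed to be on a common longitude branch (the default region scheme
# uses [-180, 180) throughout). Boundary points are resolved by edge-crossing
# parity, which is deterministic; overlapping regions resolve by scheme
# precedence, not by this routine.
pointInPolygon <- function(lon, lat, poly) {
  px <- poly[, 1]
  py <- poly[, 2]
  nv <- length(px)
  j <- c(nv, seq_len(nv - 1L))
  inside <- rep(FALSE, length(lon))
  for (k in seq_len(nv)) {
    xi <- px[k]; yi <- py[k]
    xj <- px[j[k]]; yj <- py[j[k]]
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside
}
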