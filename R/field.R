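# Gridded-field text I/O and trilinear interpolation.
#
# Fields are exchanged as a plain-text long-format CSV:
#   # gridded-field v1
#   # units: m s-1
#   lon,lat,time,u,v
# one row per grid node and time, NA components marking masked (land) cells.

.VALID_UNITS <- c("m s-1", "m/s", "m s^-1", "meter/second", "meters per second")

#' Read a gridded velocity field
#'
#' Reads the package's long-format gridded-field CSV (see
#' [writeGriddedField()]). Longitudes on a 0-360 convention are normalized to
#' \code{[-180, 180)} with the arrays re-ordered; cells whose components are
#' missing at every time become the land/missing mask and are never treated
#' as zero velocity. The declared units must be m s^-1 unless a converter is
#' registered for them.
#'
#' @param path CSV file with a \code{# units:} header line and columns
#'   \code{lon,lat,time,u,v}.
#' @param converters optional named list of functions; if the declared unit
#'   string matches a name, that function is applied to u and v.
#' @return a [GriddedField-class].
#' @export
readGriddedField <- function(path, converters = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 10L)
  uline <- grep("^#\\s*units:", hdr, value = TRUE)
  units <- if (length(uline)) trimws(sub("^#\\s*units:", "", uline[1])) else ""
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("lon", "lat", "time", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing coordinate/component column(s): ",
                         paste(miss, collapse = ", "))
  if (!units %in% .VALID_UNITS) {
    conv <- converters[[units]]
    if (is.null(conv)) {
      stop("unit mismatch: declared '", units,
           "' is not m s-1 and no converter is registered")
    }
    df$u <- conv(df$u)
    df$v <- conv(df$v)
    units <- "m s-1"
  }
  df$lon <- normalizeLon(df$lon)
  lons <- sort(unique(df$lon))
  lats <- sort(unique(df$lat))
  times <- sort(unique(df$time))
  d <- c(length(lons), length(lats), length(times))
  if (nrow(df) != prod(d)) {
    stop("grid is not complete: expected ", prod(d), " rows, got ", nrow(df))
  }
  ii <- cbind(match(df$lon, lons), match(df$lat, lats), match(df$time, times))
  u <- array(NA_real_, dim = d)
  v <- array(NA_real_, dim = d)
  u[ii] <- df$u
  v[ii] <- df$v
  griddedField(lons, lats, times, u, v, units = units)
}

#' Write a gridded velocity field
#'
#' @param field a [GriddedField-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGriddedField <- function(field, path) {
  d <- c(length(field@lon), length(field@lat), length(field@time))
  grid <- expand.grid(lon = field@lon, lat = field@lat, time = field@time,
                      KEEP.OUT.ATTRS = FALSE)
  grid$u <- as.vector(field@u)
  grid$v <- as.vector(field@v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gridded-field v1", paste0("# units: ", field@units)), con)
  write.csv(grid, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Core interpolation used by both the public interpField and the tracker.
# Returns list(u, v, nearLand); out-of-domain points come back NA (the public
# wrapper turns those into errors when requested).
interpCore <- function(field, lon, lat, t) {
  n <- length(lon)
  lon <- normalizeLon(lon)
  glon <- field@lon; glat <- field@lat; gt <- field@time
  nlon <- length(glon); nlat <- length(glat); nt <- length(gt)

  ix <- findInterval(lon, glon)
  iy <- findInterval(lat, glat)
  ix[lon == glon[nlon]] <- nlon - 1L
  iy[lat == glat[nlat]] <- nlat - 1L
  okxy <- ix >= 1L & ix <= nlon - 1L & iy >= 1L & iy <= nlat - 1L

  if (nt == 1L) {
    it <- rep(1L, n); wt <- rep(0, n); okt <- rep(TRUE, n)
    it2 <- it
  } else {
    okt <- t >= gt[1] & t <= gt[nt]
    it <- findInterval(t, gt)
    it[t == gt[nt]] <- nt - 1L
    it <- pmax(1L, pmin(it, nt - 1L))
    it2 <- it + 1L
    wt <- (t - gt[it]) / (gt[it2] - gt[it])
  }
  ok <- okxy & okt & is.finite(lon) & is.finite(lat)

  u <- v <- rep(NA_real_, n)
  nearLand <- rep(FALSE, n)
  if (!any(ok)) return(list(u = u, v = v, nearLand = nearLand))

  i1 <- ix[ok]; j1 <- iy[ok]
  wx <- (lon[ok] - glon[i1]) / (glon[i1 + 1L] - glon[i1])
  wy <- (lat[ok] - glat[j1]) / (glat[j1 + 1L] - glat[j1])
  # 4 spatial corners: (i,j), (i+1,j), (i,j+1), (i+1,j+1)
  ci <- cbind(i1, i1 + 1L, i1, i1 + 1L)
  cj <- cbind(j1, j1, j1 + 1L, j1 + 1L)
  w4 <- cbind((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
  m4 <- matrix(field@mask[cbind(as.vector(ci), as.vector(cj))], ncol = 4L)
  wEff <- w4 * m4
  wSum <- rowSums(wEff)
  nearLand[ok] <- rowSums(!m4 & w4 > 0) > 0

  sliceVal <- function(arr, itk) {
    vals <- matrix(arr[cbind(as.vector(ci), as.vector(cj),
                             rep(itk, 4L))], ncol = 4L)
    vals[!m4] <- 0  # masked nodes carry zero weight; keep 0 * NA out of the sum
    rowSums(wEff * vals) / wSum
  }
  u1 <- sliceVal(field@u, it[ok]); v1 <- sliceVal(field@v, it[ok])
  if (nt == 1L) {
    u[ok] <- u1; v[ok] <- v1
  } else {
    u2 <- sliceVal(field@u, it2[ok]); v2 <- sliceVal(field@v, it2[ok])
    wtk <- wt[ok]
    u[ok] <- (1 - wtk) * u1 + wtk * u2
    v[ok] <- (1 - wtk) * v1 + wtk * v2
  }
  list(u = u, v = v, nearLand = nearLand)
}

#' Interpolate a gridded field at points
#'
#' Trilinear (bilinear in space, linear in time) interpolation. When a
#' contributing grid node is masked the point is flagged near-land and its
#' value uses the remaining unmasked nodes with renormalized weights; a point
#' whose four surrounding nodes are all masked gets \code{NA}.
#'
#' @param field a [GriddedField-class].
#' @param lon,lat,t query coordinates (vectors recycled to common length).
#' @param outOfDomain "error" (default) or "na" for queries outside the grid
#'   or its time coverage.
#' @return data.frame with columns \code{u}, \code{v} (m s^-1) and
#'   \code{near_land}.
#' @export
interpField <- function(field, lon, lat, t, outOfDomain = c("error", "na")) {
  outOfDomain <- match.arg(outOfDomain)
  n <- max(length(lon), length(lat), length(t))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t <- rep_len(t, n)
  res <- interpCore(field, lon, lat, t)
  inDomain <- normalizeLon(lon) >= field@lon[1] &
    normalizeLon(lon) <= field@lon[length(field@lon)] &
    lat >= field@lat[1] & lat <= field@lat[length(field@lat)] &
    (length(field@time) == 1L |
       (t >= field@time[1] & t <= field@time[length(field@time)]))
  if (outOfDomain == "error" && any(!inDomain)) {
    stop("query outside grid domain or time coverage")
  }
  data.frame(u = res$u, v = res$v, near_land = res$nearLand)
}
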