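# Shared fixtures, built in code at test time.

# Write a small tissue CSV and return its path.
writeTissueFixture <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste(
    "sample_id,cruise,station_id,latitude,longitude,date,species,replicate",
    "pct_C,pct_N,pct_P,d15N,as_ug_g,era", sep = ","
  )
  writeLines(c(header, rows), path)
  path
}

tissueRow <- function(id = "s1", lat = 25, lon = -66, pct_C = 30, pct_N = 1,
                      pct_P = 0.05, d15N = 0.5, as_ug_g = 100,
                      species = "S_fluitans_III", era = "y2021") {
  sprintf("%s,A22,st01,%s,%s,2021-04-15,%s,1,%s,%s,%s,%s,%s,%s",
          id, lat, lon, species, pct_C, pct_N, pct_P, d15N, as_ug_g, era)
}

# Independent brute-force trilinear interpolation oracle: explicit weighted
# sum over the 8 surrounding nodes (no mask logic).
oracleInterp <- function(lon, lat, t, glon, glat, gt, arr) {
  i <- max(which(glon <= lon)); i <- min(i, length(glon) - 1)
  j <- max(which(glat <= lat)); j <- min(j, length(glat) - 1)
  if (length(gt) == 1) {
    ks <- c(1, 1); wt <- 0
  } else {
    k <- max(which(gt <= t)); k <- min(k, length(gt) - 1)
    ks <- c(k, k + 1); wt <- (t - gt[k]) / (gt[k + 1] - gt[k])
  }
  wx <- (lon - glon[i]) / (glon[i + 1] - glon[i])
  wy <- (lat - glat[j]) / (glat[j + 1] - glat[j])
  val <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 1:2) {
    w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
      (if (dk == 2) wt else 1 - wt)
    if (length(gt) == 1 && dk == 2) next
    if (length(gt) == 1) w <- (if (di) wx else 1 - wx) *
      (if (dj) wy else 1 - wy)
    val <- val + w * arr[i + di, j + dj, ks[dk]]
  }
  val
}

# Quiescent (zero-velocity) steady field over a generous box.
quiescentField <- function() {
  genField("uniform", domain = c(-75, -40, 0, 40), resolution = 1,
           u0 = 0, v0 = 0)$field
}
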