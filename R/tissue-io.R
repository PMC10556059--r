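# Reading, validating, grouping and summarizing tissue-composition records.

.TISSUE_COLS <- c(
  "sample_id", "cruise", "station_id", "latitude", "longitude", "date",
  "species", "replicate", "pct_C", "pct_N", "pct_P", "d15N", "as_ug_g", "era"
)
.TISSUE_NUMERIC <- c("latitude", "longitude", "pct_C", "pct_N", "pct_P",
                     "d15N", "as_ug_g")
.SPECIES_LEVELS <- c("S_fluitans_III", "S_natans_I")
.ERA_LEVELS <- c("y2021", "y1983_1987", "y2015_2018")
.REGION_LEVELS <- c("NSS", "SS", "WTA", "CAR", "other")

#' Read a tissue-composition table
#'
#' Reads a CSV of per-replicate Sargassum tissue measurements (percent dry
#' weight C/N/P, delta-15N in permil, arsenic in ug per g dry weight, plus
#' cruise/station/position/species/era metadata). Rows with unparseable or
#' out-of-range coordinates, or with every chemistry value missing, are
#' rejected with a logged reason; missing individual values ("NA" or empty)
#' are retained as \code{NA} and excluded later by the fits that need them.
#' Longitudes are normalized to \code{[-180, 180)}.
#'
#' @param path CSV file with header columns
#'   \code{sample_id,cruise,station_id,latitude,longitude,date,species,
#'   replicate,pct_C,pct_N,pct_P,d15N,as_ug_g,era} (ISO-8601 dates).
#' @param schema optional named character vector mapping the canonical column
#'   names above to the file's column names.
#' @return a \code{data.frame} of accepted records, with attributes
#'   \code{nAccepted}, \code{nRejected} and \code{rejectLog} (a data.frame of
#'   row numbers and reasons).
#' @export
readTissueTable <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty tissue table: ", path)
  cols <- .TISSUE_COLS
  filecols <- if (is.null(schema)) setNames(cols, cols) else schema
  missing_map <- setdiff(cols, names(filecols))
  if (length(missing_map)) {
    stop("schema must map column(s): ", paste(missing_map, collapse = ", "))
  }
  absent <- setdiff(unname(filecols), names(raw))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }
  df <- setNames(raw[, unname(filecols[cols]), drop = FALSE], cols)
  for (v in .TISSUE_NUMERIC) {
    df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  }
  df$replicate <- suppressWarnings(as.integer(df$replicate))

  reasons <- rep(NA_character_, nrow(df))
  badlat <- is.na(df$latitude) | df$latitude < -90 | df$latitude > 90
  badlon <- is.na(df$longitude)
  reasons[badlat | badlon] <- "unparseable or out-of-range coordinates"
  chem <- c("pct_C", "pct_N", "pct_P", "d15N", "as_ug_g")
  allmiss <- rowSums(!is.na(as.matrix(df[, chem]))) == 0L
  reasons[is.na(reasons) & allmiss] <- "all chemistry values missing"
  negchem <- !is.na(df$pct_C) & df$pct_C < 0 |
    !is.na(df$pct_N) & df$pct_N < 0 |
    !is.na(df$pct_P) & df$pct_P < 0 |
    !is.na(df$as_ug_g) & df$as_ug_g < 0
  reasons[is.na(reasons) & negchem] <- "negative element content"

  keep <- is.na(reasons)
  out <- df[keep, , drop = FALSE]
  out$longitude <- normalizeLon(out$longitude)
  out$species <- factor(out$species, levels = .SPECIES_LEVELS)
  out$era <- factor(out$era, levels = .ERA_LEVELS)
  rownames(out) <- NULL
  rejectLog <- data.frame(
    row = which(!keep), reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  if (nrow(rejectLog)) {
    message(sprintf("readTissueTable: rejected %d of %d rows",
                    nrow(rejectLog), nrow(df)))
  }
  attr(out, "nAccepted") <- sum(keep)
  attr(out, "nRejected") <- sum(!keep)
  attr(out, "rejectLog") <- rejectLog
  out
}

#' Region schemes for grouping samples
#'
#' A region scheme is a named list of simple lon/lat polygons plus a
#' precedence order used when polygons overlap or a point sits on a shared
#' boundary. The default scheme approximates the western North Atlantic
#' sample groupings with four configurable boxes: northern Sargasso Sea
#' (NSS, 30-40N), Sargasso Sea proper (SS, 22-30N), Caribbean interior
#' (CAR, west of 64W), and western tropical Atlantic (WTA, south of 12N).
#' Points in no polygon fall back to "other".
#'
#' @return a list with elements \code{regions} (named list of two-column
#'   lon/lat vertex matrices) and \code{precedence} (character vector).
#' @export
defaultRegionScheme <- function() {
  box <- function(lonmin, lonmax, latmin, latmax) {
    cbind(
      lon = c(lonmin, lonmax, lonmax, lonmin),
      lat = c(latmin, latmin, latmax, latmax)
    )
  }
  list(
    regions = list(
      NSS = box(-70, -45, 30, 40),
      SS  = box(-70, -45, 22, 30),
      CAR = box(-90, -64, 8, 22),
      WTA = box(-64, -40, 0, 12)
    ),
    precedence = c("NSS", "SS", "CAR", "WTA")
  )
}

#' Read a region scheme from YAML
#'
#' Expects \code{precedence: [..]} and \code{regions: {NAME: {lon: [..],
#' lat: [..]}, ..}} with matching-length vertex vectors per region.
#'
#' @param path YAML file.
#' @return a region scheme list as in [defaultRegionScheme()].
#' @export
readRegionScheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("region scheme YAML must define 'regions'")
  regions <- lapply(cfg$regions, function(r) {
    if (length(r$lon) != length(r$lat) || length(r$lon) < 3) {
      stop("each region needs matching lon/lat vertex vectors (>= 3 vertices)")
    }
    cbind(lon = normalizeLon(as.numeric(r$lon)), lat = as.numeric(r$lat))
  })
  precedence <- cfg$precedence %||% names(regions)
  list(regions = regions, precedence = as.character(precedence))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign samples to regions
#'
#' Deterministic point-in-polygon assignment: polygons are tested in the
#' scheme's precedence order and the first containing polygon wins, so points
#' on a shared boundary resolve by precedence. Every finite coordinate yields
#' a code; points in no polygon get "other".
#'
#' @param lon,lat coordinate vectors (degrees); or pass a tissue data.frame
#'   via \code{samples}.
#' @param scheme a region scheme (default [defaultRegionScheme()]).
#' @param samples optional data.frame with \code{longitude}/\code{latitude};
#'   overrides \code{lon}/\code{lat}.
#' @return factor of region codes with levels
#'   \code{NSS, SS, WTA, CAR, other}; with \code{samples}, the data.frame with
#'   a \code{region} column appended.
#' @export
assignRegion <- function(lon, lat, scheme = defaultRegionScheme(),
                         samples = NULL) {
  if (!is.null(samples)) {
    region <- assignRegion(samples$longitude, samples$latitude, scheme)
    samples$region <- region
    return(samples)
  }
  lon <- normalizeLon(lon)
  out <- rep("other", length(lon))
  remaining <- is.finite(lon) & is.finite(lat)
  out[!remaining] <- "other"
  for (code in scheme$precedence) {
    poly <- scheme$regions[[code]]
    if (is.null(poly)) next
    hit <- remaining & pointInPolygon(lon, lat, poly)
    out[hit] <- code
    remaining <- remaining & !hit
  }
  factor(out, levels = .REGION_LEVELS)
}

#' Elemental ratios of tissue samples
#'
#' Computes C:N, C:P, N:P and As:P per record. On the weight basis ratios are
#' direct percent-dry-weight ratios, with arsenic converted from ug per g to
#' percent (division by 1e4). On the molar basis each percent is divided by
#' its atomic mass first (C 12.011, N 14.007, P 30.974, As 74.922 g/mol).
#' A zero or missing denominator yields \code{NA} (an undefined-ratio flag),
#' never an error.
#'
#' @param samples data.frame with columns \code{pct_C, pct_N, pct_P, as_ug_g}.
#' @param basis "weight" or "molar".
#' @return data.frame with columns \code{c_to_n, c_to_p, n_to_p, as_to_p}
#'   and \code{basis}.
#' @export
elementalRatios <- function(samples, basis = c("weight", "molar")) {
  basis <- match.arg(basis)
  pc <- samples$pct_C
  pn <- samples$pct_N
  pp <- samples$pct_P
  pas <- samples$as_ug_g / 1e4  # ug/g dry wt -> percent dry wt
  if (basis == "molar") {
    pc <- pc / .ATOMIC_MASS[["C"]]
    pn <- pn / .ATOMIC_MASS[["N"]]
    pp <- pp / .ATOMIC_MASS[["P"]]
    pas <- pas / .ATOMIC_MASS[["As"]]
  }
  safeDiv <- function(a, b) ifelse(is.na(b) | b == 0, NA_real_, a / b)
  data.frame(
    c_to_n = safeDiv(pc, pn),
    c_to_p = safeDiv(pc, pp),
    n_to_p = safeDiv(pn, pp),
    as_to_p = safeDiv(pas, pp),
    basis = basis,
    stringsAsFactors = FALSE
  )
}

#' Summarize tissue variables by group
#'
#' @param samples tissue data.frame (with a \code{region} column if grouping
#'   by region).
#' @param groupKeys character vector among \code{"region"}, \code{"species"},
#'   \code{"era"}.
#' @param variables numeric columns to summarize (default the five
#'   measurements).
#' @return long data.frame: one row per group x variable with \code{n}
#'   (non-missing), \code{n_missing}, \code{mean}, \code{sd}, \code{median},
#'   \code{iqr}. Empty groups are omitted with a warning.
#' @export
summarizeByGroup <- function(samples,
                             groupKeys = c("region", "species", "era"),
                             variables = c("pct_C", "pct_N", "pct_P",
                                           "d15N", "as_ug_g")) {
  groupKeys <- match.arg(groupKeys, several.ok = TRUE)
  miss <- setdiff(c(groupKeys, variables), names(samples))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(samples[groupKeys], drop = FALSE, sep = "|")
  empty <- setdiff(levels(key), unique(as.character(key)))
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  }
  rows <- lapply(split(seq_len(nrow(samples)), key, drop = TRUE), function(idx) {
    g <- samples[idx, , drop = FALSE]
    do.call(rbind, lapply(variables, function(v) {
      x <- g[[v]]
      ok <- !is.na(x)
      cbind(
        g[1, groupKeys, drop = FALSE],
        data.frame(
          variable = v, n = sum(ok), n_missing = sum(!ok),
          mean = if (any(ok)) mean(x[ok]) else NA_real_,
          sd = if (sum(ok) > 1) sd(x[ok]) else NA_real_,
          median = if (any(ok)) median(x[ok]) else NA_real_,
          iqr = if (any(ok)) IQR(x[ok]) else NA_real_,
          stringsAsFactors = FALSE
        )
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a tissue variable across groups
#'
#' Welch's unequal-variance one-way test across all groups, followed by
#' pairwise Welch t-tests with Holm correction and a standardized mean
#' difference (Cohen's d with the unpooled average-variance denominator) per
#' pair. The method labels are carried in the output because the appropriate
#' test is a user decision, not a package assumption.
#'
#' @param samples tissue data.frame.
#' @param variable column to compare.
#' @param grouping grouping column ("region", "species" or "era").
#' @return list with \code{testable}, \code{method}, \code{statistic} (Welch
#'   F), \code{df}, \code{p_value}, \code{pairwise} (data.frame: group1,
#'   group2, p_holm, cohens_d), \code{groups} (per-group n). Groups need at
#'   least 3 non-missing values; with fewer than 2 such groups the result is
#'   flagged not testable.
#' @export
compareGroups <- function(samples, variable, grouping = "region") {
  x <- samples[[variable]]
  g <- droplevels(factor(samples[[grouping]]))
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  counts <- table(g)
  usable <- names(counts)[counts >= 3]
  if (length(usable) < 2) {
    return(list(
      testable = FALSE, method = "welch-anova + pairwise-welch-holm",
      reason = "fewer than 2 groups with >= 3 non-missing values"
    ))
  }
  keep <- g %in% usable
  x <- x[keep]; g <- droplevels(g[keep])
  constant <- all(tapply(x, g, function(v) var(v) == 0 || is.na(var(v))))
  if (constant && length(unique(x)) == 1L) {
    pw <- t(combn(levels(g), 2))
    return(list(
      testable = TRUE, method = "welch-anova + pairwise-welch-holm",
      statistic = 0, df = c(length(levels(g)) - 1, NA), p_value = 1,
      pairwise = data.frame(group1 = pw[, 1], group2 = pw[, 2],
                            p_holm = 1, cohens_d = 0,
                            stringsAsFactors = FALSE),
      groups = as.data.frame(table(g), responseName = "n")
    ))
  }
  ow <- oneway.test(x ~ g, var.equal = FALSE)
  pairs <- t(combn(levels(g), 2))
  pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- x[g == pairs[i, 1]]
    b <- x[g == pairs[i, 2]]
    p <- tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    sdm <- sqrt((var(a) + var(b)) / 2)
    d <- if (isTRUE(sdm > 0)) (mean(a) - mean(b)) / sdm
         else if (isTRUE(mean(a) == mean(b))) 0 else NA_real_
    data.frame(group1 = pairs[i, 1], group2 = pairs[i, 2],
               p_raw = p, cohens_d = d, stringsAsFactors = FALSE)
  }))
  pw$p_holm <- p.adjust(pw$p_raw, method = "holm")
  list(
    testable = TRUE, method = "welch-anova + pairwise-welch-holm",
    statistic = unname(ow$statistic), df = unname(ow$parameter),
    p_value = ow$p.value,
    pairwise = pw[, c("group1", "group2", "p_raw", "p_holm", "cohens_d")],
    groups = as.data.frame(table(g), responseName = "n")
  )
}
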