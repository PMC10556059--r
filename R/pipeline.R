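# Pipeline orchestration: read -> group -> ratios -> fit -> backtrack ->
# manifest, behind a single config list (YAML-loadable).

#' Read a pipeline run configuration
#'
#' The configuration is a YAML mapping with blocks \code{tissue} (either
#' \code{path:} or \code{synthetic:} generator options), optional
#' \code{region_scheme} (YAML path), \code{fit} (\code{basis},
#' \code{n_boot}, \code{seed}), optional \code{isotope} (the three
#' delta-15N end-members), and optional \code{backtrack} (either field paths
#' \code{currents}/\code{winds} or \code{synthetic:} field options, plus
#' \code{stations} and the tracker parameters \code{D}, \code{windage},
#' \code{dt_hours}, \code{days}, \code{particles}, \code{direction},
#' \code{seed}). Exactly one of path/synthetic must be given per input.
#'
#' @param path YAML file.
#' @return config list for [runAll()].
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

checkOneOf <- function(block, name) {
  hasPath <- !is.null(block$path)
  hasSyn <- !is.null(block$synthetic)
  if (hasPath == hasSyn) {
    stop("config error: '", name,
         "' needs exactly one of 'path' or 'synthetic'")
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: tissue input (read or generate), region assignment,
#' elemental ratios, group summaries and comparisons, the As:P power-law fit,
#' the correlation/ratio-fit summary, the optional isotope-dilution
#' calculation, and the optional particle backtracking. Every output file is
#' listed in a manifest with its MD5 hash, the package version and all seeds;
#' a rerun with the same config reproduces the hashes. A stage failure halts
#' the run with the stage name while preserving the outputs already written.
#'
#' @param config config list (see [readRunConfig()]).
#' @param outDir output directory, created if needed.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
runAll <- function(config, outDir = config$out_dir %||% "sargasso-run") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sargasso")),
    seeds = list(), outputs = list()
  )
  outputs <- character()
  emit <- function(name, writer) {
    p <- file.path(outDir, name)
    writer(p)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- tissue input -------------------------------------------------------
  samples <- stage("tissue-input", {
    blk <- config$tissue
    if (is.null(blk)) stop("config must define a 'tissue' block")
    checkOneOf(blk, "tissue")
    if (!is.null(blk$path)) {
      readTissueTable(blk$path, schema = NULL)
    } else {
      gcfg <- do.call(tissueGenConfig, blk$synthetic %||% list())
      manifest$seeds$tissue <- gcfg$seed
      tab <- genTissueDataset(gcfg)
      emit("tissue_synthetic.csv", function(p) {
        write.csv(tab[, .TISSUE_COLS], p, row.names = FALSE)
      })
      tab
    }
  })

  scheme <- stage("region-scheme", {
    if (!is.null(config$region_scheme)) readRegionScheme(config$region_scheme)
    else defaultRegionScheme()
  })
  samples <- stage("assign-region", assignRegion(samples = samples,
                                                 scheme = scheme))

  basis <- config$fit$basis %||% "weight"
  ratios <- stage("elemental-ratios", elementalRatios(samples, basis = basis))

  stage("summaries", {
    summ <- summarizeByGroup(samples, groupKeys = "region")
    emit("summary_by_region.csv", function(p) {
      write.csv(summ, p, row.names = FALSE)
    })
    comps <- lapply(c("pct_N", "pct_P", "as_ug_g", "d15N"), function(v) {
      compareGroups(samples, v, "region")
    })
    names(comps) <- c("pct_N", "pct_P", "as_ug_g", "d15N")
    emit("group_comparisons.json", function(p) {
      jsonlite::write_json(comps, p, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    })
  })

  fit <- stage("asp-fit", {
    nBoot <- config$fit$n_boot %||% 10000L
    seed <- config$fit$seed %||% 42L
    manifest$seeds$fit <- seed
    f <- fitPowerLaw(samples$pct_P, ratios$as_to_p, nBoot = nBoot,
                     seed = seed, basis = basis)
    emit("fit_asp.json", function(p) {
      jsonlite::write_json(fitReport(f), p, auto_unbox = TRUE, digits = NA)
    })
    f
  })

  stage("correlation-summary", {
    cs <- correlationSummary(samples, nBoot = config$fit$n_boot %||% 1000L,
                             seed = config$fit$seed %||% 42L)
    emit("correlations.json", function(p) {
      jsonlite::write_json(
        list(correlations = cs$correlations,
             ratio_fits = lapply(Filter(Negate(is.null), cs$ratioFits),
                                 fitReport)),
        p, auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
    })
  })

  if (!is.null(config$isotope)) {
    stage("isotope-mixing", {
      iso <- isotopeMixing(config$isotope$d15N_initial,
                           config$isotope$d15N_new_growth,
                           config$isotope$d15N_target)
      emit("isotope_mixing.json", function(p) {
        jsonlite::write_json(c(config$isotope, iso), p, auto_unbox = TRUE,
                             digits = NA)
      })
    })
  }

  if (!is.null(config$backtrack)) {
    stage("backtrack", {
      blk <- config$backtrack
      cfg <- backtrackConfig(
        D = blk$D %||% 4000, windage = blk$windage %||% 0.02,
        dt = (blk$dt_hours %||% 6) * 3600,
        duration = (blk$days %||% 60) * 86400,
        nParticles = blk$particles %||% 100L,
        direction = blk$direction %||% "backward",
        seed = blk$seed %||% 1L
      )
      manifest$seeds$backtrack <- cfg@seed
      loadField <- function(b, what) {
        if (is.null(b)) return(NULL)
        checkOneOf(b, what)
        if (!is.null(b$path)) readGriddedField(b$path)
        else do.call(genField, b$synthetic)$field
      }
      currents <- loadField(blk$currents, "backtrack.currents")
      if (is.null(currents)) stop("backtrack block needs a 'currents' input")
      winds <- loadField(blk$winds, "backtrack.winds")
      if (cfg@windage > 0 && is.null(winds)) {
        stop("config error: windage = ", cfg@windage,
             " but no wind field is configured")
      }
      stations <- if (!is.null(blk$stations$path)) {
        read.csv(blk$stations$path, stringsAsFactors = FALSE)
      } else {
        do.call(genStations, blk$stations$synthetic %||% list(n = 5L))
      }
      ens <- backtrackEnsemble(stations, currents, winds, cfg)
      emit("trajectories.csv", function(p) writeTrajectories(ens, p, "csv"))
      emit("trajectories.geojson", function(p) {
        writeTrajectories(ens, p, "geojson")
      })
      ctr <- do.call(rbind, lapply(names(ens), function(id) {
        cbind(station_id = id, ensembleCentroid(ens[[id]]))
      }))
      emit("centroids.csv", function(p) write.csv(ctr, p, row.names = FALSE))
    })
  }

  manifest$outputs <- lapply(outputs, function(p) {
    list(file = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
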