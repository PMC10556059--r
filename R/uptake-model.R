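# Michaelis-Menten arsenate/phosphate uptake kinetics and the As:P prediction.

#' Michaelis-Menten uptake rate
#'
#' \eqn{\rho = \mu \, c / (k + c)}: uptake saturates at the maximal rate
#' \eqn{\mu} with half-saturation constant \eqn{k} (the concentration at which
#' uptake equals \eqn{\mu/2}).
#'
#' @param conc substrate concentration, >= 0 (same units as \code{k}).
#' @param mu maximal uptake rate, > 0.
#' @param k half-saturation constant, > 0.
#' @return uptake rate(s), in the units of \code{mu}.
#' @export
#' @examples
#' mmUptake(0.5, mu = 2, k = 0.5)  # half-saturation: mu/2 = 1
mmUptake <- function(conc, mu, k) {
  if (any(mu <= 0) || any(k <= 0) || any(conc < 0)) {
    stop("mmUptake requires mu > 0, k > 0 and conc >= 0")
  }
  mu * conc / (k + conc)
}

#' Kinetic parameters for coupled arsenate/phosphate uptake
#'
#' @param mu_P,mu_As maximal uptake rates of phosphate and arsenate (shared
#'   arbitrary rate units).
#' @param k_P,k_As half-saturation constants (shared concentration units).
#' @return validated named list of the four constants.
#' @export
uptakeParams <- function(mu_P, mu_As, k_P, k_As) {
  p <- list(mu_P = mu_P, mu_As = mu_As, k_P = k_P, k_As = k_As)
  if (any(unlist(p) <= 0)) stop("all uptake parameters must be > 0")
  p
}

#' Ratio of arsenate to phosphate uptake
#'
#' In the full regime the ratio of the two Michaelis-Menten rates is
#' returned. In the linearized (low-concentration) regime uptake is
#' approximately \eqn{\mu c / k} for each ion, so the ratio collapses to
#' \eqn{(\mu_{As} k_P)/(\mu_P k_{As}) \cdot [AsO_4]/[PO_4]}; the two regimes
#' agree to first order as concentrations shrink below the half-saturation
#' constants.
#'
#' @param params output of [uptakeParams()].
#' @param PO4,AsO4 dissolved phosphate and arsenate concentrations (same
#'   units as the k's); \code{PO4} must be > 0.
#' @param regime "full" or "linearized".
#' @return uptake-rate ratio \eqn{\rho_{As}/\rho_P} (dimensionless).
#' @export
uptakeRatio <- function(params, PO4, AsO4, regime = c("full", "linearized")) {
  regime <- match.arg(regime)
  if (any(PO4 <= 0)) stop("undefined ratio: PO4 must be > 0")
  if (any(AsO4 < 0)) stop("AsO4 must be >= 0")
  if (regime == "linearized") {
    (params$mu_As * params$k_P) / (params$mu_P * params$k_As) * AsO4 / PO4
  } else {
    mmUptake(AsO4, params$mu_As, params$k_As) /
      mmUptake(PO4, params$mu_P, params$k_P)
  }
}

#' Predicted As:P uptake ratio across a phosphate gradient
#'
#' With surface arsenate held fixed (it is far more uniform than phosphate in
#' the tropical/subtropical Atlantic) the linearized kinetics predict
#' \eqn{\rho_{As}/\rho_P \propto 1/[PO_4]}: an exact hyperbola, i.e. slope -1
#' of log10(ratio) against log10(P). The full regime bends shallower than -1
#' as phosphate approaches saturation.
#'
#' @param P_grid strictly positive phosphate concentrations. For the
#'   linearized regime the grid should sit well inside the linear regime;
#'   values above \code{k_P/10} are accepted but flagged.
#' @param params output of [uptakeParams()].
#' @param AsO4_fixed fixed arsenate concentration.
#' @param regime "linearized" (default) or "full".
#' @return data.frame with columns \code{P} and \code{ratio}; attribute
#'   \code{regimeWarning} is TRUE when the grid leaves the linear regime.
#' @export
predictedAspCurve <- function(P_grid, params, AsO4_fixed,
                              regime = c("linearized", "full")) {
  regime <- match.arg(regime)
  if (any(P_grid <= 0)) stop("P_grid must be strictly positive")
  outside <- regime == "linearized" && max(P_grid) > params$k_P / 10
  if (outside) {
    warning("P_grid exceeds k_P/10: outside the linear uptake regime")
  }
  ratio <- uptakeRatio(params, PO4 = P_grid, AsO4 = AsO4_fixed,
                       regime = regime)
  out <- data.frame(P = P_grid, ratio = ratio)
  attr(out, "regimeWarning") <- outside
  out
}

#' Two-end-member nitrogen isotope dilution
#'
#' Mass balance for growth dilution of an isotopic signature: a population
#' carrying \code{d15N_initial} grows by a factor \code{F} on a nitrogen
#' source imparting \code{d15N_new_growth}, giving
#' \eqn{\delta_{final} = \delta_{init}/F + (1 - 1/F)\,\delta_{new}}.
#' Solving for the growth factor:
#' \eqn{F = (\delta_{init} - \delta_{new}) / (\delta_{final} - \delta_{new})},
#' and the number of population doublings is \eqn{\log_2 F}.
#'
#' Typical values for western North Atlantic Sargassum: Gulf of Mexico
#' end-member +6 to +8 permil, nitrogen fixation about -2 permil, observed
#' +2 permil.
#'
#' @param d15N_initial initial tissue delta-15N (permil).
#' @param d15N_new_growth delta-15N imparted by the new nitrogen source.
#' @param d15N_target observed (final) delta-15N; must lie strictly between
#'   the other two for a solvable dilution.
#' @return list with \code{F} (growth factor) and \code{doublings}
#'   (\code{log2(F)}).
#' @export
#' @examples
#' isotopeMixing(7, -2, 2)  # F = 2.25, about 1.17 doublings
isotopeMixing <- function(d15N_initial, d15N_new_growth, d15N_target) {
  if (d15N_new_growth == d15N_initial) {
    stop("degenerate mixing: end-members are equal, dilution undefined")
  }
  lo <- min(d15N_initial, d15N_new_growth)
  hi <- max(d15N_initial, d15N_new_growth)
  if (d15N_target <= lo || d15N_target >= hi) {
    if (d15N_target == d15N_initial) {
      return(list(F = 1, doublings = 0))
    }
    stop("no solution: target delta-15N must lie strictly between ",
         "the initial and new-growth values")
  }
  F <- (d15N_initial - d15N_new_growth) / (d15N_target - d15N_new_growth)
  list(F = F, doublings = log2(F))
}
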