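#' Convert headspace oxygen fraction to dissolved concentration
#'
#' Equilibrium Henry-law conversion at 1 atm total pressure: dissolved O2
#' (uM) = `henry_constant` x headspace fraction. With the default constant
#' of 1200 uM/atm, a 1% headspace corresponds to 12 uM dissolved O2 and a
#' 0.01% headspace to 120 nM, the conditions at which the hFixL and FnrN
#' sensors respectively become active.
#'
#' @param fraction Headspace O2 as a dimensionless fraction (0.21 =
#'   atmospheric). Vectorised. Fractions above 0.21 trigger a warning.
#' @param params A `cascade_params` object.
#' @return Dissolved O2 concentration(s) in uM.
#' @export
#' @examples
#' headspace_to_dissolved(0.01)    # 12 uM
#' headspace_to_dissolved(0.0001)  # 0.12 uM = 120 nM
headspace_to_dissolved <- function(fraction, params = cascade_params()) {
  if (!is.numeric(fraction) || any(!is.finite(fraction))) {
    stop("`fraction` must be finite numeric", call. = FALSE)
  }
  if (any(fraction < 0)) stop("headspace fraction must be >= 0", call. = FALSE)
  if (any(fraction > 0.21)) {
    warning("headspace fraction above 0.21 is not physically meaningful ",
            "for air-equilibrated assays", call. = FALSE)
  }
  params$henry_constant * fraction
}

#' Oxygen conditions
#'
#' Bundle a headspace fraction with its equilibrium dissolved concentration,
#' or fix the dissolved concentration directly (as inside nodules, where the
#' gradient is set by plant tissue and leghaemoglobin rather than gas
#' equilibrium).
#'
#' @param headspace_fraction Headspace O2 fraction, or `NA` when the
#'   condition is specified by dissolved concentration only.
#' @param dissolved Dissolved O2 in uM; computed from the headspace when
#'   omitted.
#' @param params A `cascade_params` object.
#' @return An `oxygen_condition` object (list with `headspace_fraction` and
#'   `dissolved`).
#' @export
#' @examples
#' oxygen_condition(0.01)
#' oxygen_condition(dissolved = 0.03)  # 30 nM, nodule interior
oxygen_condition <- function(headspace_fraction = NA_real_, dissolved = NULL,
                             params = cascade_params()) {
  if (is.null(dissolved)) {
    if (is.na(headspace_fraction)) {
      stop("supply `headspace_fraction` or `dissolved`", call. = FALSE)
    }
    dissolved <- headspace_to_dissolved(headspace_fraction, params)
  } else {
    if (!is.numeric(dissolved) || dissolved < 0) {
      stop("`dissolved` must be a non-negative concentration in uM",
           call. = FALSE)
    }
  }
  structure(list(headspace_fraction = headspace_fraction,
                 dissolved = dissolved),
            class = "oxygen_condition")
}

#' @export
print.oxygen_condition <- function(x, ...) {
  hs <- if (is.na(x$headspace_fraction)) "fixed dissolved" else
    sprintf("%.4g%% headspace", 100 * x$headspace_fraction)
  cat(sprintf("<oxygen_condition> %s, %.4g uM dissolved O2\n", hs, x$dissolved))
  invisible(x)
}

#' Experimental scenarios
#'
#' The three assay conditions modelled: `"atmospheric"` (21% headspace),
#' `"free_living"` (microaerobic growth at 1% headspace, 12 uM dissolved)
#' and `"in_planta"` (bacteroids in the nodule interior; default 30 nM
#' dissolved, within the reported 20-50 nM range). In-planta states of
#' multistable genotypes are selected by forward integration from that
#' genotype's free-living steady state (`state_selection = "history"`),
#' mimicking a bacterium descending the nodule oxygen gradient; the other
#' scenarios are monostable and use the unique state.
#'
#' @param name Scenario preset name.
#' @param dissolved Override for the dissolved O2 (uM) of the `in_planta`
#'   scenario; e.g. 0.3 for the underdeveloped-nodule variant.
#' @param params A `cascade_params` object.
#' @return A `cascade_scenario` object.
#' @export
#' @examples
#' scenario("free_living")
#' scenario("in_planta", dissolved = 0.3)
scenario <- function(name = c("atmospheric", "free_living", "in_planta"),
                     dissolved = NULL, params = cascade_params()) {
  name <- match.arg(name)
  ox <- switch(name,
    atmospheric = oxygen_condition(0.21, params = params),
    free_living = oxygen_condition(0.01, params = params),
    in_planta = oxygen_condition(dissolved = dissolved %||% 0.03))
  if (name != "in_planta" && !is.null(dissolved)) {
    ox <- oxygen_condition(dissolved = dissolved)
  }
  structure(list(name = name, oxygen = ox,
                 state_selection = if (name == "in_planta") "history"
                                   else "unique"),
            class = "cascade_scenario")
}

as_scenario <- function(x, params = cascade_params()) {
  if (inherits(x, "cascade_scenario")) return(x)
  if (is.character(x) && length(x) == 1) return(scenario(x, params = params))
  stop("expected a cascade_scenario or a scenario name", call. = FALSE)
}

#' @export
print.cascade_scenario <- function(x, ...) {
  cat(sprintf("<cascade_scenario> %s (%.4g uM dissolved O2, %s state)\n",
              x$name, x$oxygen$dissolved, x$state_selection))
  invisible(x)
}

#' Default oxygen sweep grid
#'
#' Log-spaced descending dissolved-O2 grid from 21% to 0.001% headspace
#' equivalents, the range over which the cascade transitions from fully off
#' to fully on.
#'
#' @param n Number of grid points.
#' @param params A `cascade_params` object.
#' @return Numeric vector of dissolved O2 (uM), descending.
#' @export
default_o2_grid <- function(n = 200, params = cascade_params()) {
  hi <- headspace_to_dissolved(0.21, params)
  lo <- headspace_to_dissolved(1e-5, params)
  exp(seq(log(hi), log(lo), length.out = n))
}
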