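#' Scenario-resolved steady state for a genotype
#'
#' Computes the steady state a population of the given genotype adopts in an
#' experimental scenario. Monostable scenarios use the unique state. For the
#' `in_planta` scenario the state is selected by the history rule: forward
#' evolution from the genotype's free-living (1% O2) steady state, mimicking
#' bacteria descending the nodule oxygen gradient. The default `"reduced"`
#' method exploits the feed-forward structure of the cascade (exact, fast);
#' `"ode"` integrates the full system with `deSolve` and is retained as a
#' cross-check.
#'
#' @param genotype A `cascade_genotype` or preset name.
#' @param scen A `cascade_scenario` or scenario name.
#' @param params A `cascade_params` object.
#' @param method `"reduced"` (default) or `"ode"`.
#' @return A named cascade state.
#' @export
#' @examples
#' scenario_steady_state("wt", "free_living", default_params())
scenario_steady_state <- function(genotype, scen, params = cascade_params(),
                                  method = c("reduced", "ode")) {
  method <- match.arg(method)
  genotype <- as_genotype(genotype)
  scen <- as_scenario(scen, params)
  if (method == "reduced") {
    return(reduced_scenario_state(scen, params, genotype))
  }
  basal <- cascade_state()
  if (identical(scen$state_selection, "history")) {
    fl <- integrate_to_steady(basal, headspace_to_dissolved(0.01, params),
                              params, genotype)
    if (!fl$converged) stop("free-living steady state did not converge",
                            call. = FALSE)
    res <- integrate_to_steady(fl$state, scen$oxygen$dissolved, params,
                               genotype)
  } else {
    res <- integrate_to_steady(basal, scen$oxygen$dissolved, params, genotype)
  }
  if (!res$converged) stop("steady state did not converge in scenario '",
                           scen$name, "'", call. = FALSE)
  res$state
}

#' Mutant/wild-type expression ratio
#'
#' Ratio (x100, percent of WT) of a reporter promoter's steady-state
#' activity in a mutant versus wild type under the same scenario. The
#' default readout is the instantaneous promoter transcription rate, the
#' quantity a plasmid-borne transcriptional fusion reads out in any genetic
#' background; `readout = "protein"` uses the corresponding protein level
#' instead (identical up to the shared removal rate at steady state).
#'
#' @param genotype Mutant genotype (`cascade_genotype` or preset name).
#' @param reporter `"fnrN"` or `"fixNOQP"`.
#' @param scen Scenario (`cascade_scenario` or name).
#' @param params A `cascade_params` object.
#' @param readout `"rate"` (default) or `"protein"`.
#' @param method Steady-state method, see [scenario_steady_state()].
#' @return Percent of wild type (numeric scalar).
#' @export
#' @examples
#' expression_ratio("hfixL", "fnrN", "free_living", default_params())
expression_ratio <- function(genotype, reporter = c("fnrN", "fixNOQP"),
                             scen = "free_living",
                             params = cascade_params(),
                             readout = c("rate", "protein"),
                             method = c("reduced", "ode")) {
  reporter <- match.arg(reporter)
  readout <- match.arg(readout)
  method <- match.arg(method)
  scen <- as_scenario(scen, params)
  mut <- scenario_steady_state(genotype, scen, params, method)
  wt <- scenario_steady_state("wt", scen, params, method)
  100 * reporter_activity(mut, scen, params, reporter, readout) /
        reporter_activity(wt, scen, params, reporter, readout)
}

reporter_activity <- function(state, scen, params, reporter, readout = "rate") {
  if (readout == "protein") {
    return(switch(reporter, fnrN = state[["N"]], fixNOQP = state[["F"]]))
  }
  r <- promoter_rates(state, scen$oxygen$dissolved, params)
  r[[reporter]]
}

#' Fold induction of a promoter between two oxygen conditions
#'
#' Ratio of steady-state promoter activity at the low-oxygen scenario over
#' the high-oxygen scenario for one genotype, e.g. the ~5-fold microaerobic
#' induction of fixNOQP between 21% and 1% headspace O2 in wild type.
#'
#' @param reporter `"fnrN"` or `"fixNOQP"`.
#' @param genotype A `cascade_genotype` or preset name.
#' @param high_o2,low_o2 Scenarios (`cascade_scenario` or names).
#' @param params A `cascade_params` object.
#' @param method Steady-state method, see [scenario_steady_state()].
#' @return Fold induction (numeric scalar).
#' @export
#' @examples
#' fold_induction("fixNOQP", "wt", "atmospheric", "free_living",
#'                default_params())
fold_induction <- function(reporter = c("fnrN", "fixNOQP"),
                           genotype = "wt",
                           high_o2 = "atmospheric", low_o2 = "free_living",
                           params = cascade_params(),
                           method = c("reduced", "ode")) {
  reporter <- match.arg(reporter)
  method <- match.arg(method)
  high_o2 <- as_scenario(high_o2, params)
  low_o2 <- as_scenario(low_o2, params)
  hi <- reporter_activity(scenario_steady_state(genotype, high_o2, params,
                                                method),
                          high_o2, params, reporter)
  lo <- reporter_activity(scenario_steady_state(genotype, low_o2, params,
                                                method),
                          low_o2, params, reporter)
  if (hi <= 0) stop("high-O2 promoter activity is zero; cannot form a fold",
                    call. = FALSE)
  lo / hi
}

#' Nodule oxygen gradient specification
#'
#' Maps normalised position along the nodule axis (0 = infection-thread tip,
#' 1 = root-proximal nitrogen-fixing core) onto dissolved O2 with log-linear
#' interpolation between the tip and core concentrations.
#'
#' @param n Number of positions.
#' @param o2_tip Dissolved O2 at the tip (uM); default 12 uM, where hFixL is
#'   half-active (zone I activity of the hFixL pathway).
#' @param o2_core Dissolved O2 at the core (uM); default 30 nM, inside the
#'   reported 20-50 nM range of the fixation zone.
#' @return A tibble with columns `position` and `oxygen`.
#' @export
nodule_gradient <- function(n = 100, o2_tip = 12, o2_core = 0.03) {
  stopifnot(n >= 2, o2_tip > o2_core, o2_core > 0)
  position <- seq(0, 1, length.out = n)
  tibble::tibble(position = position,
                 oxygen = exp(log(o2_tip) + position *
                                (log(o2_core) - log(o2_tip))))
}

#' Spatial expression profile along the nodule oxygen gradient
#'
#' Steady-state promoter activities of fnrN and fixNOQP at each position of
#' a prescribed nodule oxygen gradient. The history rule is applied from the
#' tip inward: each position's state is the one reached by forward evolution
#' from the previous (more aerobic) position's state, so bistable genotypes
#' retain their branch as they descend the gradient. Deterministic given the
#' parameters and gradient.
#'
#' @param genotype A `cascade_genotype` or preset name.
#' @param params A `cascade_params` object.
#' @param gradient A gradient tibble from [nodule_gradient()].
#' @return A tibble of class `zone_profile`, one row per (position,
#'   reporter): columns `position`, `oxygen`, `reporter`, `activity`.
#' @export
#' @examples
#' prof <- nodule_zone_profile("wt", default_params(), nodule_gradient(40))
nodule_zone_profile <- function(genotype, params = cascade_params(),
                                gradient = nodule_gradient()) {
  genotype <- as_genotype(genotype)
  stopifnot(all(c("position", "oxygen") %in% names(gradient)))
  if (is.unsorted(rev(gradient$oxygen), strictly = TRUE)) {
    stop("gradient oxygen must be strictly decreasing along the axis",
         call. = FALSE)
  }
  p <- params
  n <- nrow(gradient)
  states <- vector("list", n)
  rr0 <- reduced_n_roots(gradient$oxygen[1], p, genotype)
  N_prev <- min(rr0$roots[rr0$stable])
  for (i in seq_len(n)) {
    st <- reduced_history_state(gradient$oxygen[i], p, genotype,
                                from_N = N_prev)
    states[[i]] <- st
    N_prev <- st[["N"]]
  }
  rates <- lapply(seq_len(n), function(i) {
    promoter_rates(states[[i]], gradient$oxygen[i], p)
  })
  out <- tidyr::expand_grid(idx = seq_len(n),
                            reporter = c("fnrN", "fixNOQP")) |>
    dplyr::mutate(position = gradient$position[.data$idx],
                  oxygen = gradient$oxygen[.data$idx],
                  activity = purrr::map2_dbl(.data$idx, .data$reporter,
                                             ~ rates[[.x]][[.y]])) |>
    dplyr::select("position", "oxygen", "reporter", "activity")
  class(out) <- c("zone_profile", class(out))
  attr(out, "genotype") <- genotype
  out
}

#' Onset steepness of a spatial expression profile
#'
#' Summarises how abruptly a reporter switches on along the nodule axis: the
#' maximum spatial derivative of min-max normalised expression, and the
#' position where it occurs. Wild-type fixNOQP turns on abruptly at the
#' II-III interzone, whereas the hfixL knockout rises gradually.
#'
#' @param profile A `zone_profile` from [nodule_zone_profile()].
#' @return A tibble with one row per reporter: `reporter`, `steepness`
#'   (per unit nodule axis), `position` of the steepest rise.
#' @export
onset_steepness <- function(profile) {
  stopifnot(inherits(profile, "zone_profile"))
  profile |>
    dplyr::group_by(.data$reporter) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::summarise(steepness = {
      rng <- range(.data$activity)
      z <- if (diff(rng) > 0) (.data$activity - rng[1]) / diff(rng)
           else .data$activity * 0
      max(diff(z) / diff(.data$position))
    }, position = {
      rng <- range(.data$activity)
      z <- if (diff(rng) > 0) (.data$activity - rng[1]) / diff(rng)
           else .data$activity * 0
      d <- diff(z) / diff(.data$position)
      mid <- (.data$position[-1] + .data$position[-length(.data$position)]) / 2
      mid[which.max(d)]
    }, .groups = "drop")
}
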