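#' Kinetic and affinity parameters of the oxygen-response cascade
#'
#' Construct the full parameter set of the five-species hFixL-FxkR-FixK /
#' FnrN cascade model. Dissolved oxygen is measured in micromolar; protein
#' concentrations are in arbitrary units whose scale is fixed by the
#' calibration (all model outputs are reported as percentages of wild type).
#' Time is nondimensionalised by the shared first-order removal rate, so the
#' shipped default has `delta = 1`.
#'
#' @param henry_constant Dissolved O2 per atmosphere of headspace O2 at
#'   equilibrium, in uM/atm. The default 1200 uM/atm makes a 1% headspace
#'   correspond to 12 uM and 0.01% to 120 nM dissolved O2.
#' @param K_L O2 concentration (uM) at which half the hFixL pool is active.
#' @param n_L Hill coefficient of hFixL-O2 binding (cooperative, default 2).
#' @param K_NO2 O2 concentration (uM) at which half the FnrN pool is active.
#' @param n_NO2 Hill coefficient of FnrN-O2 inactivation (default 1).
#' @param beta_L,beta_R Constitutive synthesis rates of hFixL and FxkR.
#' @param alpha_K,alpha_N,alpha_F Basal (leaky) transcription rates of
#'   fixK, fnrN and fixNOQP.
#' @param beta_K,beta_N,beta_F Maximal regulated transcription rates of
#'   fixK, fnrN and fixNOQP.
#' @param delta Shared first-order removal (dilution/turnover) rate.
#' @param K_RK Half-saturation of K-box induction by active (phosphorylated)
#'   FxkR.
#' @param A_K_dist,A_N_dist Anaerobox half-saturation constants of FixK and
#'   FnrN at the fnrN distal (activating) box. FnrN binds anaeroboxes more
#'   tightly than FixK, so `A_N_dist < A_K_dist` is required.
#' @param A_K_fix,A_N_fix Anaerobox half-saturation constants of FixK and
#'   FnrN at the fixNOQP operator. The two operators share the consensus
#'   motif but sit in different promoter contexts, and the knockout ratio
#'   data cannot be reproduced with a single shared pair; `A_N_fix <
#'   A_K_fix` is required likewise.
#' @param rho_K,rho_N Multiplicative affinity penalties (> 1) of the
#'   proximal, sterically repressing anaerobox of the fnrN promoter relative
#'   to the distal activating box.
#' @param n_DNA Hill coefficient of FixK/FnrN DNA binding (dimers, default 2).
#'
#' @return An object of class `cascade_params`: a named list of validated
#'   numeric parameters.
#' @seealso [default_params()] for the shipped calibrated set,
#'   [read_params()] and [write_params()] for file round-trips.
#' @export
#' @examples
#' p <- cascade_params()
#' p$K_L
cascade_params <- function(henry_constant = 1200,
                           K_L = 12, n_L = 2,
                           K_NO2 = 0.12, n_NO2 = 1,
                           beta_L = 1, beta_R = 1,
                           alpha_K = 0.02, beta_K = 1,
                           alpha_N = 0.02, beta_N = 1,
                           alpha_F = 0.02, beta_F = 1,
                           delta = 1,
                           K_RK = 0.1,
                           A_K_dist = 1, A_N_dist = 0.05,
                           A_K_fix = 1, A_N_fix = 0.05,
                           rho_K = 4, rho_N = 4,
                           n_DNA = 2) {
  p <- list(henry_constant = henry_constant,
            K_L = K_L, n_L = n_L,
            K_NO2 = K_NO2, n_NO2 = n_NO2,
            beta_L = beta_L, beta_R = beta_R,
            alpha_K = alpha_K, beta_K = beta_K,
            alpha_N = alpha_N, beta_N = beta_N,
            alpha_F = alpha_F, beta_F = beta_F,
            delta = delta, K_RK = K_RK,
            A_K_dist = A_K_dist, A_N_dist = A_N_dist,
            A_K_fix = A_K_fix, A_N_fix = A_N_fix,
            rho_K = rho_K, rho_N = rho_N,
            n_DNA = n_DNA)
  validate_params(p)
  structure(p, class = "cascade_params")
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("non-numeric or non-scalar parameter(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  pos <- vapply(p, function(x) x > 0, logical(1))
  if (!all(pos)) {
    stop("all cascade parameters must be strictly positive; offending: ",
         paste(names(p)[!pos], collapse = ", "), call. = FALSE)
  }
  if (p$A_N_dist >= p$A_K_dist || p$A_N_fix >= p$A_K_fix) {
    stop("A_N must be smaller than A_K at each anaerobox ",
         "(FnrN binds anaeroboxes more tightly than FixK)", call. = FALSE)
  }
  if (p$rho_K <= 1 || p$rho_N <= 1) {
    stop("rho_K and rho_N are affinity penalties and must exceed 1",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("<cascade_params>\n")
  v <- unlist(x)
  out <- format(v, digits = 6, scientific = FALSE)
  for (i in seq_along(v)) cat(sprintf("  %-14s %s\n", names(v)[i], out[i]))
  invisible(x)
}

#' Shipped calibrated parameter set
#'
#' Loads the parameter set calibrated against the built-in mutant/wild-type
#' expression-ratio table (see [builtin_ratio_table()] and
#' [calibrate_cascade()]). This set reproduces the free-living and bacteroid
#' knockout ratios, the wild-type fixNOQP fold induction of about 5 between
#' 21% and 1% O2, monostability of the wild-type sweep and a bistable window
#' below 120 nM dissolved O2 for the hfixL knockout.
#'
#' @return A `cascade_params` object.
#' @export
#' @examples
#' default_params()$K_L
default_params <- function() {
  path <- system.file("extdata", "params_default.yaml", package = "fixcascade")
  if (!nzchar(path)) stop("shipped default parameter file not found")
  read_params(path)
}

#' Read and write parameter files
#'
#' Parameter sets serialise to a flat declarative YAML mapping of parameter
#' name to value. Unknown keys are rejected with an error naming the key.
#'
#' @param path File path.
#' @param params A `cascade_params` object.
#' @return `read_params()` returns a `cascade_params`; `write_params()`
#'   invisibly returns `path`.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- formals(cascade_params)
  unknown <- setdiff(names(raw), names(template))
  if (length(unknown)) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(cascade_params, lapply(raw, as.numeric))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cascade_params"))
  yaml::write_yaml(lapply(unclass(params), function(x) unname(x)), path)
  invisible(path)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named parameters replaced, re-running
#' validation.
#'
#' @param params A `cascade_params` object.
#' @param ... Named scalar replacements, e.g. `K_L = 10`.
#' @return A `cascade_params` object.
#' @export
#' @examples
#' p <- update_params(default_params(), K_RK = 0.2)
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cascade_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_params(p)
  structure(p, class = "cascade_params")
}

#' Rescale the protein concentration unit
#'
#' Protein concentrations in the model are in arbitrary units. Rescaling
#' that unit by a factor `s` multiplies every synthesis rate and every
#' protein half-saturation constant (`K_RK`, `A_K_dist`, `A_N_dist`) by `s`
#' while leaving oxygen-side parameters untouched. All mutant/wild-type
#' ratios and fold inductions are invariant under this rescaling.
#'
#' @param params A `cascade_params` object.
#' @param s Positive scale factor.
#' @return A `cascade_params` object.
#' @export
rescale_concentration_unit <- function(params, s) {
  stopifnot(inherits(params, "cascade_params"), is.numeric(s), s > 0)
  update_params(params,
                beta_L = params$beta_L * s, beta_R = params$beta_R * s,
                alpha_K = params$alpha_K * s, beta_K = params$beta_K * s,
                alpha_N = params$alpha_N * s, beta_N = params$beta_N * s,
                alpha_F = params$alpha_F * s, beta_F = params$beta_F * s,
                K_RK = params$K_RK * s,
                A_K_dist = params$A_K_dist * s,
                A_N_dist = params$A_N_dist * s,
                A_K_fix = params$A_K_fix * s,
                A_N_fix = params$A_N_fix * s)
}
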