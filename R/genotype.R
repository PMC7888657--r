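#' Genotypes: which cascade genes are functional
#'
#' A genotype records which of the four regulator genes carry a functional
#' copy. Knocking a gene out zeroes its synthesis rate in the dynamics and
#' nothing else; reporter fusions remain readable in any background because
#' promoter activity is computed from the regulator levels, not from the
#' knocked-out gene itself.
#'
#' Presets mirror the experimental strains: `"wt"`, `"fnrN"` (fnrN::Omega
#' insertion), `"hfixL"` (double hfixL knockout; the model carries a single
#' hfixL copy), `"fxkR"`, and `"hfixL_fnrN"` (triple mutant lacking both
#' sensor inputs).
#'
#' @param preset Character preset name, or `NULL` to use the logical flags.
#' @param hfixl,fxkr,fixk,fnrn Logical; is the gene functional?
#' @return An object of class `cascade_genotype`.
#' @export
#' @examples
#' genotype("hfixL")
#' genotype(hfixl = FALSE, fnrn = FALSE)
genotype <- function(preset = NULL, hfixl = TRUE, fxkr = TRUE,
                     fixk = TRUE, fnrn = TRUE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("wt", "fnrN", "hfixL", "fxkR", "hfixL_fnrN"))
    hfixl <- !(preset %in% c("hfixL", "hfixL_fnrN"))
    fxkr <- preset != "fxkR"
    fixk <- TRUE
    fnrn <- !(preset %in% c("fnrN", "hfixL_fnrN"))
  }
  stopifnot(is.logical(hfixl), is.logical(fxkr),
            is.logical(fixk), is.logical(fnrn))
  structure(list(hfixl_functional = hfixl, fxkr_functional = fxkr,
                 fixk_functional = fixk, fnrn_functional = fnrn),
            class = "cascade_genotype",
            label = genotype_label(hfixl, fxkr, fixk, fnrn))
}

genotype_label <- function(hfixl, fxkr, fixk, fnrn) {
  ko <- c("hfixL", "fxkR", "fixK", "fnrN")[!c(hfixl, fxkr, fixk, fnrn)]
  if (!length(ko)) "wt" else paste(ko, collapse = "_")
}

#' @export
print.cascade_genotype <- function(x, ...) {
  cat("<cascade_genotype>", attr(x, "label"), "\n")
  invisible(x)
}

as_genotype <- function(x) {
  if (inherits(x, "cascade_genotype")) return(x)
  if (is.character(x) && length(x) == 1) return(genotype(x))
  stop("expected a cascade_genotype or a preset name", call. = FALSE)
}
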