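#' Published reference parameter estimates
#'
#' Bundled tables of published memory-chain parameter estimates for classic
#' retrograde-amnesia studies, shipped as plain CSV under `inst/extdata`.
#'
#' `animal_study_fits()` returns two-store fits to prospective animal
#' lesion/transgenic studies (mice, rats, monkeys): acquired intensity
#' `mu1`, consolidation rate `mu2`, MTL decline rate `a1` (with `a2 = 0`
#' and full lesions assumed), the reported `R^2`, and the expected MTL
#' trace lifetime in days. `human_study_fits()` returns rr-gradient fits to
#' retrospective patient studies (Korsakoff, transient global amnesia,
#' hypoxia, ECT, ...): `a1`, `mu2`, lesion fraction `lambda`, `R^2`, SSE.
#'
#' These are reference values for comparison and examples; the underlying
#' raw data points were published only as figures and are not included.
#'
#' @return A data frame.
#' @examples
#' af <- animal_study_fits()
#' all.equal(round(mtl_lifetime(af$a1), 1), af$mtl_lifetime_days,
#'           tolerance = 0.11 / min(af$mtl_lifetime_days))
#' @export
animal_study_fits <- function() {
  utils::read.csv(system.file("extdata", "animal_study_fits.csv",
                              package = "memorychain"),
                  stringsAsFactors = FALSE)
}

#' @rdname animal_study_fits
#' @export
human_study_fits <- function() {
  utils::read.csv(system.file("extdata", "human_study_fits.csv",
                              package = "memorychain"),
                  stringsAsFactors = FALSE)
}
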