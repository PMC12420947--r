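# Unit conventions: mm - Pa - s everywhere inside the package.

#' Unit conversion helpers
#'
#' The package works internally in a millimetre--Pascal--second system.
#' Pressures quoted in mmHg at the user interface are converted with
#' 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(100)   # 13332.2
#' pa_to_mmhg(13332.2)
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

# kPa -> Pa (material constants are quoted in kPa)
kpa_to_pa <- function(x) x * 1000
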