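#' Temperature scale conversions
#'
#' All internal computation is in kelvin; results are usually presented in
#' degrees Celsius to match clinical convention (body temperature 37 C,
#' hyperthermia window 41-47 C).
#'
#' @param x Temperature(s) in Celsius (`C_to_K`) or kelvin (`K_to_C`).
#' @return Converted temperature(s).
#' @export
C_to_K <- function(x) x + 273.15

#' @rdname C_to_K
#' @export
K_to_C <- function(x) x - 273.15
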