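#' Pressure unit conversions
#'
#' Clinical intraocular pressure is quoted in mmHg while the constitutive
#' models and the solver work in MPa. The fixed conversion constant is
#' 1 mmHg = 1.33322e-4 MPa.
#'
#' @param x pressure values.
#' @return converted pressure values.
#' @export
mmhg_to_mpa <- function(x) x * 1.33322e-4

#' @rdname mmhg_to_mpa
#' @export
mpa_to_mmhg <- function(x) x / 1.33322e-4

# default overflow cap on k2*<E>^2 in the fiber exponential
.default_cap <- 50
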