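#' Unit conversions used at package interfaces
#'
#' Internally the package works in SI seconds and becquerel; microcurie and
#' minutes are accepted at interfaces and converted exactly (1 uCi = 3.7e4 Bq).
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @examples
#' uCi_to_Bq(1)      # 37000
#' Bq_to_uCi(3.7e4)  # 1
#' @export
uCi_to_Bq <- function(x) x * 3.7e4

#' @rdname uCi_to_Bq
#' @export
Bq_to_uCi <- function(x) x / 3.7e4

#' @rdname uCi_to_Bq
#' @export
min_to_s <- function(x) x * 60

#' @rdname uCi_to_Bq
#' @export
s_to_min <- function(x) x / 60

# internal: lognormal sigma giving an exact coefficient of variation `cv`
lognormal_sigma <- function(cv) {
  stopifnot(cv >= 0)
  sqrt(log(1 + cv^2))
}
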