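#' Convert temperatures to degrees Celsius
#'
#' The package works in degrees Celsius internally; Kelvin is accepted only at
#' ingest (CMIP6 NetCDF/CSV exports carry `tasmax`/`tasmin` in Kelvin).
#'
#' @param values numeric vector of temperatures.
#' @param input_unit `"K"` or `"C"`.
#' @return numeric vector in degrees Celsius, same length as `values`.
#' @examples
#' to_celsius(c(273.15, 300), "K")
#' @export
to_celsius <- function(values, input_unit = c("C", "K")) {
  if (length(input_unit) != 1L || !input_unit %in% c("C", "K")) {
    stop("unknown temperature unit: '", paste(input_unit, collapse = ","),
         "' (expected \"K\" or \"C\")")
  }
  if (input_unit == "K") values - 273.15 else values
}
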