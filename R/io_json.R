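## JSON configuration interfaces for models, protocols and factor sets.

gate_to_list <- function(g) {
  list(pH50 = g$pH50, n = g$hill_n, tau_alk = g$tau_alkaline,
       tau_acid = g$tau_acidic, tau_pH50 = g$tau_pH50, tau_n = g$tau_hill_n)
}

gate_from_list <- function(l) {
  gate_parameters(l$pH50, l$n, l$tau_alk, l$tau_acid, l$tau_pH50, l$tau_n)
}

#' Write / read a channel model as JSON
#'
#' Schema: `{activation: {pH50, n, tau_alk, tau_acid, tau_pH50, tau_n},
#' sensitization: {...}, current_scale, current_sign}`.
#'
#' @param model an [channel_model()].
#' @param path JSON file path.
#' @return `read_channel_model` returns an `asic_model`;
#'   `write_channel_model` returns the path invisibly.
#' @export
write_channel_model <- function(model, path) {
  stopifnot(inherits(model, "asic_model"))
  jsonlite::write_json(list(activation = gate_to_list(model$activation),
                            sensitization = gate_to_list(model$sensitization),
                            current_scale = model$current_scale,
                            current_sign = model$current_sign),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_model
#' @export
read_channel_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_model(gate_from_list(l$activation), gate_from_list(l$sensitization),
                current_scale = l$current_scale,
                current_sign = l$current_sign)
}

#' Write / read a pH protocol as JSON
#'
#' Schema: `{conditioning_pH, fall_time_s, dt_s,
#' segments: [{duration_s, pH}, ...]}`.
#'
#' @param protocol a [ph_protocol()].
#' @param path JSON file path.
#' @return `read_ph_protocol` returns a `ph_protocol`;
#'   `write_ph_protocol` returns the path invisibly.
#' @export
write_ph_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "ph_protocol"))
  jsonlite::write_json(list(conditioning_pH = protocol$conditioning_pH,
                            fall_time_s = protocol$fall_time,
                            dt_s = protocol$dt,
                            segments = protocol$segments),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ph_protocol
#' @export
read_ph_protocol <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph_protocol(as.data.frame(l$segments), conditioning_pH = l$conditioning_pH,
              fall_time = l$fall_time_s, dt = l$dt_s)
}

#' Write an estimated factor set as JSON
#'
#' Schema: `{F_C, F_O, F_CD, F_OD, pattern, warnings}`.
#'
#' @param factors a [fluorescence_factors()] object (typically from
#'   [estimate_factors()], whose pattern and warnings are carried along).
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_factors <- function(factors, path) {
  stopifnot(inherits(factors, "vcf_factors"))
  jsonlite::write_json(c(unclass(factors),
                         list(pattern = attr(factors, "pattern"),
                              warnings = as.list(attr(factors, "warnings")))),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
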