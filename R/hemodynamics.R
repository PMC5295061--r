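# Indicator-dilution plasma flow and bicarbonate-phase CO2 kinetics.

#' Infusion protocol description
#'
#' Describes the three primed-continuous infusates of the standard limb
#' tracer protocol: NaH13CO3 (jugular vein, 0-2 h) to estimate CO2
#' production, \[1-13C\]leucine (jugular vein, 2-8 h) for leucine kinetics,
#' and PAH (femoral artery, from -1 h through the experiment) for plasma
#' flow by indicator dilution. Defaults carry the conventional primes and
#' rates (bicarbonate 7.5 umol/kg prime + 10 umol/kg/h; leucine 10 umol/kg
#' prime + 10 umol/kg/h; PAH 19.1 mL prime + 0.788 mL/min). The PAH solution
#' concentration (mg/mL) is required to convert the volumetric rate to a
#' mass rate; the default of 20 mg/mL is a package convention, not a
#' published value.
#'
#' @param bicarb_prime,bicarb_rate NaH13CO3 prime (umol/kg) and continuous
#'   rate (umol/kg/h).
#' @param bicarb_window Active window (h) of the bicarbonate infusion.
#' @param leucine_prime,leucine_rate \[1-13C\]leucine prime (umol/kg) and
#'   rate (umol/kg/h).
#' @param leucine_window Active window (h) of the leucine infusion.
#' @param pah_prime_ml,pah_rate_ml_min PAH prime (mL) and rate (mL/min).
#' @param pah_conc_mg_ml PAH solution concentration (mg/mL).
#' @param pah_window Active window (h) of the PAH infusion.
#' @return An `infusion_protocol` list with one element per infusate.
#' @export
infusion_protocol <- function(bicarb_prime = 7.5, bicarb_rate = 10,
                              bicarb_window = c(0, 2),
                              leucine_prime = 10, leucine_rate = 10,
                              leucine_window = c(2, 8),
                              pah_prime_ml = 19.1, pah_rate_ml_min = 0.788,
                              pah_conc_mg_ml = 20, pah_window = c(-1, 8)) {
  check_window <- function(w, what) {
    if (length(w) != 2 || w[1] >= w[2]) {
      leuflux_abort(sprintf("%s window must be [start, end] with start < end", what),
                    "format")
    }
  }
  check_window(bicarb_window, "bicarbonate")
  check_window(leucine_window, "leucine")
  check_window(pah_window, "PAH")
  if (bicarb_rate <= 0 || leucine_rate <= 0 || pah_rate_ml_min <= 0) {
    leuflux_abort("infusion rates must be positive", "format")
  }
  if (is.null(pah_conc_mg_ml) || !is.finite(pah_conc_mg_ml) || pah_conc_mg_ml <= 0) {
    leuflux_abort("PAH solution concentration (mg/mL) is required and must be positive",
                  "format")
  }
  structure(list(
    NaH13CO3 = list(prime = bicarb_prime, rate = bicarb_rate,
                    route = "jugular_vein", window = bicarb_window),
    leucine_1_13C = list(prime = leucine_prime, rate = leucine_rate,
                         route = "jugular_vein", window = leucine_window),
    PAH = list(prime_ml = pah_prime_ml, rate_ml_min = pah_rate_ml_min,
               conc_mg_ml = pah_conc_mg_ml, route = "femoral_artery",
               window = pah_window)
  ), class = "infusion_protocol")
}

#' @export
print.infusion_protocol <- function(x, ...) {
  cat("Infusion protocol:\n")
  cat(sprintf("  NaH13CO3:  prime %g umol/kg, %g umol/kg/h, %s, %g-%g h\n",
              x$NaH13CO3$prime, x$NaH13CO3$rate, x$NaH13CO3$route,
              x$NaH13CO3$window[1], x$NaH13CO3$window[2]))
  cat(sprintf("  [1-13C]leucine: prime %g umol/kg, %g umol/kg/h, %s, %g-%g h\n",
              x$leucine_1_13C$prime, x$leucine_1_13C$rate, x$leucine_1_13C$route,
              x$leucine_1_13C$window[1], x$leucine_1_13C$window[2]))
  cat(sprintf("  PAH:       prime %g mL, %g mL/min at %g mg/mL (%g mg/h), %s, %g-%g h\n",
              x$PAH$prime_ml, x$PAH$rate_ml_min, x$PAH$conc_mg_ml,
              pah_infusion_mg_h(x), x$PAH$route, x$PAH$window[1], x$PAH$window[2]))
  invisible(x)
}

#' PAH mass infusion rate
#'
#' Converts the volumetric PAH infusion (mL/min at a solution concentration
#' in mg/mL) to a mass rate: `mg/h = mL/min * 60 * mg/mL`.
#'
#' @param protocol An [infusion_protocol()].
#' @return PAH infusion rate in mg/h.
#' @export
pah_infusion_mg_h <- function(protocol) {
  protocol$PAH$rate_ml_min * 60 * protocol$PAH$conc_mg_ml
}

#' Read or write an infusion protocol file
#'
#' JSON or YAML, chosen by file extension. Fields mirror the arguments of
#' [infusion_protocol()].
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return [read_protocol()] returns an `infusion_protocol`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) leuflux_abort(sprintf("no such file: %s", path), "io")
  ext <- tolower(tools::file_ext(path))
  spec <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    leuflux_abort("protocol file must be .json or .yaml", "format"))
  do.call(infusion_protocol, spec)
}

#' @rdname read_protocol
#' @param protocol An `infusion_protocol` to serialize.
#' @export
write_protocol <- function(protocol, path) {
  fields <- list(
    bicarb_prime = protocol$NaH13CO3$prime, bicarb_rate = protocol$NaH13CO3$rate,
    bicarb_window = protocol$NaH13CO3$window,
    leucine_prime = protocol$leucine_1_13C$prime,
    leucine_rate = protocol$leucine_1_13C$rate,
    leucine_window = protocol$leucine_1_13C$window,
    pah_prime_ml = protocol$PAH$prime_ml,
    pah_rate_ml_min = protocol$PAH$rate_ml_min,
    pah_conc_mg_ml = protocol$PAH$conc_mg_ml,
    pah_window = protocol$PAH$window)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(fields, path, auto_unbox = FALSE, digits = NA)
  } else {
    yaml::write_yaml(fields, path)
  }
  invisible(path)
}

#' Plasma flow across the limb by PAH indicator dilution
#'
#' PAH infused upstream into the femoral artery is diluted by limb plasma
#' flow, so the venous concentration exceeds the (carotid) arterial one and
#' `PF = infusion / (c_ven - c_art) / body_weight`.
#'
#' @param pah_infusion PAH infusion rate, mg/h.
#' @param c_art,c_ven Arterial and venous plasma PAH concentrations, mg/L.
#' @param body_weight Body weight, kg.
#' @return Plasma flow in L/kg/h.
#' @export
plasma_flow_pah <- function(pah_infusion, c_art, c_ven, body_weight) {
  if (any(body_weight <= 0)) leuflux_abort("body weight must be positive", "format")
  if (any(pah_infusion <= 0)) leuflux_abort("PAH infusion must be positive", "format")
  if (any(c_ven <= c_art)) {
    leuflux_abort("venous PAH must exceed arterial PAH (no dilution signal)",
                  "no_dilution")
  }
  pah_infusion / (c_ven - c_art) / body_weight
}

#' Whole-body CO2 production from the bicarbonate tracer
#'
#' Tracer dilution at isotopic steady state:
#' `Ra_CO2 = bicarbonate infusion rate / arterial 13CO2 enrichment`.
#'
#' @param bicarb_rate NaH13CO3 infusion rate, umol/kg/h.
#' @param e_co2_art Arterial 13CO2 enrichment, fraction.
#' @return CO2 production rate, umol/kg/h.
#' @export
whole_body_co2_production <- function(bicarb_rate, e_co2_art) {
  if (any(e_co2_art <= 0)) {
    leuflux_abort("arterial CO2 enrichment must be positive", "division_guard")
  }
  bicarb_rate / e_co2_art
}

#' Labeled CO2 release across the limb
#'
#' Arteriovenous balance of labeled CO2:
#' `F13CO2 = PF * (c_ven * e_ven - c_art * e_art)` (umol/kg/h). Negative
#' values (venous labeled content below arterial) are propagated and
#' flagged via the `"negative"` attribute.
#'
#' @param pf Plasma flow, L/kg/h.
#' @param c_co2_art,c_co2_ven CO2 concentrations, umol/L.
#' @param e_art,e_ven 13CO2 enrichments, fraction.
#' @return Labeled CO2 release, umol/kg/h (tracer units).
#' @export
limb_13co2_release <- function(pf, c_co2_art, e_art, c_co2_ven, e_ven) {
  check_numeric(c(c_co2_art, c_co2_ven), "CO2 concentrations", lower = 0)
  check_numeric(c(e_art, e_ven), "CO2 enrichments", lower = 0)
  out <- pf * (c_co2_ven * e_ven - c_co2_art * e_art)
  structure(out, negative = out < 0)
}
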