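# Indirect-calorimetry trace analysis: light/dark partitioning and
# per-phase VO2 / VCO2 / RER / energy-expenditure summaries.

#' Calorimetry trace container
#'
#' An ordered respirometry trace with the chamber's light schedule and the
#' animal's body mass. VO2/VCO2 are mass-specific (mL/kg/h), the convention
#' of CLAMS-style systems.
#'
#' @param samples data.frame with columns `time` (POSIXct, strictly
#'   increasing), `vo2`, `vco2` (mL/kg/h, >= 0), and optionally
#'   `activity` (counts) and `food_g` (g).
#' @param lights_on,lights_off clock times `"HH:MM"` (or `"HH:MM:SS"`);
#'   the light (diurnal) phase is `[lights_on, lights_off)`, wrap-around
#'   schedules allowed.
#' @param body_mass_g body mass in grams.
#' @return object of class `calorimetry_trace`.
#' @export
calorimetry_trace <- function(samples, lights_on = "06:00",
                              lights_off = "18:00", body_mass_g = 30) {
  stopifnot(is.data.frame(samples),
            all(c("time", "vo2", "vco2") %in% names(samples)))
  if (!inherits(samples$time, "POSIXct"))
    stop("samples$time must be POSIXct")
  if (is.unsorted(as.numeric(samples$time), strictly = TRUE))
    stop("timestamps must be strictly increasing")
  if (any(samples$vo2 < 0) || any(samples$vco2 < 0))
    stop("vo2/vco2 must be >= 0")
  if (!"activity" %in% names(samples)) samples$activity <- 0
  if (!"food_g" %in% names(samples)) samples$food_g <- 0
  if (body_mass_g <= 0) stop("body_mass_g must be positive")
  structure(list(samples = samples,
                 lights_on = lights_on, lights_off = lights_off,
                 body_mass_g = body_mass_g),
            class = "calorimetry_trace")
}

#' @export
print.calorimetry_trace <- function(x, ...) {
  cat(sprintf("<calorimetry_trace> %d samples, lights %s-%s, %.1f g\n",
              nrow(x$samples), x$lights_on, x$lights_off, x$body_mass_g))
  invisible(x)
}

# "HH:MM[:SS]" -> seconds since midnight
clock_seconds <- function(s) {
  parts <- as.numeric(strsplit(s, ":")[[1]])
  if (length(parts) == 2L) parts <- c(parts, 0)
  parts[1] * 3600 + parts[2] * 60 + parts[3]
}

#' Label trace samples as diurnal (light) or nocturnal (dark)
#'
#' A sample is diurnal iff its clock time falls in the half-open interval
#' `[lights_on, lights_off)`; otherwise nocturnal. Schedules crossing
#' midnight are handled.
#'
#' @param trace a [calorimetry_trace()].
#' @return factor of `"diurnal"` / `"nocturnal"`, one per sample.
#' @export
partition_cycles <- function(trace) {
  stopifnot(inherits(trace, "calorimetry_trace"))
  on <- clock_seconds(trace$lights_on)
  off <- clock_seconds(trace$lights_off)
  if (on == off)
    adp_error("lights_on equals lights_off: invalid schedule",
              "invalid_schedule")
  tt <- trace$samples$time
  lt <- as.POSIXlt(tt)
  secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
  light <- if (on < off) secs >= on & secs < off else secs >= on | secs < off
  factor(ifelse(light, "diurnal", "nocturnal"),
         levels = c("diurnal", "nocturnal"))
}

#' Respiratory exchange ratio
#'
#' `RER = VCO2 / VO2`; near 0.7 for pure fat oxidation, near 1.0 for pure
#' carbohydrate oxidation.
#'
#' @param vo2,vco2 gas exchange rates in matching units; `vo2` must be
#'   strictly positive.
#' @return numeric vector of ratios.
#' @export
compute_rer <- function(vo2, vco2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0))
    adp_error("RER undefined for vo2 <= 0", "undefined_rer")
  vco2 / vo2
}

#' Energy expenditure from gas exchange
#'
#' Converts mass-specific VO2/VCO2 (mL/kg/h) to absolute L/h via the body
#' mass, then applies a calorimetric equation:
#' \describe{
#'   \item{lusk}{`EE (kcal/h) = 3.815 * VO2 + 1.232 * VCO2` — equivalently
#'     `(3.815 + 1.232 * RER) * VO2` — the Lusk-type equation implemented by
#'     CLAMS-class analysis software.}
#'   \item{weir}{`EE (kcal/h) = 3.941 * VO2 + 1.106 * VCO2`, the abbreviated
#'     Weir equation without urinary nitrogen.}
#' }
#'
#' @param vo2,vco2 mass-specific rates (mL/kg/h).
#' @param body_mass_g body mass in grams.
#' @param formula `"lusk"` (default) or `"weir"`.
#' @return energy expenditure in kcal/h.
#' @export
compute_ee <- function(vo2, vco2, body_mass_g, formula = c("lusk", "weir")) {
  formula <- match.arg(formula)
  if (any(!is.finite(vo2)) || any(vo2 <= 0))
    adp_error("energy expenditure undefined for vo2 <= 0", "undefined_rer")
  if (body_mass_g <= 0) stop("body_mass_g must be positive")
  # mL/kg/h * kg / 1000 -> L/h
  vo2_lh <- vo2 * (body_mass_g / 1000) / 1000
  vco2_lh <- vco2 * (body_mass_g / 1000) / 1000
  co <- if (formula == "lusk") c(3.815, 1.232) else c(3.941, 1.106)
  co[1] * vo2_lh + co[2] * vco2_lh
}

#' Per-phase summaries of a calorimetry trace
#'
#' Arithmetic means of VO2, VCO2, RER and energy expenditure plus totals of
#' activity and food intake, separately for the diurnal and nocturnal
#' phases. Optionally drops an initial acclimatization window.
#'
#' @param trace a [calorimetry_trace()].
#' @param labels phase labels from [partition_cycles()]; recomputed when
#'   `NULL`.
#' @param ee_formula passed to [compute_ee()].
#' @param drop_acclimation_h drop samples within this many hours of the
#'   first timestamp (default 0).
#' @return data.frame with one row per phase: phase, n_samples, mean_vo2,
#'   mean_vco2, mean_rer, mean_ee_kcal_h, total_activity, total_food_g.
#' @export
summarize_cycles <- function(trace, labels = NULL,
                             ee_formula = c("lusk", "weir"),
                             drop_acclimation_h = 0) {
  stopifnot(inherits(trace, "calorimetry_trace"))
  ee_formula <- match.arg(ee_formula)
  if (is.null(labels)) labels <- partition_cycles(trace)
  s <- trace$samples
  stopifnot(length(labels) == nrow(s))
  if (drop_acclimation_h > 0) {
    keep <- as.numeric(s$time) - as.numeric(s$time[1]) >=
      drop_acclimation_h * 3600
    s <- s[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  out <- lapply(levels(labels), function(ph) {
    idx <- labels == ph
    if (!any(idx)) {
      warning("no samples in the ", ph, " phase; phase omitted")
      return(NULL)
    }
    x <- s[idx, , drop = FALSE]
    data.frame(phase = ph,
               n_samples = nrow(x),
               mean_vo2 = mean(x$vo2),
               mean_vco2 = mean(x$vco2),
               mean_rer = mean(compute_rer(x$vo2, x$vco2)),
               mean_ee_kcal_h = mean(compute_ee(x$vo2, x$vco2,
                                                trace$body_mass_g,
                                                ee_formula)),
               total_activity = sum(x$activity),
               total_food_g = sum(x$food_g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a calorimetry trace from CSV + JSON metadata
#'
#' @param trace_csv CSV with columns `time` (ISO-8601), `vo2`, `vco2`, and
#'   optionally `activity`, `food_g`.
#' @param meta_json JSON file with `lights_on`, `lights_off`,
#'   `body_mass_g`.
#' @return a [calorimetry_trace()].
#' @export
read_calorimetry <- function(trace_csv, meta_json) {
  s <- utils::read.csv(trace_csv, stringsAsFactors = FALSE)
  s$time <- as.POSIXct(s$time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS"))
  meta <- jsonlite::read_json(meta_json, simplifyVector = TRUE)
  calorimetry_trace(s, meta$lights_on, meta$lights_off, meta$body_mass_g)
}
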