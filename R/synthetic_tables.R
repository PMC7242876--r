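# Synthetic calorimetry traces and qPCR / densitometry tables with known
# ground truth.

#' Generate a two-phase calorimetry trace with exact phase means
#'
#' VO2/VCO2 follow phase-specific levels (nocturnal elevation as in mice)
#' modulated by a within-phase sinusoid; after composition every phase is
#' recentered so its arithmetic mean equals the specified level exactly,
#' then Gaussian noise is added. The trace starts at `lights_on`, so a
#' whole number of 12:12 days yields exactly balanced phase counts.
#'
#' @param hours trace duration (default 48).
#' @param dt_min sampling cadence in minutes (default 10).
#' @param lights_on,lights_off light schedule (default 06:00-18:00).
#' @param vo2_light,vo2_dark mean VO2 per phase (mL/kg/h).
#' @param rer_light,rer_dark mean RER per phase; VCO2 = RER * VO2.
#' @param sin_amp relative amplitude of the within-phase sinusoid.
#' @param noise_sd Gaussian noise SD added to VO2 and VCO2 (mL/kg/h).
#' @param body_mass_g body mass (default 30 g).
#' @param activity_dark,activity_light mean activity counts per sample.
#' @param seed integer seed.
#' @return list with `trace` (a [calorimetry_trace()]) and `truth` (the
#'   specified per-phase means).
#' @export
make_clams_trace <- function(hours = 48, dt_min = 10,
                             lights_on = "06:00", lights_off = "18:00",
                             vo2_light = 3000, vo2_dark = 3600,
                             rer_light = 0.82, rer_dark = 0.95,
                             sin_amp = 0.05, noise_sd = 0,
                             body_mass_g = 30,
                             activity_dark = 120, activity_light = 40,
                             seed = 1L) {
  n <- as.integer(round(hours * 60 / dt_min))
  t0 <- as.POSIXct(paste("2024-01-01", lights_on), tz = "UTC")
  times <- t0 + (seq_len(n) - 1L) * dt_min * 60
  with_seed(seed, {
    lt <- as.POSIXlt(times)
    secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
    on <- clock_seconds(lights_on); off <- clock_seconds(lights_off)
    light <- if (on < off) secs >= on & secs < off else secs >= on | secs < off
    base_vo2 <- ifelse(light, vo2_light, vo2_dark)
    base_rer <- ifelse(light, rer_light, rer_dark)
    # within-phase modulation, recentered to exact phase means below
    phase_pos <- (secs - on) %% 86400
    mod <- sin(2 * pi * phase_pos / 43200)
    vo2 <- base_vo2 * (1 + sin_amp * mod)
    for (ph in c(TRUE, FALSE)) {
      idx <- light == ph
      if (any(idx)) {
        tgt <- if (ph) vo2_light else vo2_dark
        vo2[idx] <- vo2[idx] - mean(vo2[idx]) + tgt
      }
    }
    vco2 <- base_rer * vo2
    for (ph in c(TRUE, FALSE)) {
      idx <- light == ph
      if (any(idx)) {
        tgt <- if (ph) rer_light * vo2_light else rer_dark * vo2_dark
        vco2[idx] <- vco2[idx] - mean(vco2[idx]) + tgt
      }
    }
    if (noise_sd > 0) {
      vo2 <- pmax(vo2 + stats::rnorm(n, 0, noise_sd), 1)
      vco2 <- pmax(vco2 + stats::rnorm(n, 0, noise_sd), 1)
    }
    activity <- stats::rpois(n, ifelse(light, activity_light, activity_dark))
    food <- round(stats::runif(n, 0, ifelse(light, 0.01, 0.04)), 3)
    trace <- calorimetry_trace(
      data.frame(time = times, vo2 = vo2, vco2 = vco2,
                 activity = activity, food_g = food),
      lights_on, lights_off, body_mass_g)
    list(trace = trace,
         truth = data.frame(
           phase = c("diurnal", "nocturnal"),
           mean_vo2 = c(vo2_light, vo2_dark),
           mean_vco2 = c(rer_light * vo2_light, rer_dark * vo2_dark),
           mean_rer = c(rer_light, rer_dark)))
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Builds control and test groups measuring target genes plus a reference
#' gene. Noiseless tables reproduce the specified fold changes exactly via
#' the delta-delta-Ct arithmetic; with noise, Ct values of target and
#' reference genes receive independent Gaussian jitter.
#'
#' @param genes named numeric vector: true fold change (test vs control) per
#'   gene, e.g. `c(ucp1 = 10)`.
#' @param n_control,n_test samples per group (default 4).
#' @param reference_gene reference gene name (default `"18s"`).
#' @param ct_ref mean reference-gene Ct (default 10).
#' @param ct_base mean control-group target Ct (default 25).
#' @param ct_noise_sd Gaussian SD added to every Ct (default 0).
#' @param seed integer seed.
#' @return list with `table` (data.frame: sample_id, group, gene, ct) and
#'   `truth` (the `genes` vector).
#' @export
make_qpcr_table <- function(genes = c(ucp1 = 10), n_control = 4, n_test = 4,
                            reference_gene = "18s", ct_ref = 10,
                            ct_base = 25, ct_noise_sd = 0, seed = 1L) {
  stopifnot(all(genes > 0), n_control >= 1, n_test >= 1)
  with_seed(seed, {
    samples <- data.frame(
      sample_id = sprintf("s%02d", seq_len(n_control + n_test)),
      group = rep(c("control", "test"), c(n_control, n_test)),
      stringsAsFactors = FALSE)
    rows <- list()
    for (i in seq_len(nrow(samples))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[i], group = samples$group[i],
        gene = reference_gene,
        ct = ct_ref + stats::rnorm(1, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
      for (g in names(genes)) {
        ct <- if (samples$group[i] == "control") ct_base
              else ct_base - log2(genes[[g]])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples$sample_id[i], group = samples$group[i],
          gene = g, ct = ct + stats::rnorm(1, 0, ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows), truth = genes)
  })
}

#' Generate a densitometry table with known normalized ratios
#'
#' @param proteins named numeric vector: true normalized IDV (test vs
#'   control) per protein.
#' @param n_control,n_test lanes per group.
#' @param loading_control loading-control name (default `"beta-actin"`).
#' @param control_intensity loading-control band intensity (default 1000).
#' @param cv multiplicative lognormal noise CV on intensities (default 0).
#' @param seed integer seed.
#' @return list with `table` (data.frame: lane_id, group, protein,
#'   intensity) and `truth`.
#' @export
make_densitometry_table <- function(proteins = c(ucp1 = 3), n_control = 6,
                                    n_test = 6,
                                    loading_control = "beta-actin",
                                    control_intensity = 1000, cv = 0,
                                    seed = 1L) {
  stopifnot(all(proteins >= 0))
  with_seed(seed, {
    lanes <- data.frame(
      lane_id = sprintf("L%02d", seq_len(n_control + n_test)),
      group = rep(c("control", "test"), c(n_control, n_test)),
      stringsAsFactors = FALSE)
    jitter <- function(x) if (cv > 0)
      x * stats::rlnorm(length(x), -cv^2 / 2, cv) else x
    rows <- list()
    for (i in seq_len(nrow(lanes))) {
      ctl <- jitter(control_intensity)
      rows[[length(rows) + 1L]] <- data.frame(
        lane_id = lanes$lane_id[i], group = lanes$group[i],
        protein = loading_control, intensity = ctl,
        stringsAsFactors = FALSE)
      for (p in names(proteins)) {
        ratio <- if (lanes$group[i] == "control") 1 else proteins[[p]]
        rows[[length(rows) + 1L]] <- data.frame(
          lane_id = lanes$lane_id[i], group = lanes$group[i],
          protein = p, intensity = jitter(ctl * ratio),
          stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows), truth = proteins)
  })
}
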