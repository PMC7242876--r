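# End-to-end synthetic study orchestration: generate per-subject inputs for
# every stage, run the corresponding quantification, and assemble a report.

#' Build a study configuration
#'
#' Defaults describe a two-group phenotyping contrast (lean "test" vs obese
#' "control") across all stages. Every field can be overridden; the whole
#' configuration is serializable and written next to the outputs, and a
#' given (config, seed) pair reproduces outputs byte-identically.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @param n_per_group subjects per group (default 3).
#' @param stages character vector of stages to run, subset of
#'   `c("ct", "adipo", "stain", "pet", "clams", "qpcr", "blot")`.
#' @param params named list of per-stage parameter lists; see Details in
#'   the package vignette. Anything not supplied keeps the defaults below.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1L, out_dir = tempfile("adipophen_study_"),
                         n_per_group = 3L,
                         stages = c("ct", "adipo", "stain", "pet", "clams",
                                    "qpcr", "blot"),
                         params = list()) {
  defaults <- list(
    ct = list(dims = c(64, 64, 96), spacing_mm = 0.2, noise_sd_hu = 20,
              fat_fraction = c(control = 0.35, test = 0.14)),
    adipo = list(n_cells = 150, sdlog = 0.35,
                 mean_area_um2 = c(control = 5000, test = 1800)),
    stain = list(kind = "psr", dims = c(300, 300),
                 stained_fraction = c(control = 0.12, test = 0.04)),
    pet = list(dims = c(48, 48, 48), spacing_mm = 0.4, injected_dose = 10,
               uptake = c(control = 8, test = 20)),
    clams = list(hours = 48, dt_min = 10, noise_sd = 60,
                 vo2_light = c(control = 2800, test = 3200),
                 vo2_dark = c(control = 3300, test = 3900)),
    qpcr = list(genes = c(ucp1 = 10), ct_noise_sd = 0.15),
    blot = list(proteins = c(ucp1 = 3), cv = 0.1)
  )
  for (nm in names(params)) {
    defaults[[nm]][names(params[[nm]])] <- params[[nm]]
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_per_group = as.integer(n_per_group),
                 stages = stages, params = defaults),
            class = "study_config")
}

# deterministic per-(stage, group, subject) seed below 2^31
stage_seed <- function(base, stage, group, subject) {
  stage_i <- match(stage, c("ct", "adipo", "stain", "pet", "clams", "qpcr",
                            "blot"))
  group_i <- match(group, c("control", "test"))
  (as.integer(base) + 104729L * stage_i + 7919L * group_i + 31L * subject) %%
    2147483647L
}

write_stage_csv <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

#' Run the full synthetic study
#'
#' For every requested stage, generates one synthetic input per subject and
#' group (with stage/group/subject-specific seeds derived from the master
#' seed), runs the package's quantification, and writes per-stage CSVs, a
#' summary table (mean, SEM per group plus Welch t-test p-values, labeled as
#' such) and the serialized configuration into `config$out_dir`. The
#' orchestrator adds no computation of its own: every number in the outputs
#' comes from a module function.
#'
#' @param config a [study_config()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with `results` (per-stage data.frames),
#'   `summary` (the summary data.frame) and `out_dir`.
#' @export
run_study <- function(config = study_config(), quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  n <- config$n_per_group
  groups <- c("control", "test")
  say <- function(...) if (!quiet) message(...)
  results <- list()

  subj_grid <- expand.grid(subject = seq_len(n), group = groups,
                           stringsAsFactors = FALSE)

  if ("ct" %in% config$stages) {
    say("stage ct: ", nrow(subj_grid), " phantoms")
    rows <- lapply(seq_len(nrow(subj_grid)), function(i) {
      g <- subj_grid$group[i]; s <- subj_grid$subject[i]
      ph <- make_ct_phantom(dims = p$ct$dims, spacing_mm = p$ct$spacing_mm,
                            fat_fraction = p$ct$fat_fraction[[g]],
                            noise_sd_hu = p$ct$noise_sd_hu,
                            seed = stage_seed(config$seed, "ct", g, s))
      r <- suppressWarnings(ct_fat_pipeline(ph$volume))
      data.frame(subject = sprintf("%s_%02d", g, s), group = g,
                 metric = "percent_fat", true = ph$true_percent_fat,
                 value = r$result$percent_fat)
    })
    results$ct <- do.call(rbind, rows)
  }

  if ("adipo" %in% config$stages) {
    say("stage adipo: ", nrow(subj_grid), " mosaics")
    rows <- lapply(seq_len(nrow(subj_grid)), function(i) {
      g <- subj_grid$group[i]; s <- subj_grid$subject[i]
      mz <- make_adipocyte_mosaic(n_cells = p$adipo$n_cells,
                                  mean_area_um2 = p$adipo$mean_area_um2[[g]],
                                  sdlog = p$adipo$sdlog,
                                  seed = stage_seed(config$seed, "adipo", g, s))
      seg <- segment_adipocytes(preprocess_he(mz$field),
                                mz$field$pixel_size_um)
      data.frame(subject = sprintf("%s_%02d", g, s), group = g,
                 metric = "mean_adipocyte_area_um2",
                 true = mean(mz$truth$area_um2),
                 value = mean(seg$cells$area_um2))
    })
    results$adipo <- do.call(rbind, rows)
  }

  if ("stain" %in% config$stages) {
    say("stage stain: ", nrow(subj_grid), " fields")
    rows <- lapply(seq_len(nrow(subj_grid)), function(i) {
      g <- subj_grid$group[i]; s <- subj_grid$subject[i]
      sf <- make_stain_field(p$stain$kind,
                             p$stain$stained_fraction[[g]],
                             dims = p$stain$dims,
                             seed = stage_seed(config$seed, "stain", g, s))
      r <- quantify_stain_area(sf$field, sf$roi)
      data.frame(subject = sprintf("%s_%02d", g, s), group = g,
                 metric = "percent_stained", true = sf$true_percent,
                 value = r$percent_stained)
    })
    results$stain <- do.call(rbind, rows)
  }

  if ("pet" %in% config$stages) {
    say("stage pet: ", nrow(subj_grid), " phantoms")
    rows <- lapply(seq_len(nrow(subj_grid)), function(i) {
      g <- subj_grid$group[i]; s <- subj_grid$subject[i]
      u <- p$pet$uptake[[g]]
      dose <- p$pet$injected_dose
      ph <- make_pet_phantom(dims = p$pet$dims, spacing_mm = p$pet$spacing_mm,
                             radii_vox = c(9, 8, 11),
                             c_hot = u * dose / 100, c_bg = 0.02 * u * dose / 100,
                             injected_dose = dose,
                             seed = stage_seed(config$seed, "pet", g, s))
      roi <- interpolate_roi(ph$contours, dim(ph$volume$data))
      pet <- compute_pet_uptake(ph$volume, roi, dose)$percent_id_per_g
      gam <- with_seed(stage_seed(config$seed, "pet", g, s) + 1L, {
        w <- stats::runif(1, 0.08, 0.15)
        gamma_uptake(u / 100 * 1e6 * w * (1 + stats::rnorm(1, 0, 0.02)),
                     1e6, w)
      })
      data.frame(subject = sprintf("%s_%02d", g, s), group = g,
                 metric = c("pet_percent_id_per_g", "gamma_percent_id_per_g"),
                 true = u, value = c(pet, gam))
    })
    results$pet <- do.call(rbind, rows)
  }

  if ("clams" %in% config$stages) {
    say("stage clams: ", nrow(subj_grid), " traces")
    rows <- lapply(seq_len(nrow(subj_grid)), function(i) {
      g <- subj_grid$group[i]; s <- subj_grid$subject[i]
      tr <- make_clams_trace(hours = p$clams$hours, dt_min = p$clams$dt_min,
                             vo2_light = p$clams$vo2_light[[g]],
                             vo2_dark = p$clams$vo2_dark[[g]],
                             noise_sd = p$clams$noise_sd,
                             seed = stage_seed(config$seed, "clams", g, s))
      sm <- summarize_cycles(tr$trace)
      data.frame(subject = sprintf("%s_%02d", g, s), group = g,
                 metric = paste0(sm$phase, "_", rep(c("vo2", "ee"), each = 2)),
                 true = c(p$clams$vo2_light[[g]], p$clams$vo2_dark[[g]],
                          NA, NA),
                 value = c(sm$mean_vo2, sm$mean_ee_kcal_h))
    })
    results$clams <- do.call(rbind, rows)
  }

  if ("qpcr" %in% config$stages) {
    say("stage qpcr")
    tab <- make_qpcr_table(genes = p$qpcr$genes, n_control = n, n_test = n,
                           ct_noise_sd = p$qpcr$ct_noise_sd,
                           seed = stage_seed(config$seed, "qpcr", "control", 0L))
    rows <- lapply(names(p$qpcr$genes), function(g) {
      fc <- fold_change(tab$table, g)
      data.frame(subject = fc$sample_id, group = fc$group,
                 metric = paste0("fold_", g), true = ifelse(fc$group == "test",
                                                            p$qpcr$genes[[g]], 1),
                 value = fc$fold)
    })
    results$qpcr <- do.call(rbind, rows)
  }

  if ("blot" %in% config$stages) {
    say("stage blot")
    tab <- make_densitometry_table(proteins = p$blot$proteins, n_control = n,
                                   n_test = n, cv = p$blot$cv,
                                   seed = stage_seed(config$seed, "blot",
                                                     "control", 0L))
    rows <- lapply(names(p$blot$proteins), function(pr) {
      nd <- normalize_densitometry(tab$table, pr)
      data.frame(subject = nd$lane_id, group = nd$group,
                 metric = paste0("idv_", pr),
                 true = ifelse(nd$group == "test", p$blot$proteins[[pr]], 1),
                 value = nd$idv)
    })
    results$blot <- do.call(rbind, rows)
  }

  # summary: descriptive mean +/- SEM per group per metric, Welch t-test p
  all_rows <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  summ <- do.call(rbind, lapply(split(all_rows, all_rows$metric), function(d) {
    ctrl <- d$value[d$group == "control"]
    test <- d$value[d$group == "test"]
    pval <- if (length(ctrl) >= 2 && length(test) >= 2 &&
                (stats::var(ctrl) + stats::var(test)) > 0)
      stats::t.test(test, ctrl)$p.value else NA_real_
    data.frame(metric = d$metric[1],
               mean_control = mean(ctrl),
               sem_control = stats::sd(ctrl) / sqrt(length(ctrl)),
               mean_test = mean(test),
               sem_test = stats::sd(test) / sqrt(length(test)),
               welch_p = pval, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  for (nm in names(results)) write_stage_csv(results[[nm]], config$out_dir, nm)
  write_stage_csv(summ, config$out_dir, "summary")
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, summary = summ, out_dir = config$out_dir))
}
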