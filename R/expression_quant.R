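# Relative mRNA quantification (delta-delta-Ct) and blot densitometry
# normalization.

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(gene) - Ct(reference)`; the control baseline is the
#' arithmetic mean dCt over control samples, and
#' `fold = 2^-(dCt - baseline)`. Normalizing to both a reference gene and the
#' control group means the control-group fold changes have geometric mean 1
#' exactly.
#'
#' @param table data.frame with columns `sample_id`, `group`
#'   (`"control"` / `"test"`), `gene`, `ct`.
#' @param gene target gene name.
#' @param reference_gene reference (housekeeping) gene, default `"18s"`.
#' @return data.frame per sample: sample_id, group, delta_ct, ddct, fold;
#'   group means attached as attribute `group_means` (data.frame with
#'   arithmetic and geometric mean fold per group).
#' @export
fold_change <- function(table, gene, reference_gene = "18s") {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(table$ct)) || any(table$ct <= 0))
    stop("Ct values must be finite and positive")
  tg <- table[table$gene == gene, ]
  rf <- table[table$gene == reference_gene, ]
  if (nrow(tg) == 0L) stop("gene not found: ", gene)
  if (nrow(rf) == 0L) stop("reference gene not found: ", reference_gene)
  m <- merge(tg[, c("sample_id", "group", "ct")],
             rf[, c("sample_id", "ct")],
             by = "sample_id", suffixes = c("_gene", "_ref"))
  dropped <- setdiff(tg$sample_id, m$sample_id)
  if (length(dropped) > 0L)
    warning("dropping sample(s) without reference measurements: ",
            paste(dropped, collapse = ", "))
  m$delta_ct <- m$ct_gene - m$ct_ref
  ctrl <- m$group == "control"
  if (!any(ctrl)) adp_error("no control samples", "no_controls")
  baseline <- mean(m$delta_ct[ctrl])
  m$ddct <- m$delta_ct - baseline
  m$fold <- 2^(-m$ddct)
  out <- m[order(m$sample_id), c("sample_id", "group", "delta_ct", "ddct", "fold")]
  rownames(out) <- NULL
  gm <- do.call(rbind, lapply(split(out, out$group), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               mean_fold = mean(g$fold),
               geo_mean_fold = exp(mean(log(g$fold))),
               stringsAsFactors = FALSE)))
  rownames(gm) <- NULL
  attr(out, "group_means") <- gm
  attr(out, "gene") <- gene
  attr(out, "reference_gene") <- reference_gene
  out
}

#' Normalize blot densitometry to a loading control
#'
#' Per lane, the integrated density value (IDV) of the target protein is
#' divided by the loading control's; optionally the ratios are rescaled so
#' the control-group mean equals 1.
#'
#' @param table data.frame with columns `lane_id`, `group`, `protein`,
#'   `intensity`.
#' @param protein target protein name.
#' @param loading_control loading-control protein, default `"beta-actin"`.
#' @param rescale_to_control rescale so the control-group mean IDV is 1
#'   (default TRUE).
#' @return data.frame per lane: lane_id, group, idv; group means attached
#'   as attribute `group_means`.
#' @export
normalize_densitometry <- function(table, protein,
                                   loading_control = "beta-actin",
                                   rescale_to_control = TRUE) {
  need <- c("lane_id", "group", "protein", "intensity")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(table$intensity < 0)) stop("intensities must be >= 0")
  tg <- table[table$protein == protein, ]
  lc <- table[table$protein == loading_control, ]
  if (nrow(tg) == 0L) stop("protein not found: ", protein)
  if (nrow(lc) == 0L) stop("loading control not found: ", loading_control)
  m <- merge(tg[, c("lane_id", "group", "intensity")],
             lc[, c("lane_id", "intensity")],
             by = "lane_id", suffixes = c("_protein", "_control"))
  zero <- m$intensity_control == 0
  if (any(zero)) {
    warning("dropping lane(s) with zero loading control: ",
            paste(m$lane_id[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no usable lanes")
  m$idv <- m$intensity_protein / m$intensity_control
  if (rescale_to_control) {
    ctrl <- m$group == "control"
    if (!any(ctrl)) adp_error("no control lanes", "no_controls")
    m$idv <- m$idv / mean(m$idv[ctrl])
  }
  out <- m[order(m$lane_id), c("lane_id", "group", "idv")]
  rownames(out) <- NULL
  gm <- do.call(rbind, lapply(split(out, out$group), function(g)
    data.frame(group = g$group[1], n = nrow(g), mean_idv = mean(g$idv),
               stringsAsFactors = FALSE)))
  rownames(gm) <- NULL
  attr(out, "group_means") <- gm
  attr(out, "protein") <- protein
  attr(out, "loading_control") <- loading_control
  out
}

#' Confidence interval for the test-group fold change
#'
#' Welch two-sample CI on the delta-Ct difference (test minus control),
#' transformed to the fold scale (`2^-d`). The proper interval for a
#' two-group delta-delta-Ct design: baseline uncertainty is included.
#'
#' @param fc result of [fold_change()].
#' @param conf_level confidence level (default 0.95).
#' @return list with `fold`, `lower`, `upper`, `conf_level`.
#' @export
fold_change_ci <- function(fc, conf_level = 0.95) {
  d_test <- fc$delta_ct[fc$group == "test"]
  d_ctrl <- fc$delta_ct[fc$group == "control"]
  if (length(d_test) < 2L || length(d_ctrl) < 2L)
    stop("need >= 2 samples per group for a confidence interval")
  tt <- stats::t.test(d_test, d_ctrl, conf.level = conf_level)
  list(fold = 2^(-unname(diff(rev(tt$estimate)))),
       lower = 2^(-tt$conf.int[2]),
       upper = 2^(-tt$conf.int[1]),
       conf_level = conf_level)
}
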