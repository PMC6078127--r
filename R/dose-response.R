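#' Fraction of dead cells from a resorufin viability readout
#'
#' `(control - treated) / control`. The resorufin signal scales with living
#' cells, so treated signal above control gives a negative fraction (allowed:
#' treatments can mildly stimulate growth relative to control).
#'
#' @param resorufin_control mean untreated-control signal (> 0).
#' @param resorufin_treated treated-well signal (>= 0), vectorized.
#' @return fraction dead, <= 1.
#' @examples
#' fraction_dead(1000, 840)  # 0.16
#' @export
fraction_dead <- function(resorufin_control, resorufin_treated) {
  if (any(resorufin_control <= 0)) stop("control signal must be positive")
  if (any(resorufin_treated < 0)) stop("treated signal must be non-negative")
  (resorufin_control - resorufin_treated) / resorufin_control
}


# coefficient of determination without summary.lm's perfect-fit chatter
rsq <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / tss))
}

is_control_label <- function(x) tolower(x) %in% c("vehicle", "control", "untreated")
is_scramble_label <- function(x) tolower(x) %in% c("scramble", "scrambled", "scr")

#' Construct a dose-response series
#'
#' @param treatment treatment label.
#' @param dose_uM doses in µM, strictly increasing.
#' @param fa_mean mean fraction affected per dose (<= 1; negatives allowed).
#' @param fa_sd per-dose standard deviation (optional).
#' @param n per-dose replicate count (optional).
#' @param timepoint label, e.g. "24h".
#' @return a `dose_response_series`.
#' @export
dose_response_series <- function(treatment, dose_uM, fa_mean, fa_sd = NA_real_,
                                 n = NA_integer_, timepoint = "24h") {
  if (any(diff(dose_uM) <= 0)) stop("doses must be strictly increasing")
  if (any(fa_mean > 1)) stop("fraction affected cannot exceed 1")
  pts <- data.frame(dose_uM = dose_uM, fa_mean = fa_mean, fa_sd = fa_sd,
                    n = n)
  structure(list(treatment = treatment, timepoint = timepoint, points = pts),
            class = "dose_response_series")
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("Dose-response series '%s' (%s): %d doses, %.3g-%.3g uM\n",
              x$treatment, x$timepoint, nrow(x$points),
              min(x$points$dose_uM), max(x$points$dose_uM)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Summarize a viability plate into dose-response series
#'
#' Computes per-well fraction affected against the mean untreated-control
#' signal, then aggregates mean/SD/replicates per treatment and dose. With
#' `adjust_to_scramble`, the plate's mean scramble fraction affected is
#' subtracted from every treatment value, removing sequence-independent
#' toxicity measured on the same plate (adjusted values may go negative).
#'
#' @param records data frame with columns well, treatment, dose_uM,
#'   fluorescence (one row per well). Untreated controls are wells labeled
#'   "vehicle"/"control"/"untreated"; scramble wells "scramble"/"scr".
#' @param adjust_to_scramble subtract the plate's mean scramble FA.
#' @return named list of `dose_response_series`, one per non-control
#'   treatment (scramble included, unadjusted).
#' @export
summarize_plate <- function(records, adjust_to_scramble = FALSE) {
  need <- c("well", "treatment", "dose_uM", "fluorescence")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("plate records missing column(s): ", paste(missing, collapse = ", "))
  ctrl <- is_control_label(records$treatment)
  if (!any(ctrl)) stop("plate has no untreated-control wells")
  ctrl_signal <- mean(records$fluorescence[ctrl])
  records$fa <- fraction_dead(ctrl_signal, records$fluorescence)
  scr <- is_scramble_label(records$treatment)
  if (adjust_to_scramble && !any(scr))
    stop("adjust_to_scramble = TRUE but the plate has no scramble wells")
  scr_fa <- if (any(scr)) mean(records$fa[scr]) else NA_real_

  out <- list()
  for (tr in unique(records$treatment[!ctrl])) {
    rows <- records[records$treatment == tr, , drop = FALSE]
    agg <- do.call(rbind, lapply(split(rows, rows$dose_uM), function(d)
      data.frame(dose_uM = d$dose_uM[1], fa_mean = mean(d$fa),
                 fa_sd = stats::sd(d$fa), n = nrow(d))))
    agg <- agg[order(agg$dose_uM), , drop = FALSE]
    if (any(agg$n < 2))
      warning("treatment '", tr, "' has dose(s) with fewer than 2 replicates")
    if (adjust_to_scramble && !is_scramble_label(tr))
      agg$fa_mean <- agg$fa_mean - scr_fa
    ser <- dose_response_series(tr, agg$dose_uM, agg$fa_mean, agg$fa_sd, agg$n)
    ser$scramble_fa <- scr_fa
    ser$adjusted <- adjust_to_scramble && !is_scramble_label(tr)
    out[[tr]] <- ser
  }
  out
}

#' EC50 implied by a linear sensitivity slope
#'
#' Under the linear dose-response model (percent dead cells regressed on
#' dose in nM), the dose reaching 50% dead cells is `50 / |slope|` nM,
#' reported in µM. The magnitude of the slope is used so that weak
#' negative-slope (non-cytotoxic) fits still yield a positive EC50.
#'
#' @param slope sensitivity in percent dead cells per nM.
#' @return EC50 in µM (Inf for slope 0).
#' @examples
#' ec50_from_slope(0.408)  # 0.1225 uM
#' @export
ec50_from_slope <- function(slope) {
  ifelse(slope == 0, Inf, 50 / abs(slope) / 1000)
}

#' Linear sensitivity fit of a dose-response series
#'
#' Ordinary least squares of percent dead cells (`fa * 100`) on dose in nM.
#' The slope is the "sensitivity" (% dead cells per nM); EC50 is derived
#' from the slope alone via [ec50_from_slope()]. A negative slope marks a
#' non-cytotoxic response and is flagged with a warning. Set
#' `log_dose = TRUE` to regress on log10(dose) instead (the slope then loses
#' its per-nM unit and no EC50 is derived from it).
#'
#' @param series a `dose_response_series` with >= 3 dose points.
#' @param log_dose regress on log10 dose rather than linear dose in nM.
#' @return a `linear_fit`: slope, intercept, r_squared, ec50_uM, n.
#' @export
linear_sensitivity <- function(series, log_dose = FALSE) {
  stopifnot(inherits(series, "dose_response_series"))
  pts <- series$points
  if (nrow(pts) < 3) stop("need at least 3 dose points")
  x <- if (log_dose) log10(pts$dose_uM * 1000) else pts$dose_uM * 1000
  if (stats::var(x) == 0) stop("zero dose variance")
  y <- pts$fa_mean * 100
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- rsq(fit, y)
  non_cytotoxic <- slope < 0
  if (non_cytotoxic)
    warning("negative slope for '", series$treatment,
            "': non-cytotoxic response; EC50 uses |slope|")
  structure(list(treatment = series$treatment, slope = slope,
                 intercept = unname(stats::coef(fit)[1]), r_squared = r2,
                 ec50_uM = if (log_dose) NA_real_ else ec50_from_slope(slope),
                 n = nrow(pts), log_dose = log_dose,
                 non_cytotoxic = non_cytotoxic, lm = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear sensitivity fit '%s': slope %.4g %s (r2 = %.3f)",
              x$treatment, x$slope,
              if (x$log_dose) "% per log10(nM)" else "% dead cells per nM",
              x$r_squared))
  if (!is.na(x$ec50_uM)) cat(sprintf(", EC50 = %.4g uM", x$ec50_uM))
  cat("\n")
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.linear_fit <- function(object, dose_uM, ...) {
  x <- if (object$log_dose) log10(dose_uM * 1000) else dose_uM * 1000
  (object$intercept + object$slope * x) / 100
}

#' Median-effect (mass-action) fit of a dose-response series
#'
#' Fits the median-effect equation fa/(1 - fa) = (D/Dm)^m by ordinary least
#' squares of log10(fa/(1-fa)) on log10(D). `m` is the slope (sigmoidicity);
#' `Dm = 10^(-intercept/m)` is the median-effect dose, at which the model
#' predicts fa = 0.5. Points with fa outside (0, 1) have an undefined logit
#' and are excluded; the excluded count is recorded.
#'
#' @param series a `dose_response_series`, or a data frame with columns
#'   dose_uM and fa (or fa_mean).
#' @return a `median_effect_fit`: m, Dm (µM), r_squared, n_points,
#'   n_excluded.
#' @export
median_effect_fit <- function(series) {
  pts <- if (inherits(series, "dose_response_series")) series$points
         else as.data.frame(series)
  if (!"fa_mean" %in% names(pts) && "fa" %in% names(pts))
    pts$fa_mean <- pts$fa
  usable <- pts$fa_mean > 0 & pts$fa_mean < 1
  n_excluded <- sum(!usable)
  pts <- pts[usable, , drop = FALSE]
  if (nrow(pts) < 2) stop("need at least 2 points with fa strictly in (0, 1)")
  if (length(unique(pts$dose_uM)) < 2) stop("all usable doses are equal")
  x <- log10(pts$dose_uM)
  y <- log10(pts$fa_mean / (1 - pts$fa_mean))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b0 <- unname(stats::coef(fit)[1])
  if (m <= 0) warning("non-positive median-effect slope m = ", signif(m, 3))
  structure(list(treatment = if (inherits(series, "dose_response_series"))
                   series$treatment else NA_character_,
                 m = m, Dm = 10^(-b0 / m),
                 r_squared = rsq(fit, y),
                 n_points = nrow(pts), n_excluded = n_excluded),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit%s: m = %.4g, Dm = %.4g uM (r2 = %.4f, %d points%s)\n",
              if (is.na(x$treatment)) "" else paste0(" '", x$treatment, "'"),
              x$m, x$Dm, x$r_squared, x$n_points,
              if (x$n_excluded > 0)
                paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}

#' @export
coef.median_effect_fit <- function(object, ...) {
  c(m = object$m, Dm = object$Dm)
}

#' @export
predict.median_effect_fit <- function(object, dose_uM, ...) {
  r <- (dose_uM / object$Dm)^object$m
  r / (1 + r)
}

#' Dose achieving a given effect level under a median-effect fit
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa/(1-fa))^(1/m)`. By
#' definition `dose_for_effect(fit, 0.5) == Dm`, and the dose is strictly
#' increasing in fa.
#'
#' @param fit a `median_effect_fit`.
#' @param fa effect level strictly in (0, 1).
#' @return dose in µM.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Classify a combination index value
#'
#' CI < 1 indicates synergy, CI = 1 additivity, CI > 1 antagonism. Because
#' an exact-1 class would be vacuous under floating point (and published
#' values like 1.10 are read as additive), values within `additive_band`
#' are labeled additive.
#'
#' @param ci combination index (> 0), vectorized.
#' @param additive_band closed interval treated as additive
#'   (default c(0.9, 1.1)).
#' @return character vector: "synergy", "additive" or "antagonism".
#' @examples
#' classify_interaction(c(0.15, 1.10, 210))
#' @export
classify_interaction <- function(ci, additive_band = c(0.9, 1.1)) {
  if (any(ci <= 0)) stop("combination index must be positive")
  ifelse(ci < additive_band[1], "synergy",
         ifelse(ci > additive_band[2], "antagonism", "additive"))
}

#' Chou-Talalay combination index for a fixed-ratio mixture
#'
#' For a mixture dosed by total concentration at fixed mixing fractions, the
#' total dose achieving effect `fa` is taken from the mixture's own
#' median-effect fit; each component's contribution is its fraction of that
#' total. The combination index is the sum over components of (component
#' dose in the mixture) / (single-agent dose producing the same effect):
#' CI = sum_i f_i * D_combo(fa) / Dx_i(fa). A sham combination of an agent
#' with itself gives CI = 1 at every effect level. Supports n >= 2
#' components (an equimolar 12-agent cocktail uses fractions of 1/12).
#'
#' @param component_fits list of per-agent `median_effect_fit` objects.
#' @param fractions mixing proportions, summing to 1 (tolerance 1e-6).
#' @param combo_fit `median_effect_fit` of the mixture dosed by total
#'   concentration.
#' @param fa effect level at which to evaluate (default 0.5, i.e. ED50).
#' @param additive_band passed to [classify_interaction()].
#' @return an `interaction_result`: components, fractions, fa, ci, label.
#' @export
combination_index <- function(component_fits, fractions, combo_fit, fa = 0.5,
                              additive_band = c(0.9, 1.1)) {
  stopifnot(all(vapply(component_fits, inherits, logical(1),
                       "median_effect_fit")),
            inherits(combo_fit, "median_effect_fit"))
  if (length(component_fits) < 2) stop("need at least 2 components")
  if (length(fractions) != length(component_fits))
    stop("one mixing fraction per component is required")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("mixing fractions must sum to 1 (got ", sum(fractions), ")")
  d_total <- dose_for_effect(combo_fit, fa)
  d_single <- vapply(component_fits, dose_for_effect, numeric(1), fa = fa)
  ci <- sum(fractions * d_total / d_single)
  labels <- names(component_fits)
  if (is.null(labels))
    labels <- vapply(component_fits, function(f)
      if (is.na(f$treatment)) "?" else f$treatment, character(1))
  structure(list(components = labels, fractions = fractions, fa = fa,
                 ci = ci, label = classify_interaction(ci, additive_band),
                 total_dose_uM = d_total, component_doses_uM = fractions * d_total),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Combination index at fa = %.2f: CI = %.4g (%s) [%s]\n",
              x$fa, x$ci, x$label, paste(x$components, collapse = " + ")))
  invisible(x)
}

#' Pairwise interaction matrices and their consensus
#'
#' Builds, per cell line, a labeled target-by-target matrix of interaction
#' calls, plus a consensus matrix labeling each unordered pair with the
#' shared call when all cell lines agree and "discordant" otherwise.
#'
#' @param results data frame with columns cell_line, target_a, target_b and
#'   either ci (labels derived via [classify_interaction()]) or label.
#' @param additive_band passed to [classify_interaction()] when labels are
#'   derived from ci values.
#' @return list with `per_line` (named list of matrices) and `consensus`.
#' @export
interaction_matrix <- function(results, additive_band = c(0.9, 1.1)) {
  need <- c("cell_line", "target_a", "target_b")
  missing <- setdiff(need, names(results))
  if (length(missing))
    stop("results missing column(s): ", paste(missing, collapse = ", "))
  if (!"label" %in% names(results)) {
    if (!"ci" %in% names(results)) stop("results need a ci or label column")
    results$label <- classify_interaction(results$ci, additive_band)
  }
  pair_key <- apply(cbind(results$target_a, results$target_b), 1,
                    function(p) paste(sort(p), collapse = "|"))
  for (line in unique(results$cell_line)) {
    keys <- pair_key[results$cell_line == line]
    if (anyDuplicated(keys))
      stop("duplicate pair within cell line '", line, "': ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  targets <- sort(unique(c(results$target_a, results$target_b)))
  empty <- matrix(NA_character_, length(targets), length(targets),
                  dimnames = list(targets, targets))
  per_line <- lapply(split(results, results$cell_line), function(df) {
    m <- empty
    for (i in seq_len(nrow(df))) {
      m[df$target_a[i], df$target_b[i]] <- df$label[i]
      m[df$target_b[i], df$target_a[i]] <- df$label[i]
    }
    m
  })
  consensus <- empty
  for (a in targets) for (b in targets) {
    if (a == b) next
    calls <- unique(stats::na.omit(vapply(per_line, function(m) m[a, b],
                                          character(1))))
    consensus[a, b] <-
      if (length(calls) == 0L) NA_character_
      else if (length(calls) == 1L) calls
      else "discordant"
  }
  list(per_line = per_line, consensus = consensus)
}

#' Read viability-plate records from TSV
#'
#' @param path TSV with columns well, treatment, dose_uM, fluorescence.
#' @return data frame of plate records.
#' @export
read_plate <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("well", "treatment", "dose_uM", "fluorescence")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("plate TSV missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$dose_uM < 0)) stop("doses must be non-negative")
  if (any(df$fluorescence < 0)) stop("fluorescence must be non-negative")
  df
}
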