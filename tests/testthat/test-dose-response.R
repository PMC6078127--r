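test_that("fraction dead is (control - treated)/control, negatives allowed", {
  expect_equal(fraction_dead(1000, 840), 0.16)
  expect_equal(fraction_dead(123.4, 123.4), 0)
  expect_equal(fraction_dead(800, 872), -0.09)
  # scale invariance
  set.seed(2)
  ctrl <- runif(10, 100, 1000); trt <- runif(10, 0, 1200)
  expect_equal(fraction_dead(3.7 * ctrl, 3.7 * trt), fraction_dead(ctrl, trt))
  expect_error(fraction_dead(0, 10), "positive")
})

make_plate <- function(ctrl = 1000, fa_by_dose, replicates = 3,
                       scramble_fa = NA) {
  doses <- as.numeric(names(fa_by_dose))
  fa_by_dose <- unname(fa_by_dose)
  treated <- do.call(rbind, lapply(seq_along(doses), function(i)
    data.frame(well = paste0("T", i, "_", seq_len(replicates)),
               treatment = "oligo", dose_uM = doses[i],
               fluorescence = ctrl * (1 - fa_by_dose[i]))))
  veh <- data.frame(well = paste0("V", seq_len(replicates)),
                    treatment = "vehicle", dose_uM = 0, fluorescence = ctrl)
  out <- rbind(veh, treated)
  if (!is.na(scramble_fa))
    out <- rbind(out, data.frame(well = "S1", treatment = "scramble",
                                 dose_uM = max(doses),
                                 fluorescence = ctrl * (1 - scramble_fa)))
  out
}

test_that("plate summaries aggregate FA per dose and adjust to scramble", {
  plate <- make_plate(fa_by_dose = c(`0.1` = 0, `0.3` = 0, `1` = 0))
  ser <- summarize_plate(plate)
  expect_equal(ser$oligo$points$fa_mean, c(0, 0, 0))
  plate2 <- suppressWarnings(
    summarize_plate(make_plate(fa_by_dose = c(`0.1` = 0.10, `0.3` = 0.30),
                               scramble_fa = 0.05), adjust_to_scramble = TRUE))
  expect_equal(plate2$oligo$points$fa_mean, c(0.05, 0.25))
  expect_equal(plate2$oligo$scramble_fa, 0.05)
  # no untreated controls -> error
  bad <- make_plate(fa_by_dose = c(`0.1` = 0.1))
  bad <- bad[bad$treatment != "vehicle", ]
  expect_error(summarize_plate(bad), "untreated-control")
  expect_error(summarize_plate(make_plate(fa_by_dose = c(`1` = 0.1)),
                               adjust_to_scramble = TRUE), "scramble")
  # single-replicate doses carry a warning
  expect_warning(summarize_plate(make_plate(fa_by_dose = c(`1` = 0.1),
                                            replicates = 1)), "replicates")
})

test_that("plate summaries recover the generative FA within Monte-Carlo error", {
  set.seed(77)
  reps <- lapply(1:40, function(i) {
    plate <- simulate_viability(m = 1.5, Dm = 0.3, replicates = 6,
                                noise_sd = 0.05)
    summarize_plate(plate)$oligo$points$fa_mean
  })
  got <- colMeans(do.call(rbind, reps))
  d <- c(0.03, 0.1, 0.3, 1, 3)
  truth <- (d / 0.3)^1.5 / (1 + (d / 0.3)^1.5)
  # noise enters fluorescence multiplicatively, so recovered FA is unbiased
  expect_equal(got, truth, tolerance = 0.02)
})

test_that("linear sensitivity reproduces a constructed line and its EC50", {
  # FA = 0.001 * dose(nM): slope 0.1 %/nM, r2 = 1, EC50 = 0.5 uM
  d_nM <- c(30, 100, 300, 1000)
  ser <- dose_response_series("x", d_nM / 1000, 0.001 * d_nM)
  fit <- linear_sensitivity(ser)
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$ec50_uM, 0.5)
  expect_equal(unname(coef(fit)), c(fit$intercept, fit$slope))
  # published CHLA-10 sensitivity 0.408 %/nM implies EC50 0.12 uM (2 dp)
  expect_equal(round(ec50_from_slope(0.408), 2), 0.12)
  expect_equal(round(ec50_from_slope(0.464), 2), 0.11)
})

test_that("linear sensitivity equals the closed-form OLS oracle", {
  set.seed(13)
  for (i in 1:10) {
    d_uM <- sort(10^runif(5, -2, 0.5))
    fa <- pmin(0.9, pmax(-0.2, 0.3 * d_uM + rnorm(5, 0, 0.05)))
    ser <- dose_response_series("x", d_uM, fa)
    fit <- linear_sensitivity(ser)
    want <- oracle_ols(d_uM * 1000, fa * 100)
    expect_equal(fit$slope, want$slope)
    expect_equal(fit$intercept, want$intercept)
    expect_equal(fit$r_squared, want$r2)
  }
})

test_that("degenerate linear fits are rejected or flagged", {
  ser2 <- dose_response_series("x", c(0.1, 0.3), c(0.1, 0.2))
  expect_error(linear_sensitivity(ser2), "at least 3")
  neg <- dose_response_series("x", c(0.03, 0.1, 0.3, 1), c(0.3, 0.2, 0.1, 0.05))
  expect_warning(fit <- linear_sensitivity(neg), "non-cytotoxic")
  expect_true(fit$non_cytotoxic)
  expect_gt(fit$ec50_uM, 0)  # |slope| keeps EC50 positive
})

test_that("median-effect fitting is exact on noise-free data", {
  for (m in c(0.8, 1, 2.3)) for (Dm in c(0.2, 0.5, 1.5)) {
    d <- c(0.05, 0.15, 0.4, 1.2, 2.8)
    fa <- (d / Dm)^m / (1 + (d / Dm)^m)
    fit <- median_effect_fit(data.frame(dose_uM = d, fa = fa))
    expect_equal(fit$m, m, tolerance = 1e-10)
    expect_equal(fit$Dm, Dm, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1)
    # at dose Dm the fitted model predicts FA = 0.5
    expect_equal(predict(fit, fit$Dm), 0.5)
    expect_equal(unname(coef(fit)), c(fit$m, fit$Dm))
  }
})

test_that("median-effect fitting excludes FA outside (0,1) and validates input", {
  d <- c(0.05, 0.15, 0.4, 1.2, 2.8)
  fa <- c(0, 0.2, 0.5, 0.8, 1)
  fit <- median_effect_fit(data.frame(dose_uM = d, fa = fa))
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$n_points, 3)
  expect_error(median_effect_fit(data.frame(dose_uM = d, fa = rep(1, 5))),
               "at least 2")
  expect_error(median_effect_fit(data.frame(dose_uM = rep(0.3, 3),
                                            fa = c(0.2, 0.4, 0.6))),
               "doses are equal")
})

test_that("stochastic median-effect recovery is unbiased within a few percent", {
  # lognormal noise (sd 0.1) on the effect ratio fa/(1-fa)
  set.seed(99)
  m <- 1.5; Dm <- 0.3
  d <- c(0.03, 0.1, 0.3, 1, 3)
  fits <- lapply(1:200, function(i) {
    r <- (d / Dm)^m * exp(stats::rnorm(length(d), 0, 0.1))
    median_effect_fit(data.frame(dose_uM = d, fa = r / (1 + r)))
  })
  m_err <- vapply(fits, function(f) abs(f$m - m) / m, numeric(1))
  dm_err <- vapply(fits, function(f) abs(f$Dm - Dm) / Dm, numeric(1))
  expect_lt(stats::median(m_err), 0.05)
  expect_lt(stats::median(dm_err), 0.05)
})

test_that("dose_for_effect inverts the median-effect model", {
  d <- c(0.05, 0.2, 0.8, 2)
  fit1 <- median_effect_fit(data.frame(dose_uM = d,
                                       fa = (d / 1)^1 / (1 + (d / 1)^1)))
  expect_equal(dose_for_effect(fit1, 0.5), 1)     # fa 0.5 -> Dm
  expect_equal(dose_for_effect(fit1, 0.9), 9)     # m=1, Dm=1: 0.9/0.1
  expect_error(dose_for_effect(fit1, 1), "strictly")
  # root-finding oracle on random parameters
  set.seed(55)
  for (i in 1:10) {
    m <- runif(1, 0.5, 3); Dm <- 10^runif(1, -1, 0.5)
    fa_target <- runif(1, 0.05, 0.95)
    fit <- median_effect_fit(data.frame(
      dose_uM = d, fa = (d / Dm)^m / (1 + (d / Dm)^m)))
    dx <- dose_for_effect(fit, fa_target)
    root <- stats::uniroot(function(D) predict(fit, D) - fa_target,
                           c(1e-6, 1e6), tol = 1e-12)$root
    expect_equal(dx, root, tolerance = 1e-6)
  }
  # strictly increasing in fa
  fas <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(dose_for_effect(fit1, fas)) > 0))
})

sham_fit <- function(m = 1.4, Dm = 0.6) {
  d <- c(0.05, 0.2, 0.8, 2.5)
  median_effect_fit(data.frame(dose_uM = d,
                               fa = (d / Dm)^m / (1 + (d / Dm)^m)))
}

test_that("sham self-combinations are exactly additive at every effect level", {
  fit <- sham_fit()
  for (fa in c(0.1, 0.25, 0.5, 0.75, 0.95)) {
    res <- combination_index(list(a = fit, b = fit), c(0.5, 0.5), fit, fa = fa)
    expect_equal(res$ci, 1, tolerance = 1e-10)
  }
  # unequal sham split is still additive
  res <- combination_index(list(a = fit, b = fit), c(0.3, 0.7), fit, fa = 0.5)
  expect_equal(res$ci, 1, tolerance = 1e-10)
  # 12-component equimolar sham cocktail
  fits <- rep(list(fit), 12)
  res12 <- combination_index(fits, rep(1 / 12, 12), fit, fa = 0.5)
  expect_equal(res12$ci, 1, tolerance = 1e-10)
})

test_that("a mixture reaching the effect at half the additive dose has CI 0.5", {
  f1 <- sham_fit(m = 1.2, Dm = 0.5)
  f2 <- sham_fit(m = 1.2, Dm = 1.5)
  # Loewe-additive total dose at fa = 0.5 for a 50/50 mix:
  # D_add with 0.5*D/Dx1 + 0.5*D/Dx2 = 1
  d_add <- 1 / (0.5 / dose_for_effect(f1, 0.5) + 0.5 / dose_for_effect(f2, 0.5))
  combo <- sham_fit(m = 1.2, Dm = d_add / 2)  # combo Dm at half the additive dose
  res <- combination_index(list(f1, f2), c(0.5, 0.5), combo, fa = 0.5)
  expect_equal(res$ci, 0.5, tolerance = 1e-8)
  expect_equal(res$label, "synergy")
  expect_error(combination_index(list(f1, f2), c(0.5, 0.6), combo), "sum to 1")
})

test_that("interaction classification follows the CI bands", {
  expect_equal(classify_interaction(0.15), "synergy")
  expect_equal(classify_interaction(210), "antagonism")
  expect_equal(classify_interaction(1.10), "additive")
  expect_equal(classify_interaction(c(0.89999, 0.9, 1.1, 1.10001)),
               c("synergy", "additive", "additive", "antagonism"))
  expect_error(classify_interaction(0), "positive")
})

test_that("interaction matrices build per line and agree into a consensus", {
  res <- data.frame(
    cell_line = c("L1", "L1", "L2", "L2"),
    target_a = c("A", "A", "A", "A"),
    target_b = c("B", "C", "B", "C"),
    ci = c(0.2, 5, 0.3, 0.4))
  im <- interaction_matrix(res)
  expect_equal(im$per_line$L1["A", "B"], "synergy")
  expect_equal(im$per_line$L1["B", "A"], "synergy")
  expect_equal(im$consensus["A", "B"], "synergy")     # both lines agree
  expect_equal(im$consensus["A", "C"], "discordant")  # antagonism vs synergy
  dup <- rbind(res, data.frame(cell_line = "L1", target_a = "B",
                               target_b = "A", ci = 1))
  expect_error(interaction_matrix(dup), "duplicate pair")
  # random labels match a brute-force agreement check
  set.seed(66)
  labs <- c("synergy", "additive", "antagonism")
  rnd <- expand.grid(cell_line = c("L1", "L2", "L3"),
                     target_a = "A", target_b = c("B", "C", "D"),
                     stringsAsFactors = FALSE)
  rnd$label <- sample(labs, nrow(rnd), replace = TRUE)
  im2 <- interaction_matrix(rnd)
  for (tb in c("B", "C", "D")) {
    calls <- unique(rnd$label[rnd$target_b == tb])
    want <- if (length(calls) == 1) calls else "discordant"
    expect_equal(im2$consensus["A", tb], want)
  }
})

test_that("plate TSV reader validates its columns", {
  p <- tempfile()
  utils::write.table(make_plate(fa_by_dose = c(`0.3` = 0.2)), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  plate <- read_plate(p)
  expect_true(all(c("well", "treatment", "dose_uM", "fluorescence") %in%
                    names(plate)))
  writeLines("a\tb\nc\td", p)
  expect_error(read_plate(p), "missing column")
})
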