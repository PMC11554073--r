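test_that("cohort generation honors schema, endpoint coding and determinism", {
  cfg <- small_config()
  model <- kps_outcome_model(intercept = 0.2)
  co <- simulate_cohort(12, model, config = cfg, seed = 11)

  expect_s3_class(co, "kps_cohort")
  expect_equal(nrow(co$records), 12)
  expect_length(clinical_parameter_names(), 28)
  expect_true(all(clinical_parameter_names() %in% names(co$records)))
  expect_true(all(co$records$preop_kps %% 10 == 0))
  expect_true(all(co$records$postop_kps_6mo %% 10 == 0))
  expect_true(all(co$records$postop_kps_6mo >= 0 &
                    co$records$postop_kps_6mo <= 100))
  expect_true(all(vapply(co$studies, function(s)
    inherits(s$pre, "label_volume") && inherits(s$post, "label_volume"),
    NA)))

  co2 <- simulate_cohort(12, model, config = cfg, seed = 11)
  expect_identical(serialize(co, NULL), serialize(co2, NULL))

  expect_error(simulate_cohort(5, model, config = cfg), ">= 10")
  expect_error(
    simulate_cohort(12, kps_outcome_model(clinical_coefs = c(bogus = 1)),
                    config = cfg, seed = 1),
    "unknown clinical parameter")
})

test_that("all-zero coefficients reduce to intercept-only prevalence", {
  cfg <- small_config(volumes = FALSE)
  co <- simulate_cohort(400, kps_outcome_model(intercept = 0), config = cfg,
                        seed = 21)
  prev <- mean(co$records$postop_kps_6mo < 70)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("binary marginals match their configured targets at n = 1000", {
  cfg <- small_config(volumes = FALSE)
  co <- simulate_cohort(1000, kps_outcome_model(), config = cfg, seed = 31)
  for (nm in names(cfg$binary_marginals)) {
    p <- cfg$binary_marginals[[nm]]
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(mean(co$records[[nm]]) - p), 3 * se, label = nm)
  }
  lat <- table(factor(co$records$laterality,
                      levels = names(cfg$laterality_probs))) / 1000
  expect_true(all(abs(lat - cfg$laterality_probs) <
                    3 * sqrt(cfg$laterality_probs *
                               (1 - cfg$laterality_probs) / 1000)))
})

test_that("planted covariate signals are recovered by a logistic refit", {
  cfg <- small_config(volumes = FALSE)
  model <- kps_outcome_model(
    intercept = -0.2,
    clinical_coefs = c(age = 1.2, preop_kps = -1.0),
    morphology_coefs = c(post_core_volume = 1.0))
  co <- simulate_cohort(500, model, config = cfg, seed = 41)
  y <- as.integer(co$records$postop_kps_6mo < 70)
  z <- function(x) as.numeric(scale(x))
  fit <- glm(y ~ z(co$records$age) + z(co$records$preop_kps) +
               z(co$morphology$post_core_volume), family = binomial)
  expect_gt(coef(fit)[2], 0)   # age increases risk
  expect_lt(coef(fit)[3], 0)   # preoperative KPS is protective
  expect_gt(coef(fit)[4], 0)   # residual core volume increases risk

  old <- co$records$age > median(co$records$age)
  tab <- table(old, y)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 1)
})

test_that("tumor volumes are nested ellipsoid label maps", {
  g <- test_geometry()
  v <- simulate_tumor_volume(g, grid_shape = c(16, 32, 32))
  tab <- tabulate(v$labels + 1L, nbins = 4L)
  expect_true(all(tab > 0))                       # all four classes present
  expect_gte(tab[2], tab[3])                      # brain >= edema

  # brute-force recount of the core from the ellipsoid inequality
  cnt <- 0L
  for (i in 1:16) for (j in 1:32) for (k in 1:32) {
    inside_core <- sum(((c(i, j, k) - g$center) / g$core_radii)^2) <= 1
    inside_brain <- sum(((c(i, j, k) - g$brain$center) / g$brain$radii)^2) <= 1
    if (inside_core && inside_brain) cnt <- cnt + 1L
  }
  expect_equal(sum(v$labels == 3L), cnt)
  # nesting: core and edema voxels only inside the brain mask
  expect_true(all(v$labels[v$labels >= 2L] >= 1L))

  g0 <- g; g0$core_radii <- c(0, 0, 0)
  expect_error(simulate_tumor_volume(g0, c(16, 32, 32)), "> 0")
  g_out <- g; g_out$center <- c(2, 2, 2)
  expect_error(simulate_tumor_volume(g_out, c(16, 32, 32)), "does not fit")
})

test_that("resection removes the prescribed fraction of the lesion core", {
  v <- simulate_tumor_volume(test_geometry(), grid_shape = c(16, 32, 32))
  n_core <- sum(v$labels == 3L)
  expect_gt(n_core, 0)

  post_full <- apply_resection(v, "100%", seed = 5)
  expect_equal(sum(post_full$labels == 3L), 0L)

  post_gtr <- apply_resection(v, "90-99%", seed = 5)
  frac <- sum(post_gtr$labels == 3L) / n_core
  expect_gt(frac, 0.005)
  expect_lte(frac, 0.105)

  post_partial <- apply_resection(v, "1-49%", seed = 5)
  frac2 <- sum(post_partial$labels == 3L) / n_core
  expect_gte(frac2, 0.505)
  expect_lt(frac2, 0.995)

  # resected voxels become brain, never background or edema
  expect_true(all(post_gtr$labels[v$labels == 3L] %in% c(1L, 3L)))

  expect_error(apply_resection(v, "50%", seed = 1), "unknown extent")
  empty <- label_volume(array(1L, c(4, 4, 4)))
  expect_error(apply_resection(empty, "100%"), "no lesion-core")
})

test_that("clinical tables round-trip through CSV", {
  co <- small_cohort()
  path <- tempfile(fileext = ".csv")
  write_clinical_csv(co, path)
  back <- read_clinical_csv(path)
  expect_equal(nrow(back), nrow(co$records))
  expect_identical(back$patient_id, co$records$patient_id)
  expect_identical(back$operation_date, co$records$operation_date)
  expect_equal(back$radiation_dose, co$records$radiation_dose)
  bad <- back[, -match("aphasia", names(back))]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_clinical_csv(path2), "aphasia")
})

test_that("optional missingness only blanks clinical parameters", {
  cfg <- small_config(volumes = FALSE, missing_rate = 0.1)
  co <- simulate_cohort(100, kps_outcome_model(), config = cfg, seed = 8)
  n_na <- sum(is.na(co$records[, clinical_parameter_names()]))
  expect_gt(n_na, 0)
  expect_false(anyNA(co$records$patient_id))
  expect_false(anyNA(co$records$postop_kps_6mo))
})
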