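#' Default synthetic-cohort configuration
#'
#' Target marginals for the clinical table mirror the published baseline
#' characteristics of a 150-patient single-center IDH wild-type glioblastoma
#' cohort (e.g. 43.3% female, 18% biopsy-only surgery, median age 64), so the
#' generator's defaults emulate the population the analysis is designed for.
#' Volumes are parametric label maps on a 64 x 64 in-plane grid with 32 axial
#' slices of 3 mm.
#'
#' @param grid_shape Integer length-3: slices, height, width.
#' @param spacing mm per axis (slice, row, column).
#' @param date_range Character length-2, ISO dates bounding operation dates.
#' @param volumes Logical; generate label volumes (`TRUE`) or only analytic
#'   morphology covariates (`FALSE`, for large calibration runs).
#' @param missing_rate Fraction of clinical cells blanked at random to
#'   exercise the imputation path (default 0).
#' @return A named list of generator settings.
#' @export
cohort_config <- function(grid_shape = c(32, 64, 64), spacing = c(3, 1, 1),
                          date_range = c("2001-12-01", "2022-12-31"),
                          volumes = TRUE, missing_rate = 0) {
  list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    date_range = as.Date(date_range), volumes = isTRUE(volumes),
    missing_rate = missing_rate,
    binary_marginals = c(
      sex = 0.433,              # female fraction
      dominant_hand = 0.98,     # right-handed fraction
      epilepsy = 0.267, aphasia = 0.28, paralysis = 0.447,
      other_neuro = 0.68, surgery_biopsy = 0.18, awake_surgery = 0.36,
      five_ala = 0.52, pdt = 0.047, carmustine = 0.24, mep_sep = 0.507,
      mgmt_methylation = 0.34, tertp = 0.327, mgmt_ihc = 0.36,
      tmz = 0.947, bevacizumab = 0.433, ependymal_invasion = 0.713,
      midline_shift = 0.42, corpus_callosum_invasion = 0.273,
      necrosis_cyst = 0.92),
    laterality_probs = c(right = 0.50, left = 0.42, bilateral = 0.08),
    extent_probs = c("1-49%" = 0.20, "50-89%" = 0.14,
                     "90-99%" = 0.287, "100%" = 0.373),
    age = list(mean = 64, sd = 13, range = c(18, 92)),
    preop_kps = list(mean = 80, sd = 18),
    mib1 = list(mean = 25, sd = 15, range = c(0, 90)),
    radiation = list(none_prob = 0.08, elderly_age = 70,
                     standard = c(dose = 60, fractions = 30),
                     hypofractionated = c(dose = 40.05, fractions = 15)))
}

#' Extent-of-resection categories
#'
#' Ordered levels of the extent-of-resection parameter and the fraction of the
#' lesion core each category removes.
#' @export
extent_levels <- function() c("1-49%", "50-89%", "90-99%", "100%")

extent_fraction_range <- function(extent) {
  switch(extent,
         "1-49%"  = c(0.01, 0.49),
         "50-89%" = c(0.50, 0.89),
         "90-99%" = c(0.90, 0.99),
         "100%"   = c(1.00, 1.00),
         stop("unknown extent-of-resection category: ", extent))
}

#' Planted logistic outcome model
#'
#' The synthetic endpoint (6-month postoperative KPS < 70) is drawn from a
#' logistic model over standardized generative covariates: named clinical
#' parameters plus three morphology summaries (`pre_core_volume`,
#' `post_core_volume`, `edema_volume`, in voxels). Continuous covariates are
#' z-scored within the cohort before the coefficients apply; binary ones enter
#' as 0/1 and extent of resection as its 0-3 ordinal code. With all
#' coefficients zero every patient has event probability `plogis(intercept)`.
#'
#' @param intercept Real; baseline log-odds.
#' @param clinical_coefs Named numeric vector over clinical parameter names.
#' @param morphology_coefs Named numeric over the three morphology summaries.
#' @param noise_scale SD of extra latent Gaussian noise on the log-odds.
#' @return An object of class `kps_outcome_model`.
#' @export
kps_outcome_model <- function(intercept = 0, clinical_coefs = numeric(),
                              morphology_coefs = numeric(), noise_scale = 0) {
  stopifnot(noise_scale >= 0)
  morph_ok <- c("pre_core_volume", "post_core_volume", "edema_volume")
  if (length(morphology_coefs) && !all(names(morphology_coefs) %in% morph_ok))
    stop("unknown morphology covariate(s): ",
         paste(setdiff(names(morphology_coefs), morph_ok), collapse = ", "))
  structure(list(intercept = intercept, clinical_coefs = clinical_coefs,
                 morphology_coefs = morphology_coefs,
                 noise_scale = noise_scale),
            class = "kps_outcome_model")
}

clinical_parameter_names <- function() {
  c("sex", "age", "dominant_hand", "epilepsy", "aphasia", "paralysis",
    "other_neuro", "preop_kps", "surgery_biopsy", "awake_surgery", "five_ala",
    "pdt", "carmustine", "mep_sep", "mgmt_methylation", "tertp", "mib1_index",
    "mgmt_ihc", "tmz", "bevacizumab", "radiation_dose", "radiation_fractions",
    "laterality", "ependymal_invasion", "midline_shift",
    "corpus_callosum_invasion", "necrosis_cyst", "extent_of_resection")
}

#' Simulate a parametric tumor label volume
#'
#' Builds a label map from nested ellipsoids: a brain ellipsoid (class 1), an
#' edema shell (class 2) and a lesion core (class 3). An optional jitter
#' roughens the core/edema boundaries by perturbing the ellipsoid inequality
#' per voxel.
#'
#' @param geometry List with `center` (voxel coords, slice/row/col),
#'   `core_radii` (3 positive voxel radii), `edema_margin` (shell thickness in
#'   voxels), `brain` (list with `center`, `radii`).
#' @param grid_shape Integer length-3 array dimensions.
#' @param spacing,patient_id,timepoint Passed to [label_volume()].
#' @param jitter Nonnegative amplitude of the boundary perturbation.
#' @param seed Optional integer seed (only needed when `jitter > 0`).
#' @return A [label_volume()].
#' @export
simulate_tumor_volume <- function(geometry, grid_shape, spacing = c(3, 1, 1),
                                  patient_id = "unknown", timepoint = "pre",
                                  jitter = 0, seed = NULL) {
  g <- geometry
  if (any(g$core_radii <= 0)) stop("core radii must all be > 0")
  if (g$edema_margin <= 0) stop("edema margin must be > 0")
  d <- as.integer(grid_shape)
  tumor_r <- g$core_radii + g$edema_margin
  if (any(g$center - tumor_r < 1) || any(g$center + tumor_r > d))
    stop("tumor geometry does not fit inside the grid")
  if (any(g$brain$center - g$brain$radii < 0.5) ||
      any(g$brain$center + g$brain$radii > d + 0.5))
    stop("brain ellipsoid does not fit inside the grid")

  quad <- function(center, radii) {
    ax <- lapply(1:3, function(k) ((seq_len(d[k]) - center[k]) / radii[k])^2)
    outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- array(0L, d)
  labels[quad(g$brain$center, g$brain$radii) <= 1] <- 1L
  eps <- if (jitter > 0) array(stats::runif(prod(d), -jitter, jitter), d) else 0
  edema <- quad(g$center, tumor_r) + eps <= 1 & labels == 1L
  core <- quad(g$center, g$core_radii) + eps <= 1 & labels == 1L
  labels[edema] <- 2L
  labels[core] <- 3L
  label_volume(labels, spacing = spacing, patient_id = patient_id,
               timepoint = timepoint)
}

#' Apply a resection to a preoperative volume
#'
#' Relabels a random subset of lesion-core voxels to brain parenchyma. The
#' resected fraction is drawn uniformly within the range of the requested
#' extent-of-resection category; category `"100%"` removes every core voxel.
#'
#' @param pre A preoperative [label_volume()] containing class-3 voxels.
#' @param extent One of [extent_levels()].
#' @param seed Integer seed.
#' @return A postoperative [label_volume()].
#' @export
apply_resection <- function(pre, extent, seed = 1L) {
  stopifnot(inherits(pre, "label_volume"))
  rng <- extent_fraction_range(extent)
  idx <- which(pre$labels == 3L)
  if (length(idx) == 0L) stop("preoperative volume has no lesion-core voxels")
  set.seed(seed)
  f <- stats::runif(1, rng[1], rng[2])
  n_remove <- if (extent == "100%") length(idx) else
    min(length(idx), max(1L, round(f * length(idx))))
  removed <- sample(idx, n_remove)
  labels <- pre$labels
  labels[removed] <- 1L
  label_volume(labels, spacing = pre$spacing, patient_id = pre$patient_id,
               timepoint = "post")
}

sample_tumor_geometry <- function(config) {
  d <- config$grid_shape
  brain <- list(center = (d + 1) / 2, radii = pmax(d / 2 - 2, 3))
  for (try in 1:50) {
    core_radii <- c(stats::runif(1, 2, min(5, brain$radii[1] - 3)),
                    stats::runif(2, 4, min(11, brain$radii[2] - 4)))
    margin <- stats::runif(1, 1.5, 4)
    slack <- brain$radii - (core_radii + margin) - 1.5
    if (any(slack <= 0)) next
    off <- stats::runif(3, -1, 1) * slack * 0.8
    center <- brain$center + off
    tumor_r <- core_radii + margin
    # conservative containment check: tumor ellipsoid inside brain ellipsoid
    if (all(abs(off) + tumor_r < brain$radii) &&
        all(center - tumor_r >= 1) && all(center + tumor_r <= d))
      return(list(center = center, core_radii = core_radii,
                  edema_margin = margin, brain = brain))
  }
  stop("could not place a tumor inside the brain ellipsoid")
}

# Analytic ellipsoid voxel-volume approximation used when volumes = FALSE.
ellipsoid_voxels <- function(radii) 4 / 3 * pi * prod(radii)

#' Simulate a complete synthetic cohort
#'
#' Draws `n_patients` clinical records whose marginals follow the configured
#' targets, one pre-operative tumor label volume per patient, a post-operative
#' volume obtained by resecting the core according to the sampled extent of
#' resection, and a binary 6-month KPS endpoint from the planted logistic
#' outcome model. The observed KPS value is placed on the 10-point grid on the
#' side of 70 implied by the binary label.
#'
#' @param n_patients Number of patients (>= 10).
#' @param outcome_model A [kps_outcome_model()].
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical cohorts.
#' @return A `kps_cohort`: list with `records` (data.frame, one row per
#'   patient), `studies` (per patient: `pre`, `post` label volumes unless
#'   `config$volumes` is `FALSE`), `morphology` (data.frame of generative
#'   tumor covariates in voxels), `config`, `seed`.
#' @export
simulate_cohort <- function(n_patients, outcome_model = kps_outcome_model(),
                            config = cohort_config(), seed = 1L) {
  if (n_patients < 10) stop("`n_patients` must be >= 10")
  stopifnot(inherits(outcome_model, "kps_outcome_model"))
  unknown <- setdiff(names(outcome_model$clinical_coefs),
                     clinical_parameter_names())
  if (length(unknown))
    stop("outcome model references unknown clinical parameter(s): ",
         paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- as.integer(n_patients)
  ids <- sprintf("P%04d", seq_len(n))

  dates <- sort(sample(seq(config$date_range[1], config$date_range[2],
                           by = "day"), n, replace = TRUE))
  rec <- data.frame(patient_id = ids, operation_date = dates,
                    stringsAsFactors = FALSE)
  for (nm in names(config$binary_marginals))
    rec[[nm]] <- stats::rbinom(n, 1, config$binary_marginals[[nm]])
  rec$laterality <- sample(names(config$laterality_probs), n, replace = TRUE,
                           prob = config$laterality_probs)
  rec$extent_of_resection <- sample(names(config$extent_probs), n,
                                    replace = TRUE, prob = config$extent_probs)
  a <- config$age
  rec$age <- as.integer(round(pmin(pmax(stats::rnorm(n, a$mean, a$sd),
                                        a$range[1]), a$range[2])))
  k <- config$preop_kps
  rec$preop_kps <- pmin(pmax(round(stats::rnorm(n, k$mean, k$sd) / 10) * 10,
                             10L), 100L)
  m <- config$mib1
  rec$mib1_index <- round(pmin(pmax(stats::rnorm(n, m$mean, m$sd),
                                    m$range[1]), m$range[2]), 1)
  r <- config$radiation
  no_rt <- stats::rbinom(n, 1, r$none_prob) == 1
  elderly <- rec$age >= r$elderly_age
  rec$radiation_dose <- ifelse(no_rt, 0,
                               ifelse(elderly, r$hypofractionated["dose"],
                                      r$standard["dose"]))
  rec$radiation_fractions <- as.integer(
    ifelse(no_rt, 0, ifelse(elderly, r$hypofractionated["fractions"],
                            r$standard["fractions"])))

  # Tumor morphology: geometry first, then resection per sampled extent.
  studies <- vector("list", n)
  names(studies) <- ids
  morph <- data.frame(patient_id = ids, pre_core_volume = NA_real_,
                      post_core_volume = NA_real_, edema_volume = NA_real_)
  geom_seeds <- sample.int(2^30, n)
  for (i in seq_len(n)) {
    set.seed(geom_seeds[i])
    g <- sample_tumor_geometry(config)
    if (config$volumes) {
      pre <- simulate_tumor_volume(g, config$grid_shape, config$spacing,
                                   patient_id = ids[i], timepoint = "pre")
      post <- apply_resection(pre, rec$extent_of_resection[i],
                              seed = geom_seeds[i] + 1L)
      studies[[i]] <- list(pre = pre, post = post, geometry = g)
      morph$pre_core_volume[i] <- sum(pre$labels == 3L)
      morph$post_core_volume[i] <- sum(post$labels == 3L)
      morph$edema_volume[i] <- sum(pre$labels == 2L)
    } else {
      core_v <- ellipsoid_voxels(g$core_radii)
      edema_v <- ellipsoid_voxels(g$core_radii + g$edema_margin) - core_v
      rng <- extent_fraction_range(rec$extent_of_resection[i])
      f <- stats::runif(1, rng[1], rng[2])
      morph$pre_core_volume[i] <- core_v
      morph$post_core_volume[i] <- core_v * (1 - f)
      morph$edema_volume[i] <- edema_v
      studies[[i]] <- list(geometry = g)
    }
  }

  eta <- outcome_linear_predictor(rec, morph, outcome_model)
  set.seed(seed + 1L)
  if (outcome_model$noise_scale > 0)
    eta <- eta + stats::rnorm(n, 0, outcome_model$noise_scale)
  label <- stats::rbinom(n, 1, stats::plogis(eta))
  rec$postop_kps_6mo <- ifelse(label == 1,
                               sample(seq(0L, 60L, 10L), n, replace = TRUE),
                               sample(seq(70L, 100L, 10L), n, replace = TRUE))

  if (config$missing_rate > 0) {
    maskable <- setdiff(clinical_parameter_names(), character())
    for (nm in maskable) {
      hit <- stats::runif(n) < config$missing_rate
      rec[[nm]][hit] <- NA
    }
  }

  structure(list(records = rec, studies = studies, morphology = morph,
                 config = config, seed = as.integer(seed)),
            class = "kps_cohort")
}

# Standardized linear predictor of the planted outcome model.
outcome_linear_predictor <- function(records, morphology, model) {
  zsc <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mean(x)) / s
  }
  eta <- rep(model$intercept, nrow(records))
  continuous <- c("age", "preop_kps", "mib1_index", "radiation_dose",
                  "radiation_fractions")
  for (nm in names(model$clinical_coefs)) {
    x <- records[[nm]]
    if (nm == "extent_of_resection")
      x <- match(x, extent_levels()) - 1
    else if (nm == "laterality")
      x <- as.numeric(x == "bilateral")
    else if (nm %in% continuous)
      x <- zsc(x)
    eta <- eta + model$clinical_coefs[[nm]] * x
  }
  for (nm in names(model$morphology_coefs))
    eta <- eta + model$morphology_coefs[[nm]] * zsc(morphology[[nm]])
  eta
}

#' @export
print.kps_cohort <- function(x, ...) {
  n <- nrow(x$records)
  pos <- sum(x$records$postop_kps_6mo < 70)
  cat(sprintf("<kps_cohort> %d patients, %d with 6-month KPS < 70 (%.1f%%)\n",
              n, pos, 100 * pos / n))
  cat(sprintf("  volumes: %s, grid %s, seed %d\n",
              if (x$config$volumes) "label maps" else "analytic only",
              paste(x$config$grid_shape, collapse = "x"), x$seed))
  invisible(x)
}

#' Write the clinical table of a cohort to CSV
#'
#' One row per patient; dates in ISO-8601; fixed column order given by the
#' documented schema (id, date, the 28 clinical parameters, endpoint).
#'
#' @param cohort A `kps_cohort`.
#' @param path Output CSV path.
#' @export
write_clinical_csv <- function(cohort, path) {
  cols <- c("patient_id", "operation_date", clinical_parameter_names(),
            "postop_kps_6mo")
  df <- cohort$records[, cols]
  df$operation_date <- format(df$operation_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a clinical table written by [write_clinical_csv()]
#' @param path CSV path.
#' @return A data.frame in schema order.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "operation_date", clinical_parameter_names(),
            "postop_kps_6mo")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("clinical table is missing column(s): ",
         paste(missing, collapse = ", "))
  df$operation_date <- as.Date(df$operation_date)
  df[, need]
}
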