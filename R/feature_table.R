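#' Encode clinical records as a numeric block
#'
#' The 28 clinical parameters map to 30 numeric columns: 21 binaries stay
#' 0/1, laterality becomes a 3-column one-hot (treated downstream as a single
#' logical parameter), extent of resection its ordinal code 0-3, and the five
#' continuous parameters (age, preoperative KPS, MIB-1 index, radiation dose,
#' radiation fractions) are z-scored. Scaling statistics are taken from
#' `stats` when supplied (always the training split in model fitting, to
#' avoid leakage) and computed from `records` otherwise. Missing values are
#' imputed first: train median for continuous columns, train mode for
#' binary/categorical ones; the returned imputation report lists every
#' imputed cell count.
#'
#' @param records Data frame in the clinical schema (see
#'   [read_clinical_csv()]).
#' @param stats Optional encoding statistics from a previous call (training
#'   split); contains medians/modes for imputation and mean/sd for scaling.
#' @return List with `values` (matrix), `feature_names`, `stats`,
#'   `imputation_report` (data.frame parameter/n_imputed).
#' @export
encode_clinical <- function(records, stats = NULL) {
  params <- clinical_parameter_names()
  missing_cols <- setdiff(params, names(records))
  if (length(missing_cols))
    stop("records are missing clinical parameter(s): ",
         paste(missing_cols, collapse = ", "))
  continuous <- c("age", "preop_kps", "mib1_index", "radiation_dose",
                  "radiation_fractions")
  binaries <- setdiff(params, c(continuous, "laterality",
                                "extent_of_resection"))
  lat_levels <- c("right", "left", "bilateral")

  mode_of <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("all-missing clinical column")
    names(sort(table(x), decreasing = TRUE))[1]
  }
  if (is.null(stats)) {
    stats <- list(
      medians = vapply(continuous, function(nm)
        stats::median(records[[nm]], na.rm = TRUE), 1),
      modes = vapply(c(binaries, "laterality", "extent_of_resection"),
                     function(nm) mode_of(records[[nm]]), ""),
      center = NULL, scale = NULL)
  }

  imputed <- integer(0)
  rec <- records
  for (nm in continuous) {
    na <- is.na(rec[[nm]])
    if (any(na)) rec[[nm]][na] <- stats$medians[[nm]]
    imputed[nm] <- sum(na)
  }
  for (nm in c(binaries, "laterality", "extent_of_resection")) {
    na <- is.na(rec[[nm]])
    if (any(na)) {
      fill <- stats$modes[[nm]]
      rec[[nm]][na] <- if (is.numeric(rec[[nm]])) as.numeric(fill) else fill
    }
    imputed[nm] <- sum(na)
  }

  bad_lat <- setdiff(unique(rec$laterality), lat_levels)
  if (length(bad_lat))
    stop("unknown laterality level(s): ", paste(bad_lat, collapse = ", "))
  bad_eor <- setdiff(unique(rec$extent_of_resection), extent_levels())
  if (length(bad_eor))
    stop("unknown extent-of-resection level(s): ",
         paste(bad_eor, collapse = ", "))

  cols <- list()
  for (nm in binaries) cols[[nm]] <- as.numeric(rec[[nm]])
  for (lv in lat_levels)
    cols[[paste0("laterality_", lv)]] <- as.numeric(rec$laterality == lv)
  cols$extent_of_resection <- match(rec$extent_of_resection,
                                    extent_levels()) - 1
  for (nm in continuous) cols[[nm]] <- as.numeric(rec[[nm]])
  X <- do.call(cbind, cols)
  rownames(X) <- rec$patient_id

  if (is.null(stats$center)) {
    ctr <- colMeans(X[, continuous, drop = FALSE])
    scl <- apply(X[, continuous, drop = FALSE], 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    stats$center <- ctr
    stats$scale <- scl
  }
  X[, continuous] <- sweep(sweep(X[, continuous, drop = FALSE], 2,
                                 stats$center, "-"), 2, stats$scale, "/")
  if (any(!is.finite(X))) stop("non-finite values after clinical encoding")
  list(values = X, feature_names = colnames(X), stats = stats,
       imputation_report = data.frame(parameter = names(imputed),
                                      n_imputed = unname(imputed)))
}

# Feature-group partition of the clinical columns: laterality's 3 one-hot
# columns form one group, every other parameter is its own singleton.
clinical_feature_groups <- function(feature_names) {
  groups <- list()
  for (nm in feature_names) {
    g <- if (startsWith(nm, "laterality_")) "laterality" else nm
    groups[[g]] <- c(groups[[g]], nm)
  }
  groups
}

#' Attach extracted MRI features to a cohort
#'
#' Runs slice-window selection, channel splitting and latent extraction for
#' every patient with both timepoints, and stores the resulting feature
#' matrix (and per-column groups) on the cohort.
#'
#' @param cohort A `kps_cohort` with label volumes.
#' @param vae1,vae2 Trained lesion and brain-mask VAEs.
#' @param augment Passed to [assemble_mri_features()].
#' @return The cohort with `mri` (matrix) and `mri_groups` set.
#' @export
extract_cohort_features <- function(cohort, vae1, vae2, augment = FALSE) {
  stopifnot(inherits(cohort, "kps_cohort"))
  ids <- cohort$records$patient_id
  rows <- list()
  groups <- NULL
  for (id in ids) {
    st <- cohort$studies[[id]]
    if (is.null(st$pre) || is.null(st$post))
      stop("patient ", id, " lacks label volumes; cannot extract MRI features")
    pre <- split_channels(st$pre, window = vae1$config$input_shape[1])
    post <- split_channels(st$post, window = vae1$config$input_shape[1])
    f <- assemble_mri_features(pre, post, vae1, vae2, augment = augment)
    rows[[id]] <- f$values
    groups <- f$groups
  }
  cohort$mri <- do.call(rbind, rows)
  cohort$mri_groups <- groups
  cohort
}

#' Build a design matrix for one model variant
#'
#' Assembles the analysis matrix for the clinical-only, MRI-only or
#' multimodal model. Rows are sorted by patient id so identical cohorts give
#' identical matrices regardless of input order; labels (1 = 6-month
#' postoperative KPS < 70) are aligned by patient id and identical across
#' modes. Clinical scaling statistics are computed on `train_ids` only when
#' given.
#'
#' @param cohort A `kps_cohort`; for modes `"mri"`/`"multimodal"` it must
#'   carry MRI features (see [extract_cohort_features()]).
#' @param mode `"clinical"`, `"mri"` or `"multimodal"`.
#' @param train_ids Optional patient ids defining the scaling population.
#' @param subset Optional patient ids to keep (after sorting).
#' @param scale_mri Standardize each MRI latent column (mean 0, sd 1 over the
#'   scaling population). Off by default: the KL prior already centers the
#'   latents, but their per-dimension scales can differ by orders of
#'   magnitude, which the neural network's shared initialization dislikes.
#' @return A `kps_feature_matrix`: list with `values`, `feature_names`,
#'   `feature_groups`, `label`, `patient_ids`, `mode`.
#' @export
build_matrix <- function(cohort, mode = c("clinical", "mri", "multimodal"),
                         train_ids = NULL, subset = NULL, scale_mri = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "kps_cohort"))
  rec <- cohort$records[order(cohort$records$patient_id), , drop = FALSE]

  if (mode != "clinical") {
    if (is.null(cohort$mri))
      stop("cohort has no MRI features; run extract_cohort_features() first")
    absent <- setdiff(rec$patient_id, rownames(cohort$mri))
    if (length(absent)) {
      warning("excluding patient(s) without MRI features: ",
              paste(absent, collapse = ", "))
      rec <- rec[!rec$patient_id %in% absent, , drop = FALSE]
    }
  }
  if (!is.null(subset)) rec <- rec[rec$patient_id %in% subset, , drop = FALSE]

  stats <- NULL
  if (!is.null(train_ids)) {
    tr <- cohort$records[cohort$records$patient_id %in% train_ids, ,
                         drop = FALSE]
    stats <- encode_clinical(tr)$stats
  }
  enc <- encode_clinical(rec, stats = stats)

  blocks <- list()
  groups <- list()
  if (mode %in% c("clinical", "multimodal")) {
    blocks$clinical <- enc$values
    groups <- clinical_feature_groups(enc$feature_names)
  }
  if (mode %in% c("mri", "multimodal")) {
    M <- cohort$mri[rec$patient_id, , drop = FALSE]
    if (scale_mri) {
      ref_ids <- if (!is.null(train_ids))
        intersect(rownames(cohort$mri), train_ids) else rec$patient_id
      if (!length(ref_ids))
        stop("no MRI rows available to compute scaling statistics")
      ctr <- colMeans(cohort$mri[ref_ids, , drop = FALSE])
      scl <- apply(cohort$mri[ref_ids, , drop = FALSE], 2, stats::sd)
      scl[!is.finite(scl) | scl < 1e-8] <- 1
      M <- sweep(sweep(M, 2, ctr, "-"), 2, scl, "/")
    }
    blocks$mri <- M
    for (g in unique(cohort$mri_groups))
      groups[[g]] <- colnames(M)[cohort$mri_groups == g]
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- rec$patient_id
  structure(list(values = values, feature_names = colnames(values),
                 feature_groups = groups,
                 label = as.integer(rec$postop_kps_6mo < 70),
                 patient_ids = rec$patient_id, mode = mode),
            class = "kps_feature_matrix")
}

#' @export
print.kps_feature_matrix <- function(x, ...) {
  cat(sprintf("<kps_feature_matrix> mode=%s, %d patients x %d features, %d events\n",
              x$mode, nrow(x$values), ncol(x$values), sum(x$label)))
  invisible(x)
}
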