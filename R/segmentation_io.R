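#' Construct a label volume
#'
#' A `label_volume` is the atomic imaging object of the pipeline: a 3D integer
#' label map for one patient at one timepoint, as produced by an upstream
#' tumor segmentation tool. Axis 1 is the axial slice axis. Voxel classes are
#' `0` background, `1` brain parenchyma, `2` peritumoral edema / non-enhancing
#' tumor, and `3` lesion core (enhancing tumor, necrosis, cysts).
#'
#' @param labels 3D integer array, slices x height x width, values in 0..3.
#' @param spacing Numeric length-3, mm per axis in `(slice, row, column)`
#'   order. Default `c(3, 1, 1)`: 3-mm axial slices, 1-mm in plane.
#' @param patient_id Character scalar.
#' @param timepoint `"pre"` or `"post"` (operative).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(3, 1, 1), patient_id = "unknown",
                         timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array (slices x height x width)")
  if (any(is.na(labels)) || any(labels != round(labels)))
    stop("`labels` must be integer-valued with no missing voxels")
  if (!all(labels %in% 0:3))
    stop("label classes must lie in {0, 1, 2, 3}")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel dimensions in mm")
  structure(
    list(labels = array(as.integer(labels), dim(labels)),
         spacing = as.numeric(spacing),
         patient_id = as.character(patient_id), timepoint = timepoint),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %s [%s] %d x %d x %d voxels, spacing %s mm\n",
              x$patient_id, x$timepoint, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x ")))
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf("  background %d | brain %d | edema %d | core %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Tumor area on each axial slice
#'
#' Measures the lesion-core area (class 3 only; edema is excluded) on every
#' slice, in mm^2, using the in-plane voxel area. This drives selection of the
#' slice window passed to the autoencoders.
#'
#' @param volume A [label_volume()].
#' @return Numeric vector, one area per slice.
#' @export
tumor_area_per_slice <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$labels)
  if (prod(d) == 0L) stop("empty volume")
  core <- volume$labels == 3L
  dim(core) <- c(d[1], d[2] * d[3])
  rowSums(core) * volume$spacing[2] * volume$spacing[3]
}

# Symmetric zero-padding bookkeeping for volumes shorter than the window.
pad_before_slices <- function(n_slices, window) {
  if (n_slices >= window) 0L else as.integer(floor((window - n_slices) / 2))
}

#' Select the slice window containing the largest tumor
#'
#' Chooses the start of a fixed-length window of slices such that the slice
#' with the largest tumor area sits as close to the window center as the
#' volume boundaries allow. Ties between two equally central starts are broken
#' toward the earlier start. An all-zero area vector (no measurable tumor,
#' e.g. after complete resection) falls back to centering the window on the
#' middle slice. Volumes with fewer slices than the window are symmetrically
#' zero-padded and the returned start refers to the padded stack (always 1).
#'
#' @param areas Numeric vector of per-slice tumor areas.
#' @param window Window length in slices (default 24).
#' @return Integer start index (1-based) of the selected window.
#' @export
select_slice_window <- function(areas, window = 24L) {
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1")
  n <- length(areas)
  if (n == 0L) stop("empty area vector")
  if (n <= window) return(1L)
  m <- if (all(areas == 0)) as.integer(floor((n + 1) / 2)) else which.max(areas)
  center_offset <- (window - 1) / 2
  s_ideal <- m - center_offset
  cand <- unique(pmin(pmax(c(floor(s_ideal), ceiling(s_ideal)), 1L),
                      n - window + 1L))
  dev <- abs(m - (cand + center_offset))
  as.integer(cand[which.min(dev)]) # which.min takes the first = smaller start
}

#' Split a slice window into lesion channels and brain mask
#'
#' Restricts a label volume to the selected window and separates it into the
#' two inputs of the feature extractor: a two-channel lesion stack (channel 1
#' = lesion core, channel 2 = edema) and a one-channel brain mask (any
#' non-background class). Short volumes are symmetrically zero-padded to the
#' window length.
#'
#' @param volume A [label_volume()].
#' @param window_start Start index from [select_slice_window()]. If `NULL`,
#'   it is computed from [tumor_area_per_slice()].
#' @param window Window length (default 24).
#' @return A `slice_stack`: list with `lesion` (window x H x W x 2),
#'   `brain_mask` (window x H x W x 1), `window_start`, `spacing`,
#'   `patient_id`, `timepoint`.
#' @export
split_channels <- function(volume, window_start = NULL, window = 24L) {
  stopifnot(inherits(volume, "label_volume"))
  window <- as.integer(window)
  d <- dim(volume$labels)
  if (is.null(window_start))
    window_start <- select_slice_window(tumor_area_per_slice(volume), window)
  n <- d[1]
  padded <- array(0L, c(max(n, window), d[2], d[3]))
  pb <- pad_before_slices(n, window)
  padded[pb + seq_len(n), , ] <- volume$labels
  if (window_start < 1L || window_start + window - 1L > dim(padded)[1])
    stop("window does not fit inside the (padded) volume")
  win <- padded[window_start + 0:(window - 1L), , , drop = FALSE]
  lesion <- array(0, c(window, d[2], d[3], 2L))
  lesion[, , , 1] <- win == 3L
  lesion[, , , 2] <- win == 2L
  mask <- array(as.numeric(win >= 1L), c(window, d[2], d[3], 1L))
  structure(
    list(lesion = lesion, brain_mask = mask,
         window_start = as.integer(window_start), spacing = volume$spacing,
         patient_id = volume$patient_id, timepoint = volume$timepoint),
    class = "slice_stack")
}

#' Read / write label volumes as NIfTI-1
#'
#' Volumes are stored with the in-plane axes first and the slice axis third
#' (the NIfTI convention), as int16, with voxel spacing in the header; reading
#' restores the package's slice-axis-first array layout. Files holding
#' non-integer data or classes outside 0..3 are rejected.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume A [label_volume()].
#' @param patient_id,timepoint Metadata to attach on read (NIfTI has no
#'   standard field for them).
#' @return `read_label_volume()` returns a [label_volume()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
read_label_volume <- function(path, patient_id = "unknown",
                              timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  if (any(arr != round(arr)))
    stop("non-integer voxel data; not a label volume: ", path)
  if (!all(arr %in% 0:3))
    stop("label classes outside {0,1,2,3}: ", path)
  pd <- RNifti::pixdim(img)
  labels <- aperm(arr, c(3, 1, 2))
  label_volume(labels, spacing = c(pd[3], pd[1], pd[2]),
               patient_id = patient_id, timepoint = timepoint)
}

#' @rdname read_label_volume
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  arr <- aperm(volume$labels, c(2, 3, 1))
  sp <- volume$spacing
  img <- RNifti::asNifti(arr,
    reference = list(pixdim = c(-1, sp[2], sp[3], sp[1], 0, 0, 0, 0)),
    datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}
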