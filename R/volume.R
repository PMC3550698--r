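#' Short-axis SPECT count volume
#'
#' Container for a reconstructed myocardial SPECT volume already reoriented to
#' the short axis (automatic reorientation from transaxial data is out of
#' scope; it is scanner-specific). Slices are stored apex-first: if
#' `apex_first = FALSE` the slice order is reversed on construction so that
#' slice 1 is always the most apical slice.
#'
#' @param counts 3D numeric array of non-negative tracer counts, dimensions
#'   `(slice, row, col)`.
#' @param voxel_size_mm numeric length-3: voxel size in mm along
#'   (slice, row, col).
#' @param tracer one of `"TL_STRESS"`, `"TL_REST"`, `"BMIPP"`.
#' @param apex_first logical; `TRUE` if slice 1 is the apex.
#' @return An object of class `short_axis_volume`.
#' @export
short_axis_volume <- function(counts, voxel_size_mm = c(6, 3, 3),
                              tracer = c("TL_STRESS", "TL_REST", "BMIPP"),
                              apex_first = TRUE) {
  tracer <- match.arg(tracer)
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3D array (slice, row, col)")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts must be finite and non-missing")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (dim(counts)[1] < 5L)
    stop("need at least 5 short-axis slices along the long axis")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive values")
  if (!apex_first)
    counts <- counts[dim(counts)[1]:1, , , drop = FALSE]
  structure(
    list(counts = counts,
         voxel_size_mm = as.numeric(voxel_size_mm),
         tracer = tracer),
    class = "short_axis_volume")
}

#' @export
print.short_axis_volume <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<short_axis_volume> %s: %d slices x %d x %d, voxel %s mm, max count %.1f\n",
              x$tracer, d[1], d[2], d[3],
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              max(x$counts)))
  invisible(x)
}

#' Read a short-axis volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` volume. The tracer label (and optionally voxel
#' size and apex orientation) come from a JSON sidecar with the same stem and
#' extension `.json`, or can be given directly; a direct argument wins over
#' the sidecar.
#'
#' @param path NIfTI file path.
#' @param tracer tracer label; if `NULL`, taken from the sidecar.
#' @param apex_first logical or `NULL` (sidecar, defaulting to `TRUE`).
#' @return A [short_axis_volume()].
#' @export
read_volume <- function(path, tracer = NULL, apex_first = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume in ", path)
  # NIfTI stores (x, y, z); short-axis slices are along z -> (slice, row, col)
  arr <- aperm(arr, c(3, 2, 1))
  pix <- RNifti::pixdim(img)
  vox <- c(pix[3], pix[2], pix[1])
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(tracer)) tracer <- meta$tracer_label
  if (is.null(tracer))
    stop("tracer label missing: pass `tracer` or provide a JSON sidecar for ", path)
  if (is.null(apex_first)) apex_first <- isTRUE(meta$apex_first) || is.null(meta$apex_first)
  if (!is.null(meta$voxel_size_mm)) vox <- unlist(meta$voxel_size_mm)
  short_axis_volume(arr, voxel_size_mm = vox, tracer = tracer,
                    apex_first = apex_first)
}

#' Write a short-axis volume to NIfTI plus JSON sidecar
#'
#' @param volume a [short_axis_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "short_axis_volume"))
  arr <- aperm(volume$counts, c(3, 2, 1))
  img <- RNifti::asNifti(arr, pixdim = volume$voxel_size_mm[c(3, 2, 1)])
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(tracer_label = volume$tracer,
         voxel_size_mm = volume$voxel_size_mm,
         apex_first = TRUE),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
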