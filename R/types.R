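#' Construct a 3D image volume
#'
#' A minimal container for a scalar 3D grid with physical voxel spacing.
#' Axis order is (slice, row, col); spacing is millimetres per axis in the
#' same order.
#'
#' @param data 3D numeric array of voxel intensities (all finite).
#' @param spacing Numeric length-3 vector of voxel spacing in mm, all > 0.
#' @param case_id Character scalar identifying the case.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), case_id = "case") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume must be a 3D array")
  if (!all(is.finite(data))) stop("volume contains non-finite intensities")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive values (mm)")
  }
  structure(list(data = data, spacing = spacing, case_id = as.character(case_id)),
            class = "image_volume")
}

#' Construct a binary tumor mask
#'
#' @param data 3D array coercible to logical; `TRUE`/non-zero marks tumor.
#' @param case_id Character scalar identifying the case.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(data, case_id = "case") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask must be a 3D array")
  m <- array(data != 0, dim = dim(data))
  if (!any(m)) stop("mask has no foreground voxels")
  structure(list(data = m, case_id = as.character(case_id)), class = "tumor_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s: %s voxels, spacing %s mm>\n", x$case_id,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask %s: %s grid, %d foreground voxels>\n", x$case_id,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop(sprintf("volume grid %s and mask grid %s are not aligned",
                 paste(dim(volume$data), collapse = "x"),
                 paste(dim(mask$data), collapse = "x")))
  }
  invisible(TRUE)
}

# Deterministic sub-seed streams: one global seed fans out to per-case and
# per-stage seeds by fixed arithmetic, so adding a case never reshuffles the
# others. All values kept below 2^31 - 1.
derive_seed <- function(seed, stream, index = 0L) {
  offsets <- c(volume = 104729, counts = 15485863, sets = 32452843,
               dedup = 49979687, model = 67867967, split = 86028121)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.double(seed) + offsets[[stream]] + 7919 * as.double(index)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
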