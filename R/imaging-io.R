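#' Co-registered T1-weighted / T2-FLAIR volume pair
#'
#' Container for a pair of already-preprocessed (bias-corrected,
#' skull-stripped, registered) volumes. Bias correction, skull-stripping
#' and MNI152 registration are an external-preprocessing contract: this
#' package accepts their output, it does not implement them.
#'
#' @param t1,flair 3D numeric arrays of identical dimensions, finite values.
#' @param pixdim Voxel spacing metadata (length 3, default `c(1, 1, 1)`).
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(t1, flair, pixdim = c(1, 1, 1)) {
  stopifnot(length(dim(t1)) == 3, length(dim(flair)) == 3)
  if (!identical(dim(t1), dim(flair)))
    stop_pirasurv("t1 and flair volumes have mismatched shapes",
                  "pirasurv_shape_mismatch")
  if (!all(is.finite(t1)) || !all(is.finite(flair)))
    stop_pirasurv("volumes must contain finite values", "pirasurv_bad_input")
  structure(list(t1 = array(as.numeric(t1), dim(t1)),
                 flair = array(as.numeric(flair), dim(flair)),
                 pixdim = as.numeric(pixdim)),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  cat(sprintf("Volume pair %s, pixdim (%s)\n",
              paste(dim(x$t1), collapse = " x "),
              paste(x$pixdim, collapse = ", ")))
  invisible(x)
}

#' Min–max intensity normalization
#'
#' Rescales a whole volume to `[0, 1]` by `(x - min) / (max - min)`. For a
#' [volume_pair()] the rescaling is applied per channel (per volume), which
#' preserves inter-slice contrast within each channel.
#'
#' @param x Numeric array, or a `volume_pair`.
#' @return Object of the same type with values in `[0, 1]`.
#' @examples
#' minmax_normalize(array(c(10, 20, 30, 10, 20, 30, 10, 30), c(2, 2, 2)))
#' @export
minmax_normalize <- function(x) UseMethod("minmax_normalize")

#' @export
minmax_normalize.default <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) == 0)
    stop_pirasurv("degenerate intensity range: constant volume",
                  "pirasurv_degenerate")
  (x - rng[1]) / diff(rng)
}

#' @export
minmax_normalize.volume_pair <- function(x) {
  volume_pair(minmax_normalize.default(x$t1),
              minmax_normalize.default(x$flair), pixdim = x$pixdim)
}

#' Extract the central axial slices of a volume pair
#'
#' The axial axis is the third array axis by convention. For a depth-`Z`
#' volume and `n` slices, the selected 0-based indices are
#' `floor((Z - n)/2) .. floor((Z - n)/2) + n - 1`, counted on the array
#' grid (not brain-mask-centred).
#'
#' @param x A [volume_pair()] (or a single 3D array).
#' @param n Number of slices (default 40).
#' @param normalize Apply per-volume [minmax_normalize()] before slicing
#'   (default `TRUE` for pairs).
#' @return For a pair, a `slice_stack`: array `(H, W, 2, n)` with channel
#'   order (T1, FLAIR) and attribute `indices` (1-based axial indices).
#'   For a plain array, an `(H, W, n)` array with the same attribute.
#' @examples
#' v <- array(runif(8 * 8 * 10), c(8, 8, 10))
#' attr(central_slices(v, 4), "indices") # 4:7 (0-based 3..6)
#' @export
central_slices <- function(x, n = 40L, normalize = TRUE) {
  arr <- if (inherits(x, "volume_pair")) x$t1 else x
  Z <- dim(arr)[3]
  if (Z < n)
    stop_pirasurv(sprintf(
      "volume has %d axial slices but %d were requested; lower n", Z, n),
      "pirasurv_bad_input")
  lo <- floor((Z - n) / 2) # 0-based first index
  idx <- lo + seq_len(n)   # 1-based
  if (inherits(x, "volume_pair")) {
    if (normalize) x <- minmax_normalize(x)
    out <- array(0, c(dim(arr)[1], dim(arr)[2], 2L, n))
    out[, , 1L, ] <- x$t1[, , idx]
    out[, , 2L, ] <- x$flair[, , idx]
    attr(out, "indices") <- idx
    class(out) <- "slice_stack"
    out
  } else {
    out <- arr[, , idx, drop = FALSE]
    attr(out, "indices") <- idx
    out
  }
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Slice stack: %d slices of %d x %d, 2 channels (T1, FLAIR)\n",
              d[4], d[1], d[2]))
  invisible(x)
}

#' Read a co-registered volume pair from NIfTI files
#'
#' Validates shape consistency; affine (s/q-form) disagreement beyond an
#' absolute tolerance of `1e-4` triggers a warning (the pair is still
#' returned, as registration is an upstream contract).
#'
#' @param t1_path,flair_path NIfTI file paths (`.nii` / `.nii.gz`).
#' @return A [volume_pair()].
#' @export
load_volume_pair <- function(t1_path, flair_path) {
  t1 <- RNifti::readNifti(t1_path)
  fl <- RNifti::readNifti(flair_path)
  if (!identical(dim(t1), dim(fl)))
    stop_pirasurv("NIfTI volumes have mismatched shapes",
                  "pirasurv_shape_mismatch")
  a1 <- RNifti::xform(t1); a2 <- RNifti::xform(fl)
  pd1 <- RNifti::pixdim(t1); pd2 <- RNifti::pixdim(fl)
  if (max(abs(a1 - a2)) > 1e-4 ||
      max(abs(pd1 - pd2)) > 1e-4)
    warning("volume affines differ beyond 1e-4; assuming co-registration",
            call. = FALSE)
  pd <- pd1
  volume_pair(as.array(t1), as.array(fl), pixdim = pd[seq_len(3)])
}

#' Write a volume pair (or any 3D array) as NIfTI
#'
#' @param pair A [volume_pair()].
#' @param t1_path,flair_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_volume_pair <- function(pair, t1_path, flair_path) {
  stopifnot(inherits(pair, "volume_pair"))
  one <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pair$pixdim
    RNifti::writeNifti(img, path)
  }
  one(pair$t1, t1_path)
  one(pair$flair, flair_path)
  invisible(c(t1_path, flair_path))
}

#' Write a slice stack as a 4D NIfTI volume
#'
#' Stores the `(H, W, channel, slice)` array as-is; the original axial
#' indices travel in the header description only informally, so this is a
#' cache/export format, not a round-trip of the source volume.
#'
#' @param stack A `slice_stack` from [central_slices()].
#' @param path Output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  arr <- array(as.numeric(stack), dim(stack))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read an integer-labelled parcellation volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return An integer 3D array of region labels (0 = background).
#' @export
load_parcellation <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (any(arr < 0) || any(!is_wholeish(arr)))
    stop_pirasurv("parcellation must contain non-negative integer labels",
                  "pirasurv_bad_input")
  array(as.integer(round(arr)), dim(arr))
}
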