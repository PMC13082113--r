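# Mask algebra at 1H resolution and mutually exclusive downsampling of
# ROIs onto the coarse 13C grid.

#' Bundle of 1H-resolution anatomical masks
#'
#' Holds the binary brain, T2-hyperintense lesion (T2L),
#' contrast-enhancing lesion (CEL) and white-matter (WM) volumes on a
#' shared 1H grid, plus the derived non-enhancing lesion (NEL) and
#' normal-appearing white matter (NAWM) once [derive_rois()] has run.
#'
#' @param brain,t2l,cel,wm Logical (or 0/1) 3D arrays on one grid.
#' @param voxel_dims Numeric triple of voxel dimensions in mm.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(brain, t2l, cel, wm, voxel_dims) {
  vols <- list(brain = brain, t2l = t2l, cel = cel, wm = wm)
  dims <- dim(brain)
  for (nm in names(vols)) {
    v <- vols[[nm]]
    if (!identical(dim(v), dims))
      stop("mask '", nm, "' is not on the shared grid", call. = FALSE)
    if (!all(v %in% c(0, 1, TRUE, FALSE)))
      stop("mask '", nm, "' is not binary", call. = FALSE)
    vols[[nm]] <- array(as.logical(v), dims)
  }
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0))
    stop("voxel_dims must be three positive lengths in mm", call. = FALSE)
  structure(c(vols, list(voxel_dims = as.numeric(voxel_dims))),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  d <- dim(x$brain)
  cat(sprintf("1H mask set %dx%dx%d at %g x %g x %g mm\n", d[1], d[2], d[3],
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]))
  for (nm in intersect(c("brain", "t2l", "cel", "wm", "nel", "nawm"), names(x)))
    cat(sprintf("  %-5s %d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Derive NEL and NAWM from the primary masks
#'
#' The non-enhancing lesion is the T2 lesion minus the enhancing lesion
#' (`nel = t2l & !cel`); normal-appearing white matter is white matter
#' minus any T2-lesion overlap (`nawm = wm & !t2l`). Inputs are left
#' unmodified; the derived volumes are added to the returned set.
#'
#' @param masks A [mask_set()].
#' @return The mask set with `nel` and `nawm` filled.
#' @export
derive_rois <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  masks$nel <- masks$t2l & !masks$cel
  masks$nawm <- masks$wm & !masks$t2l
  masks
}

# Block-sum an array whose dims are an exact multiple `f` of the coarse
# dims. Returns the coarse-grid array of block sums.
.block_sum <- function(a, f) {
  d <- dim(a)
  n <- d / f
  if (any(n != round(n)))
    stop("1H grid is not an integer block refinement of the 13C grid",
         call. = FALSE)
  b <- array(a, c(f, n[1], f, n[2], f, n[3]))
  apply(b, c(2, 4, 6), sum)
}

#' Downsample 1H ROIs onto the 13C grid with mutually exclusive labels
#'
#' For every 13C voxel the fraction of its volume covered by the 1H T2L
#' (and NAWM) mask is computed exactly from the block refinement. Voxels
#' with a T2L fraction of at least `t2l_frac` are labeled `"T2L"`
#' (inclusive threshold). Of the remaining voxels, those with an NAWM
#' fraction of at least `nawm_frac` are labeled `"NAWM"`; everything
#' else is `"NONE"`. T2L labeling therefore takes precedence: a voxel
#' can never carry both labels.
#'
#' The fraction is of the 13C voxel's own volume (not of the total
#' lesion volume), so labels do not depend on overall lesion size.
#'
#' @param t2l_1h,nawm_1h Logical 3D masks on the 1H grid.
#' @param factor Integer block size (1H voxels per 13C voxel per axis).
#' @param t2l_frac,nawm_frac Inclusive overlap thresholds (defaults 0.30
#'   and 0.50).
#' @return An object of class `roi_label_map`: `labels` (character 3D
#'   array over {"T2L","NAWM","NONE"} on the 13C grid), `frac_t2l`,
#'   `frac_nawm` (overlap-fraction maps retained for audit), `factor`.
#' @export
downsample_rois <- function(t2l_1h, nawm_1h, factor,
                            t2l_frac = 0.30, nawm_frac = 0.50) {
  if (!identical(dim(t2l_1h), dim(nawm_1h)))
    stop("t2l and nawm masks must share the 1H grid", call. = FALSE)
  if (factor < 1 || factor != round(factor))
    stop("factor must be a positive integer", call. = FALSE)
  block <- factor^3
  frac_t2l <- .block_sum(t2l_1h * 1, factor) / block
  frac_nawm <- .block_sum(nawm_1h * 1, factor) / block
  labels <- array("NONE", dim(frac_t2l))
  labels[frac_t2l >= t2l_frac] <- "T2L"
  labels[labels != "T2L" & frac_nawm >= nawm_frac] <- "NAWM"
  structure(
    list(labels = labels, frac_t2l = frac_t2l, frac_nawm = frac_nawm,
         factor = as.integer(factor)),
    class = "roi_label_map"
  )
}

#' @export
print.roi_label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("13C ROI labels %dx%dx%d: %d T2L, %d NAWM, %d unlabeled\n",
              d[1], d[2], d[3], sum(x$labels == "T2L"),
              sum(x$labels == "NAWM"), sum(x$labels == "NONE")))
  invisible(x)
}

#' Downsample a single 1H mask to the 13C grid by fractional overlap
#'
#' Convenience wrapper over the exact block-refinement geometry: a 13C
#' voxel is kept when at least `frac` of its volume is covered by the 1H
#' mask. Used e.g. to carry the brain mask to the 13C grid for
#' percentile ranking and background-noise estimation.
#'
#' @param mask_1h Logical 3D mask on the 1H grid.
#' @param factor Integer block size (1H voxels per 13C voxel per axis).
#' @param frac Inclusive minimum overlap fraction (default 0.5).
#' @return Logical 3D mask on the 13C grid.
#' @export
downsample_mask <- function(mask_1h, factor, frac = 0.5) {
  .block_sum(mask_1h * 1, factor) / factor^3 >= frac
}

#' Mask volume in cubic centimeters
#'
#' @param mask Logical 3D array.
#' @param voxel_dims Numeric triple of voxel dimensions in mm.
#' @return Volume in cm^3.
#' @export
volume_cc <- function(mask, voxel_dims) {
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0))
    stop("voxel_dims must be three positive lengths in mm", call. = FALSE)
  sum(mask) * prod(voxel_dims) / 1000
}

#' Percent change of a volume relative to baseline
#'
#' Returns `100 * (v - v0) / v0`, or `NA` when the baseline volume is
#' zero or missing (e.g. a patient with no enhancing lesion), never an
#' infinity.
#'
#' @param v Follow-up volume (cm^3).
#' @param v0 Baseline volume (cm^3).
#' @return Percent change, or `NA_real_` when undefined.
#' @export
volume_percent_change <- function(v, v0) {
  ifelse(is.na(v0) | is.na(v) | v0 <= 0, NA_real_, 100 * (v - v0) / v0)
}
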