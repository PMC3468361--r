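## VOI definition, co-registration and TAC extraction.

## 6-connectivity binary dilation by one voxel.
dilate6 <- function(a) {
    d <- dim(a)
    out <- a
    out[-1, , ] <- out[-1, , ] | a[-d[1L], , ]
    out[-d[1L], , ] <- out[-d[1L], , ] | a[-1, , ]
    out[, -1, ] <- out[, -1, ] | a[, -d[2L], ]
    out[, -d[2L], ] <- out[, -d[2L], ] | a[, -1, ]
    out[, , -1] <- out[, , -1] | a[, , -d[3L]]
    out[, , -d[3L]] <- out[, , -d[3L]] | a[, , -1]
    out
}

## Connected component (6-connectivity) of `mask` containing `seed`
## (linear index), by iterative frontier growth.
connectedComponent <- function(mask, seed) {
    comp <- array(FALSE, dim(mask))
    comp[seed] <- TRUE
    repeat {
        grown <- dilate6(comp) & mask
        if (sum(grown) == sum(comp)) break
        comp <- grown
    }
    comp
}

#' Threshold-based VOI on a static image
#'
#' Selects voxels at or above `fraction` of the image maximum, restricted
#' to the 6-connected component containing the maximum voxel (so a
#' second, cooler lesion crossing the threshold is not swept in).
#'
#' @param image a static (3-D) [VolumeImage-class]; typically the FDG-SUV
#'   volume, thresholded at 75 percent of the tumour maximum.
#' @param fraction threshold fraction of the maximum, in (0, 1);
#'   default 0.75.
#' @return a [VOIMask-class] with provenance recording the fraction,
#'   source modality and source maximum.
#' @export
thresholdVOI <- function(image, fraction = 0.75) {
    stopifnot(is(image, "VolumeImage"))
    if (length(dim(image@data)) != 3L)
        stop("thresholdVOI requires a static (3-D) image")
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction >= 1)
        stop("'fraction' must lie strictly between 0 and 1")
    mx <- max(image@data)
    if (mx <= 0)
        stop("degenerate input: image has no positive voxels")
    raw <- image@data >= fraction * mx
    comp <- connectedComponent(raw, which.max(image@data))
    voiMask(comp, image@voxelSize,
            provenance = list(method = "threshold", fraction = fraction,
                              sourceModality = image@modality,
                              sourceMax = mx))
}

#' Rigid co-registration of attenuation images
#'
#' Exhaustive search over integer-voxel translations within a window,
#' maximising the normalised cross-correlation between the shifted moving
#' image and the fixed image over their overlap. Ties are broken toward
#' the smallest shift norm. Intended for the attenuation pair of two
#' studies of the same patient; the returned shift aligns the moving
#' study onto the fixed study's grid and can be applied to a VOI with
#' [transferVOI()].
#'
#' @param moving,fixed attenuation [VolumeImage-class] objects on grids of
#'   equal dimensions.
#' @param searchWindowMm half-width of the search window (mm) per axis.
#' @return list with `shift` (integer voxels, length 3) and `correlation`
#'   (the attained normalised cross-correlation, exposed for QC).
#' @export
registerAttenuation <- function(moving, fixed, searchWindowMm = 12) {
    stopifnot(is(moving, "VolumeImage"), is(fixed, "VolumeImage"))
    if (moving@modality != "attenuation" || fixed@modality != "attenuation")
        stop("both images must be attenuation volumes")
    d <- dim(fixed@data)
    if (!identical(d, dim(moving@data)))
        stop("images must share grid dimensions")
    w <- floor(searchWindowMm / fixed@voxelSize)
    if (any(2L * w + 1L > d))
        stop("search window larger than the image")
    shifts <- as.matrix(expand.grid(x = -w[1L]:w[1L], y = -w[2L]:w[2L],
                                    z = -w[3L]:w[3L]))
    shifts <- shifts[order(rowSums(shifts^2)), , drop = FALSE]
    best <- -Inf
    bestShift <- c(0L, 0L, 0L)
    for (i in seq_len(nrow(shifts))) {
        s <- shifts[i, ]
        ov <- overlapRanges(d, s)
        fa <- fixed@data[ov$fx, ov$fy, ov$fz]
        ma <- moving@data[ov$mx, ov$my, ov$mz]
        if (stats::sd(fa) == 0 || stats::sd(ma) == 0) next
        cc <- stats::cor(as.vector(fa), as.vector(ma))
        if (cc > best + 1e-12) {    # strict: earlier (smaller) shifts win ties
            best <- cc
            bestShift <- as.integer(s)
        }
    }
    list(shift = bestShift, correlation = best)
}

## Index ranges of the overlap when the moving image is translated by
## `s` voxels onto the fixed grid: fixed index = moving index + s.
overlapRanges <- function(d, s) {
    f1 <- pmax(1L, 1L + s)
    f2 <- pmin(d, d + s)
    if (any(f2 < f1)) stop("shift leaves no overlap")
    list(fx = f1[1L]:f2[1L], fy = f1[2L]:f2[2L], fz = f1[3L]:f2[3L],
         mx = (f1[1L] - s[1L]):(f2[1L] - s[1L]),
         my = (f1[2L] - s[2L]):(f2[2L] - s[2L]),
         mz = (f1[3L] - s[3L]):(f2[3L] - s[3L]))
}

#' Translate a VOI mask between co-registered studies
#'
#' Applies an integer-voxel shift (as returned by
#' [registerAttenuation()]) to a mask, cropping at the image boundary.
#' The voxel count is preserved unless cropped; a shift that pushes the
#' whole mask out of the grid is an error.
#'
#' @param mask a [VOIMask-class].
#' @param shift integer voxel translation, length 3.
#' @return the translated [VOIMask-class].
#' @export
transferVOI <- function(mask, shift) {
    stopifnot(is(mask, "VOIMask"), length(shift) == 3L)
    s <- as.integer(round(shift))
    d <- dim(mask@mask)
    if (any(abs(s) >= d))
        stop("degenerate shift: mask fully outside the image")
    out <- array(FALSE, d)
    ov <- overlapRanges(d, s)
    out[ov$fx, ov$fy, ov$fz] <- mask@mask[ov$mx, ov$my, ov$mz]
    if (!any(out))
        stop("degenerate shift: mask fully outside the image")
    prov <- mask@provenance
    prov$shift <- s
    voiMask(out, mask@voxelSize, prov)
}

#' Duration-weighted summed image of a dynamic volume
#'
#' Sums selected frames of a 4-D dynamic volume weighted by their
#' durations (a time integral in kBq s / mL per voxel). The default
#' frame range covers the frames ending within the first 30 s, the early
#' bolus passage used to visualise the descending aorta.
#'
#' @param dynamic a 4-D [VolumeImage-class].
#' @param frameRange integer indices of the frames to sum; default the
#'   frames entirely within the first 30 s.
#' @return a static [VolumeImage-class] with modality "summed".
#' @export
summedImage <- function(dynamic, frameRange = NULL) {
    stopifnot(is(dynamic, "VolumeImage"))
    if (length(dim(dynamic@data)) != 4L)
        stop("summedImage requires a dynamic (4-D) volume")
    sched <- schedule(dynamic)
    if (is.null(frameRange))
        frameRange <- which(frameEnd(sched) <= 30 + 1e-9)
    frameRange <- as.integer(frameRange)
    if (length(frameRange) == 0L ||
        any(frameRange < 1L | frameRange > nFrames(sched)))
        stop("empty or out-of-range frame selection")
    dur <- frameDuration(sched)
    d <- dim(dynamic@data)
    acc <- array(0, d[1:3])
    for (f in frameRange)
        acc <- acc + dur[f] * dynamic@data[, , , f]
    volumeImage(acc, dynamic@voxelSize, modality = "summed")
}

#' Extract a VOI-mean time-activity curve
#'
#' Per-frame mean of the dynamic volume over the mask voxels.
#'
#' @param dynamic a 4-D [VolumeImage-class].
#' @param mask a [VOIMask-class] on the same grid.
#' @return a [TimeActivityCurve-class] carrying the volume's schedule and
#'   decay-correction flag.
#' @export
extractTAC <- function(dynamic, mask) {
    stopifnot(is(dynamic, "VolumeImage"), is(mask, "VOIMask"))
    if (length(dim(dynamic@data)) != 4L)
        stop("extractTAC requires a dynamic (4-D) volume")
    if (!identical(dim(dynamic@data)[1:3], dim(mask@mask)))
        stop("mask grid does not match the dynamic volume")
    if (!any(mask@mask)) stop("empty mask")
    sched <- schedule(dynamic)
    vals <- vapply(seq_len(nFrames(sched)), function(f)
        mean(dynamic@data[, , , f][mask@mask]), numeric(1))
    timeActivityCurve(sched, vals, isDecayCorrected(dynamic))
}

#' Descending-aorta VOI from the summed early image
#'
#' Sums the early dynamic frames and thresholds within a user-supplied
#' search box (index ranges), standing in for manual vessel markup. The
#' connected-component rule of [thresholdVOI()] applies inside the box.
#'
#' @param dynamic a 4-D [VolumeImage-class] of the water study.
#' @param box list with elements `x`, `y`, `z`, each `c(min, max)` voxel
#'   indices of the search region; default the whole grid.
#' @param fraction threshold fraction of the in-box maximum (default
#'   0.5 -- vessels are segmented at half maximum, which tolerates the
#'   noise amplification of a bright compact structure better than the
#'   tumour threshold does).
#' @param frameRange frames to sum (default: first 30 s).
#' @return a [VOIMask-class] on the full image grid.
#' @export
aortaVOI <- function(dynamic, box = NULL, fraction = 0.5,
                     frameRange = NULL) {
    summed <- summedImage(dynamic, frameRange)
    d <- dim(summed@data)
    if (is.null(box))
        box <- list(x = c(1L, d[1L]), y = c(1L, d[2L]), z = c(1L, d[3L]))
    ix <- box$x[1L]:box$x[2L]
    iy <- box$y[1L]:box$y[2L]
    iz <- box$z[1L]:box$z[2L]
    sub <- volumeImage(summed@data[ix, iy, iz, drop = FALSE],
                       summed@voxelSize, modality = "summed")
    voi <- thresholdVOI(sub, fraction)
    full <- array(FALSE, d)
    full[ix, iy, iz] <- voi@mask
    prov <- voi@provenance
    prov$searchBox <- box
    voiMask(full, summed@voxelSize, prov)
}
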