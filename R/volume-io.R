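#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the package's [VolumeImage-class]
#' metadata (voxel size; modality and frame schedule must be re-supplied
#' on read, NIfTI having no standard slot for them). Masks are written as
#' 0/1 volumes. Axis order is voxel-index space as stored, 0-based on
#' disk, 1-based in R.
#'
#' @param path file path (".nii" or ".nii.gz").
#' @param modality modality tag to attach on read.
#' @param sched a [FrameSchedule-class] for 4-D files.
#' @param decayCorrected logical flag to attach on read.
#' @return [readVolume()] returns a [VolumeImage-class]; the writers
#'   return `path` invisibly.
#' @export
readVolume <- function(path, modality = "unknown", sched = NULL,
                       decayCorrected = TRUE) {
    img <- RNifti::readNifti(path)
    vox <- RNifti::pixdim(img)[1:3]
    arr <- array(as.double(img), dim = dim(img))
    volumeImage(arr, vox, modality = modality, schedule = sched,
                decayCorrected = decayCorrected)
}

#' @rdname readVolume
#' @param image a [VolumeImage-class].
#' @export
writeVolume <- function(image, path) {
    stopifnot(is(image, "VolumeImage"))
    nd <- length(dim(image@data))
    img <- RNifti::asNifti(image@data)
    RNifti::pixdim(img) <- if (nd == 4L) c(image@voxelSize, 1)
                           else image@voxelSize
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname readVolume
#' @param mask a [VOIMask-class].
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "VOIMask"))
    img <- RNifti::asNifti(array(as.double(mask@mask), dim(mask@mask)))
    RNifti::pixdim(img) <- mask@voxelSize
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
    img <- RNifti::readNifti(path)
    voiMask(array(as.double(img) > 0.5, dim = dim(img)),
            RNifti::pixdim(img)[1:3],
            provenance = list(method = "file", path = path))
}

#' Read and write time-activity curves as CSV
#'
#' The interchange format has columns `frame_start_s`,
#' `frame_duration_s`, `activity_kBq_per_mL` and an optional
#' `decay_corrected` column (constant 0/1).
#'
#' @param tac a [TimeActivityCurve-class].
#' @param path file path.
#' @return [readTAC()] returns a [TimeActivityCurve-class]; [writeTAC()]
#'   returns `path` invisibly.
#' @export
writeTAC <- function(tac, path) {
    stopifnot(is(tac, "TimeActivityCurve"))
    sch <- schedule(tac)
    utils::write.csv(data.frame(
        frame_start_s = frameStart(sch),
        frame_duration_s = frameDuration(sch),
        activity_kBq_per_mL = activity(tac),
        decay_corrected = as.integer(isDecayCorrected(tac))),
        path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTAC
#' @export
readTAC <- function(path) {
    df <- utils::read.csv(path)
    need <- c("frame_start_s", "frame_duration_s", "activity_kBq_per_mL")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("TAC file missing columns: ", paste(miss, collapse = ", "))
    dc <- if ("decay_corrected" %in% names(df))
        as.logical(df$decay_corrected[1L]) else TRUE
    timeActivityCurve(frameSchedule(df$frame_start_s, df$frame_duration_s),
                      df$activity_kBq_per_mL, dc)
}
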