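## Pipeline drivers tying VOI definition, registration, TAC extraction and
## kinetic fitting together, plus the cohort statistics report. All
## drivers log stages to stderr via message() and write results to files
## only, so they compose in scripts.

#' Default pipeline configuration
#'
#' Returns the full set of tunable pipeline parameters with their
#' defaults; pass overrides as a named list (or a YAML file of the same
#' shape) to [runPerfusion()]. Unknown keys are rejected.
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
    list(thresholdFraction = 0.75,
         aortaFraction = 0.5,
         aortaBox = NULL,
         registrationWindowMm = 12,
         nBasis = 48,
         betaMax = 300,
         vascularCutoff = 2,
         delayMin = -10, delayMax = 20, delayStep = 2,
         inputModel = "gamma",
         fineStep = 0.5,
         outputDir = NULL,
         seed = 1L)
}

mergeConfig <- function(config) {
    base <- defaultConfig()
    if (is.null(config)) return(base)
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    bad <- setdiff(names(config),
                   c(names(base), "volumes", "paths", "schedule", "phantom"))
    if (length(bad))
        stop("unknown configuration keys: ", paste(bad, collapse = ", "))
    base[names(config)] <- config
    base
}

configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                                force = TRUE), tmp)
    unname(tools::md5sum(tmp))
}

provenanceBlock <- function(config) {
    list(package = "waterPET",
         version = as.character(utils::packageVersion("waterPET")),
         configHash = configHash(config[setdiff(names(config), "volumes")]),
         seed = config$seed)
}

#' Run the tumour-perfusion pipeline
#'
#' Executes the full quantification chain on one patient study:
#' FDG-based tumour VOI (threshold at the configured fraction of the
#' maximum), attenuation-image co-registration and VOI transfer onto the
#' water study, descending-aorta VOI from the summed early frames, VOI
#' mean TAC extraction for tumour and aorta, delay estimation, spectral
#' deconvolution and the nonlinear one-tissue fit. Each stage logs its
#' parameters; any stage failure aborts with a stage-labelled error.
#'
#' @param volumes named list with `water` (4-D [VolumeImage-class]),
#'   `waterAtten`, `fdg`, `fdgAtten`; alternatively give NIfTI paths plus
#'   a schedule under `config$paths` / `config$schedule`.
#' @param config named list of overrides of [defaultConfig()], or a YAML
#'   file path.
#' @return list with the VOIs, shift, TACs, delay, `spectral`
#'   ([SpectralResult-class]), `nonlinear` fit, a `report` of perfusion
#'   estimates under both conventions, and a `provenance` block. When
#'   `config$outputDir` is set, writes `perfusion_report.json` and the
#'   tumour/aorta TAC CSVs there.
#' @export
runPerfusion <- function(volumes = NULL, config = list()) {
    config <- mergeConfig(config)
    if (is.null(volumes)) {
        if (is.null(config$paths))
            stop("[input] no volumes and no paths configured")
        sch <- if (!is.null(config$schedule))
            frameSchedule(config$schedule$start, config$schedule$duration)
        else defaultFrameSchedule()
        message("[input] reading volumes from configured paths")
        volumes <- list(
            water = readVolume(config$paths$water, "water-dynamic", sch),
            waterAtten = readVolume(config$paths$waterAtten, "attenuation"),
            fdg = readVolume(config$paths$fdg, "FDG-SUV"),
            fdgAtten = readVolume(config$paths$fdgAtten, "attenuation"))
    }
    need <- c("water", "waterAtten", "fdg", "fdgAtten")
    miss <- setdiff(need, names(volumes))
    if (length(miss))
        stop("[input] missing volumes: ", paste(miss, collapse = ", "))

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    }

    message("[voi] thresholding FDG volume at fraction ",
            config$thresholdFraction)
    fdgVOI <- stage("voi", thresholdVOI(volumes$fdg,
                                        config$thresholdFraction))

    message("[register] attenuation co-registration, window ",
            config$registrationWindowMm, " mm")
    reg <- stage("register",
                 registerAttenuation(volumes$fdgAtten, volumes$waterAtten,
                                     config$registrationWindowMm))
    message("[register] shift = (", paste(reg$shift, collapse = ", "),
            ") voxels, ncc = ", signif(reg$correlation, 4))
    tumourVOI <- stage("register", transferVOI(fdgVOI, reg$shift))

    message("[aorta] summed early frames, threshold fraction ",
            config$aortaFraction)
    aorta <- stage("aorta", aortaVOI(volumes$water, config$aortaBox,
                                     config$aortaFraction))

    message("[tac] extracting tumour (", voxelCount(tumourVOI),
            " voxels) and aorta (", voxelCount(aorta), " voxels) TACs")
    tumourTAC <- stage("tac", extractTAC(volumes$water, tumourVOI))
    aortaTAC <- stage("tac", extractTAC(volumes$water, aorta))
    inputFn <- if (identical(config$inputModel, "sampled"))
        inputFromTAC(aortaTAC)
    else
        stage("input", fitInputFunction(aortaTAC, config$fineStep))
    message("[input] arterial input model: ", class(inputFn))

    basis <- spectralBasis(nRates = config$nBasis, betaMax = config$betaMax,
                           fineStep = config$fineStep)
    grid <- seq(config$delayMin, config$delayMax, by = config$delayStep)
    message("[delay] grid search ", config$delayMin, "..",
            config$delayMax, " s, step ", config$delayStep, " s")
    del <- stage("delay", estimateDelay(tumourTAC, inputFn, grid, basis))
    message("[delay] delay = ", del$delay, " s (flatness ",
            signif(del$flatness, 3), ")")

    message("[spectral] ", config$nBasis, " rates up to ", config$betaMax,
            " /min, vascular cutoff ", config$vascularCutoff, " /min")
    spec <- stage("spectral",
                  spectralFit(tumourTAC, inputFn, basis, delay = del$delay,
                              vascularCutoff = config$vascularCutoff))
    message("[nonlinear] bounded one-tissue fit")
    nl <- stage("nonlinear",
                nonlinearFit(tumourTAC, inputFn,
                             init = oneTissueParams(
                                 max(perfusionTissue(spec), 0.1),
                                 0.5, 0.05, delay = del$delay),
                             fineStep = config$fineStep))

    report <- list(
        perfusion = perfusionSum(spec),
        perfusionTissue = perfusionTissue(spec),
        vascularWeight = vascularWeight(spec),
        vascularCutoff = config$vascularCutoff,
        K1 = nl$params@K1, k2 = nl$params@k2, V0 = nl$params@V0,
        delay_s = del$delay,
        delayLowConfidence = del$lowConfidence,
        basis = list(nRates = config$nBasis, betaMax = config$betaMax,
                     fineStep = config$fineStep),
        spectralResidual = residualNorm(spec),
        nonlinearResidual = nl$residualNorm,
        nonlinearConverged = nl$converged,
        tumourVoxels = voxelCount(tumourVOI),
        aortaVoxels = voxelCount(aorta),
        registrationShift = reg$shift,
        registrationNcc = reg$correlation)
    prov <- provenanceBlock(config)
    out <- list(tumourVOI = tumourVOI, aortaVOI = aorta, shift = reg$shift,
                tumourTAC = tumourTAC, aortaTAC = aortaTAC,
                delay = del, spectral = spec, nonlinear = nl,
                report = report, provenance = prov)
    if (!is.null(config$outputDir)) {
        dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(c(report, list(provenance = prov)),
                             file.path(config$outputDir,
                                       "perfusion_report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        writeTAC(tumourTAC, file.path(config$outputDir, "tumour_tac.csv"))
        writeTAC(aortaTAC, file.path(config$outputDir, "aorta_tac.csv"))
        message("[output] wrote report and TACs to ", config$outputDir)
    }
    out
}

cohortRequiredCols <- c("perfusion_change_pct", "suv_change_wk2_pct",
                        "fdg_response", "overall_recist", "duration_cycles",
                        "clinical_benefit", "trough_ng_ml")

#' Cohort statistics report
#'
#' Computes the descriptive and inferential statistics of a response
#' table (the packaged seven-patient table, a [simulateCohort()] output,
#' or a CSV with the same columns): perfusion-decrease and SUV-reduction
#' ranges, metabolic responder and RECIST stable-disease counts,
#' stable-disease duration range, the one-sided unequal-variance t-test
#' of week-2 perfusion change between clinical-benefit groups, Pearson
#' correlations (with Fisher-z 95 percent intervals) of perfusion change
#' and biomarker ratios against SUV change, and one-sided z-tests of the
#' day-15 drug trough against a 50 ng/mL clinical reference, per benefit
#' group.
#'
#' @param x data.frame or CSV path.
#' @param outPath optional JSON output path.
#' @param troughReference reference trough level (ng/mL, default 50).
#' @return named list of statistics.
#' @export
runCohortStats <- function(x = fixtureTable(), outPath = NULL,
                           troughReference = 50) {
    df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
          else as.data.frame(x)
    miss <- setdiff(cohortRequiredCols, names(df))
    if (length(miss))
        stop("cohort table is missing required columns: ",
             paste(miss, collapse = ", "))
    benefit <- df$clinical_benefit == "Yes"
    if (sum(benefit) < 2L || sum(!benefit) < 2L)
        stop("each clinical-benefit group needs at least two patients")
    perfDecrease <- -df$perfusion_change_pct
    suvDecrease <- -df$suv_change_wk2_pct
    welch <- welchTOneSided(df$perfusion_change_pct[benefit],
                            df$perfusion_change_pct[!benefit])
    sdSel <- df$overall_recist == "SD"
    corSafe <- function(a, b) tryCatch(pearsonWithCI(a, b),
                                       error = function(e) NULL)
    stats <- list(
        n = nrow(df),
        perfusionDecreaseRange = range(perfDecrease),
        suvReductionRange = range(suvDecrease),
        metabolicResponders = sum(df$fdg_response == "Yes"),
        stableDisease = sum(sdSel),
        stableDiseaseDurationRange =
            if (any(sdSel)) range(df$duration_cycles[sdSel]) else c(NA, NA),
        welchPerfusionBenefit = welch,
        pearsonPerfusionVsSuv =
            corSafe(df$perfusion_change_pct, df$suv_change_wk2_pct),
        pearsonVegfVsSuv =
            if ("vegf_d15_d1" %in% names(df))
                corSafe(df$vegf_d15_d1, df$suv_change_wk2_pct) else NULL,
        pearsonSvegfr2VsSuv =
            if ("svegfr2_d15_d1" %in% names(df))
                corSafe(df$svegfr2_d15_d1, df$suv_change_wk2_pct) else NULL,
        ztestTroughBenefit =
            ztestVsReference(df$trough_ng_ml[benefit], troughReference),
        ztestTroughNonBenefit =
            ztestVsReference(df$trough_ng_ml[!benefit], troughReference),
        troughReference = troughReference)
    if (!is.null(outPath)) {
        jsonlite::write_json(stats, outPath, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE, null = "null")
        message("[output] wrote cohort statistics to ", outPath)
    }
    stats
}

#' Simulate a phantom study to disk
#'
#' Runs [simulatePatient()] from a configuration and persists the four
#' volumes as NIfTI plus the generating truth as JSON, in a form
#' [runPerfusion()] accepts back via `config$paths`.
#'
#' @param config list with optional `phantom` overrides for
#'   [phantomSpec()] (scalar fields only), `seed`, and `outputDir`
#'   (required).
#' @return invisible named list of written file paths.
#' @export
simulateCommand <- function(config = list()) {
    config <- mergeConfig(config)
    if (is.null(config$outputDir))
        stop("[input] simulateCommand requires config$outputDir")
    ph <- config$phantom
    spec <- do.call(phantomSpec, if (is.null(ph)) list() else ph)
    message("[simulate] phantom ", paste(spec@dim, collapse = "x"),
            ", seed ", config$seed)
    sim <- simulatePatient(spec, seed = config$seed)
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
        water = file.path(config$outputDir, "water_dynamic.nii.gz"),
        waterAtten = file.path(config$outputDir, "water_atten.nii.gz"),
        fdg = file.path(config$outputDir, "fdg_suv.nii.gz"),
        fdgAtten = file.path(config$outputDir, "fdg_atten.nii.gz"),
        truth = file.path(config$outputDir, "truth.json"))
    writeVolume(sim$water, paths$water)
    writeVolume(sim$waterAtten, paths$waterAtten)
    writeVolume(sim$fdg, paths$fdg)
    writeVolume(sim$fdgAtten, paths$fdgAtten)
    truth <- list(K1 = sim$truth$params@K1, k2 = sim$truth$params@k2,
                  V0 = sim$truth$params@V0, delay = sim$truth$params@delay,
                  fdgShift = sim$truth$fdgShift, seed = config$seed,
                  schedule = list(start = frameStart(spec@schedule),
                                  duration = frameDuration(spec@schedule)),
                  provenance = provenanceBlock(config))
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    message("[simulate] wrote ", length(paths), " files to ",
            config$outputDir)
    invisible(paths)
}
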