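# End-to-end orchestration: phantom study simulation, the full
# segmentation pipeline (multi-atlas whole-heart segmentation -> anatomy
# mapping -> wall/blood-pool extraction -> SLIC -> features -> SVM
# prediction -> metrics), and seeded experiment suites over synthetic
# cohorts.

#' Pipeline configuration
#'
#' @param atlas_dir directory with atlas_\{i\}.nii.gz volumes and
#'   atlas_\{i\}_labels.nii.gz label maps.
#' @param roadmap,lge paths to the target anatomical and LGE volumes.
#' @param clicks path to a clicks CSV (columns slice, row, col) used to
#'   train the classifier; NULL if \code{model} is given.
#' @param scar_truth optional path to a ground-truth scar mask for metrics.
#' @param out_dir output directory.
#' @param seed global seed recorded in every output.
#' @param n_atlases cap on the number of atlases used.
#' @param fusion_method label-fusion method.
#' @param registration list: use_local / use_deformable flags and iteration
#'   caps.
#' @param slic list: S and m.
#' @param training a \code{\link{trainingSetSpec}}.
#' @param mrmr_k number of features selected by mRMR.
#' @param verbose print per-stage progress.
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(atlas_dir, roadmap, lge, clicks = NULL,
                           scar_truth = NULL, out_dir = tempfile("atriascar_"),
                           seed = 1L, n_atlases = Inf,
                           fusion_method = "MSP",
                           registration = list(use_local = FALSE,
                                               use_deformable = TRUE,
                                               maxit = c(150, 100, 60)),
                           slic = list(S = 4L, m = 4),
                           training = trainingSetSpec(), mrmr_k = 3,
                           verbose = TRUE) {
  structure(list(atlas_dir = atlas_dir, roadmap = roadmap, lge = lge,
                 clicks = clicks, scar_truth = scar_truth, out_dir = out_dir,
                 seed = as.integer(seed), n_atlases = n_atlases,
                 fusion_method = fusion_method, registration = registration,
                 slic = slic, training = training, mrmr_k = mrmr_k,
                 verbose = verbose),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' CLI-facing convenience: top-level keys match the arguments of
#' \code{\link{pipelineConfig}}.
#' @param path YAML file.
#' @return a "PipelineConfig".
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- do.call(trainingSetSpec, y$training %||% list())
  y$training <- tr
  do.call(pipelineConfig, y)
}

#' Simulate a phantom study to disk
#'
#' Writes a Roadmap-like volume with ground-truth labels, an LGE-like
#' volume with a true scar mask, a deformed atlas set and a clicks CSV —
#' everything \code{\link{runFullPipeline}} needs.
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @param out_dir output directory (created).
#' @param n_atlases number of atlases.
#' @param click_density fraction of scar super-pixels clicked.
#' @return the output directory, invisibly.
#' @export
simulateStudy <- function(cfg, out_dir, n_atlases = 5, click_density = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "atlases"), showWarnings = FALSE)
  heart <- makeHeartPhantom(cfg)
  lge <- makeLGEPhantom(heart$labels, cfg)
  writeVolume(heart$volume, file.path(out_dir, "roadmap.nii.gz"))
  writeLabelMap(heart$labels, file.path(out_dir, "labels.nii.gz"))
  writeVolume(lge$volume, file.path(out_dir, "lge.nii.gz"))
  writeVolume(asVolume(lge$scar), file.path(out_dir, "scar_truth.nii.gz"))
  atl <- makeAtlasSet(n_atlases, cfg)
  for (i in seq_along(atl)) {
    writeVolume(atl[[i]]$volume,
                file.path(out_dir, "atlases", sprintf("atlas_%d.nii.gz", i)))
    writeLabelMap(atl[[i]]$labels,
                  file.path(out_dir, "atlases",
                            sprintf("atlas_%d_labels.nii.gz", i)))
  }
  spmap <- oversegmentVolume(lge$volume, S = 4L, m = 2 * stats::sd(lge$volume@data))
  clicks <- makeClicks(lge$scar, spmap, density = click_density,
                       seed = cfg$seed)
  utils::write.csv(clicks, file.path(out_dir, "clicks.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

asVolume <- function(mask) {
  Volume3D(array(as.numeric(mask@data), dim(mask@data)),
           spacing = mask@spacing, affine = mask@affine)
}

#' Run the full segmentation pipeline
#'
#' Stages, in order: multi-atlas whole-heart segmentation of the Roadmap
#' volume (hierarchical registration + label fusion), mapping of the
#' anatomy onto the LGE grid, wall and blood-pool extraction with
#' intensity normalisation, SLIC oversegmentation, feature extraction,
#' SVM training (from clicks) and prediction, scar-mask assembly and
#' metrics. Every intermediate artifact is written to the output directory
#' together with a JSON manifest (seed, parameters, per-stage runtimes).
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return the output directory, invisibly; see manifest.json inside it.
#' @export
runFullPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  for (p in c(cfg$atlas_dir, cfg$roadmap, cfg$lge, cfg$clicks,
              cfg$scar_truth)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, fusion_method = cfg$fusion_method,
                   slic = cfg$slic, mrmr_k = cfg$mrmr_k,
                   package_version = as.character(utils::packageVersion("atriascar")),
                   stages = list())
  say <- function(...) if (cfg$verbose) message(...)
  timed <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- round(proc.time()[3] - t0, 2)
    say(sprintf("[%s] %.1fs", name, proc.time()[3] - t0))
    out
  }
  roadmap <- readVolume(cfg$roadmap)
  lge <- readVolume(cfg$lge)
  atlasFiles <- sort(list.files(cfg$atlas_dir, "^atlas_[0-9]+\\.nii",
                                full.names = TRUE))
  if (length(atlasFiles) == 0) stop("no atlases found in ", cfg$atlas_dir)
  atlasFiles <- utils::head(atlasFiles, cfg$n_atlases)

  warped <- timed("mawhs_registration", lapply(atlasFiles, function(f) {
    av <- readVolume(f)
    al <- readLabelMap(sub("\\.nii", "_labels.nii", f))
    reg <- registerGlobalAffine(roadmap, av,
                                maxit = cfg$registration$maxit %||% c(150, 100, 60))
    chain <- reg@chain
    if (isTRUE(cfg$registration$use_local)) {
      chain <- registerLocalAffine(roadmap, av, chain, al)@chain
    }
    if (isTRUE(cfg$registration$use_deformable)) {
      chain <- registerDeformable(roadmap, av, chain, maxIter = 15)@chain
    }
    list(volume = resampleToGrid(av, roadmap, "linear", chain),
         labels = resampleToGrid(al, roadmap, chain = chain))
  }))
  whs <- timed("label_fusion",
               fuseLabels(warped, roadmap,
                          fusionConfig(method = cfg$fusion_method)))
  writeLabelMap(whs, file.path(cfg$out_dir, "whs_labels.nii.gz"))

  mapped <- timed("map_to_lge", {
    if (sameGrid(roadmap, lge)) list(labels = whs) else
      list(labels = mapRoadmapToLGE(roadmap, lge, whs)$labels)
  })
  labOnLge <- mapped$labels
  writeLabelMap(labOnLge, file.path(cfg$out_dir, "labels_on_lge.nii.gz"))

  anat <- timed("wall_blood_pool", {
    endo <- BinaryMask(array(labOnLge@data == labOnLge@labelDict[["LA_PV"]],
                             dim(labOnLge@data)),
                       spacing = lge@spacing, affine = lge@affine)
    wall <- extractWall(endo, cfg$training$dilation_mm)
    bp <- extractBloodPool(endo, cfg$training$erosion_mm)
    norm <- normalizeIntensities(lge, bp)
    writeVolume(asVolume(wall), file.path(cfg$out_dir, "wall.nii.gz"))
    writeVolume(norm, file.path(cfg$out_dir, "lge_normalized.nii.gz"))
    list(endo = endo, wall = wall, norm = norm)
  })

  spmap <- timed("slic", oversegmentVolume(anat$norm, S = cfg$slic$S,
                                           m = cfg$slic$m))
  writeVolume(Volume3D(array(as.numeric(spmap@data), dim(spmap@data)),
                       spacing = lge@spacing, affine = lge@affine),
              file.path(cfg$out_dir, "superpixels.nii.gz"))

  tab <- timed("features", {
    clicks <- utils::read.csv(cfg$clicks)
    clicked <- clicksToSuperpixels(clicks, spmap)
    buildTrainingSet(spmap, clicked, anat$wall, anat$norm, cfg$training)
  })
  utils::write.csv(tab, file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)

  model <- timed("train", {
    sel <- mrmrSelect(tab, cfg$mrmr_k)
    trainSvm(tab, sel, seed = cfg$seed)
  })
  pred <- timed("predict", predictScar(model, tab))
  scar <- timed("assemble", assembleScarMask(spmap, pred, anat$wall))
  writeVolume(asVolume(scar), file.path(cfg$out_dir, "scar_mask.nii.gz"))

  metrics <- list(fep = fibrosisExtent(scar, anat$wall),
                  selected_features = model$selected,
                  C = model$C, gamma = model$gamma)
  if (!is.null(cfg$scar_truth)) {
    truth <- readVolume(cfg$scar_truth)
    truthMask <- BinaryMask(array(truth@data > 0.5, dim(truth@data)),
                            spacing = truth@spacing, affine = truth@affine)
    om <- overlapMetrics(truthMask, scar)
    metrics$dice <- om$dice
    metrics$jaccard <- om$jaccard
    metrics$precision <- om$precision
    metrics$npv <- om$npv
    metrics$fep_truth <- fibrosisExtent(truthMask, anat$wall)
  }
  manifest$metrics <- metrics
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Build one phantom case for the scar-classification pipeline
#'
#' Generates the heart and LGE phantoms, extracts wall and blood pool from
#' the ground-truth anatomy (emulating a perfect whole-heart segmentation),
#' normalises intensities, oversegments, simulates clicks and builds the
#' labeled feature table.
#'
#' @param cfg a \code{\link{phantomConfig}} (its seed field is overridden).
#' @param seed case seed.
#' @param click_density fraction of scar super-pixels clicked.
#' @param slic_S,slic_m SLIC parameters (on normalised intensities).
#' @param spec a \code{\link{trainingSetSpec}}.
#' @return list with the phantoms, masks, super-pixel map, clicks and the
#'   feature table.
#' @export
makePhantomCase <- function(cfg, seed, click_density = 1, slic_S = 4L,
                            slic_m = 4, spec = trainingSetSpec()) {
  cfg$seed <- as.integer(seed)
  heart <- makeHeartPhantom(cfg)
  lge <- makeLGEPhantom(heart$labels, cfg)
  endo <- BinaryMask(array(heart$labels@data == 1L, dim(heart$labels@data)),
                     spacing = cfg$spacing,
                     affine = affine(heart$labels))
  wall <- extractWall(endo, spec$dilation_mm)
  bp <- extractBloodPool(endo, spec$erosion_mm)
  norm <- normalizeIntensities(lge$volume, bp)
  spmap <- oversegmentVolume(norm, S = slic_S, m = slic_m)
  clicks <- makeClicks(lge$scar, spmap, density = click_density, seed = seed)
  clicked <- clicksToSuperpixels(clicks, spmap)
  tab <- buildTrainingSet(spmap, clicked, wall, norm, spec,
                          case = paste0("case", seed))
  list(labels = heart$labels, lge = lge$volume, scar = lge$scar,
       endo = endo, wall = wall, norm = norm, spmap = spmap,
       clicks = clicks, clicked = clicked, table = tab, seed = seed)
}

#' Leave-one-case-out scar-segmentation experiment on a phantom cohort
#'
#' Trains the mRMR + RBF-SVM classifier on all-but-one case, predicts the
#' held-out case, assembles its scar mask and scores it against the
#' generator's ground truth; also scores the conventional baselines on
#' every case. Returns per-case rows and pooled classifier metrics.
#'
#' @param cases list of \code{\link{makePhantomCase}} results.
#' @param mrmr_k features selected per fold.
#' @param grid SVM grid (see \code{\link{trainSvm}}).
#' @param baselines baseline specs: named list of lists(method, t/n).
#' @param seed seed for CV internals.
#' @return list(per_case data.frame, pooled classifier report,
#'   baseline_dice data.frame).
#' @export
scarLooExperiment <- function(cases, mrmr_k = 3,
                              grid = list(C = 2^seq(-5, 13, 6),
                                          gamma = 2^seq(-13, -1, 6)),
                              baselines = list(
                                threshold = list(method = "threshold", t = 2),
                                sd2 = list(method = "nsd", n = 2),
                                sd4 = list(method = "nsd", n = 4),
                                sd6 = list(method = "nsd", n = 6),
                                kmeans = list(method = "kmeans"),
                                fcm = list(method = "fcm")),
                              seed = 1L) {
  tables <- lapply(cases, `[[`, "table")
  names(tables) <- vapply(cases, function(cs) paste0("case", cs$seed), "")
  cv <- looCV(tables,
              train_fn = function(tab) {
                sel <- mrmrSelect(tab, mrmr_k)
                trainSvm(tab, sel, grid = grid, seed = seed)
              },
              predict_fn = predictScar)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    nm <- names(tables)[i]
    pred <- cv$predictions[[nm]]
    scar <- assembleScarMask(cs$spmap, pred, cs$wall)
    om <- overlapMetrics(cs$scar, scar)
    data.frame(case = nm, method = "pipeline", dice = om$dice,
               jaccard = om$jaccard, precision = om$precision,
               npv = om$npv,
               fep_pred = fibrosisExtent(scar, cs$wall),
               fep_truth = fibrosisExtent(cs$scar, cs$wall))
  })
  base <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    do.call(rbind, lapply(names(baselines), function(bn) {
      b <- baselines[[bn]]
      bm <- baselineSegment(cs$norm, cs$wall, method = b$method,
                            t = b$t %||% 2, n = b$n %||% 2, seed = seed)
      data.frame(case = paste0("case", cs$seed), method = bn,
                 dice = overlapMetrics(cs$scar, bm)$dice)
    }))
  })
  list(per_case = do.call(rbind, rows), pooled = cv$pooled,
       baseline_dice = do.call(rbind, base), cv = cv)
}

#' Seeded experiment suite over synthetic cohorts
#'
#' Reproduces the two experiment shapes of the study on phantoms: the
#' label-fusion method comparison (whole-heart Dice per method over seeded
#' atlas sets) and the scar-segmentation comparison of the classifier
#' pipeline against the conventional baselines. Per-run rows and summary
#' medians are written as CSV.
#'
#' @param out_dir output directory for CSV summaries.
#' @param n_seeds number of seeded replicates.
#' @param cfg a \code{\link{phantomConfig}}.
#' @param fusion_methods label-fusion methods to compare.
#' @param n_atlases atlases per fusion replicate.
#' @param n_cases cases per scar cohort.
#' @param base_seed first seed.
#' @return list of the two per-run data.frames and their summaries.
#' @export
runExperimentSuite <- function(out_dir, n_seeds = 3,
                               cfg = phantomConfig(),
                               fusion_methods = c("MV", "LWV", "PF", "MSP"),
                               n_atlases = 5, n_cases = 5,
                               base_seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fusionRows <- list()
  scarRows <- list()
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + 97L * (s - 1L)
    f <- fusionExperiment(cfg, seed, methods = fusion_methods,
                          n_atlases = n_atlases)
    fusionRows[[s]] <- f
    cases <- lapply(seq_len(n_cases), function(i)
      makePhantomCase(cfg, seed = seed + i))
    ex <- scarLooExperiment(cases, seed = seed)
    sr <- rbind(ex$per_case[c("case", "method", "dice")], ex$baseline_dice)
    sr$seed <- seed
    scarRows[[s]] <- sr
  }
  fusion <- do.call(rbind, fusionRows)
  scar <- do.call(rbind, scarRows)
  fusionSummary <- stats::aggregate(dice ~ method, fusion, stats::median)
  scarSummary <- stats::aggregate(dice ~ method, scar, stats::median)
  utils::write.csv(fusion, file.path(out_dir, "fusion_runs.csv"),
                   row.names = FALSE)
  utils::write.csv(scar, file.path(out_dir, "scar_runs.csv"),
                   row.names = FALSE)
  utils::write.csv(fusionSummary, file.path(out_dir, "fusion_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(scarSummary, file.path(out_dir, "scar_summary.csv"),
                   row.names = FALSE)
  list(fusion = fusion, scar = scar, fusion_summary = fusionSummary,
       scar_summary = scarSummary)
}

#' Label-fusion comparison on one seeded atlas set
#'
#' The target is a fresh phantom realisation; the atlases are randomly
#' deformed, independently noised replicates of the same anatomy (their
#' residual deformation emulates registration error). Each method fuses the
#' atlas labels and is scored by the whole-heart LA Dice against the
#' target's ground truth.
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @param seed replicate seed.
#' @param methods fusion methods.
#' @param n_atlases atlas count.
#' @return data.frame(seed, method, dice).
#' @export
fusionExperiment <- function(cfg, seed, methods = c("MV", "PF", "MSP"),
                             n_atlases = 5) {
  cfg$seed <- as.integer(seed)
  base <- makeHeartPhantom(cfg)
  atl <- makeAtlasSet(n_atlases, cfg)
  truthLA <- BinaryMask(array(base$labels@data == 1L, dim(base$labels@data)),
                        spacing = cfg$spacing, affine = affine(base$labels))
  do.call(rbind, lapply(methods, function(mth) {
    fused <- fuseLabels(atl, base$volume, fusionConfig(method = mth))
    fusedLA <- BinaryMask(array(fused@data == 1L, dim(fused@data)),
                          spacing = cfg$spacing, affine = affine(fused))
    data.frame(seed = seed, method = mth,
               dice = overlapMetrics(truthLA, fusedLA)$dice)
  }))
}
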