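# Runnable pipeline stages behind the command-line interface. Each run_*
# function is a thin orchestration of the analysis modules: read inputs,
# compute, write outputs plus a manifest (config, input hashes, package
# version) sufficient to reproduce the run.

#' Resolve a run configuration
#'
#' Merges three layers with precedence CLI overrides > YAML config file >
#' package defaults. Defaults: spacing 10 mm (the 1 cm entry grid), radius
#' 5 mm, margin 10 mm, base face `-z`, display scale 1, resampling step
#' `NULL` (half the shortest voxel edge), seed 1.
#'
#' @param config_file optional path to a YAML file of settings.
#' @param overrides named list of explicit settings (highest precedence).
#' @return named list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, overrides = list()) {
  cfg <- list(spacing = 10, radius = 5, margin = 10, base_face = "-z",
              scale = 1, step = NULL, seed = 1L, progress_every = 0L)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file)
    fromfile <- yaml::read_yaml(config_file)
    cfg[names(fromfile)] <- fromfile
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

write_manifest <- function(out_dir, cfg, inputs, extra = list()) {
  manifest <- c(list(
    package = "neuroplanr",
    version = as.character(utils::packageVersion("neuroplanr")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list()), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

read_pipeline_inputs <- function(fc_path, sc_path, parc_path, tract_path) {
  for (p in c(fc_path, sc_path, parc_path, tract_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  list(fc = read_connectivity(fc_path, "functional"),
       sc = read_connectivity(sc_path, "structural"),
       parc = read_parcellation(parc_path),
       tract = read_tractogram(tract_path))
}

#' Generate and write a phantom dataset
#'
#' Writes the parcellation (NIfTI), tractogram (TCK), FC/SC matrices (CSV),
#' a target list, and the generator's ground truth (JSON) into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param preset `"basic"` for [make_phantom()] defaults or `"hub"` for
#'   [make_planted_hub_scene()].
#' @param config a [run_config()].
#' @return named character vector of the written paths, invisibly.
#' @export
run_phantom <- function(out_dir, seed = 1L, preset = c("basic", "hub"),
                        config = run_config()) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- if (preset == "hub") make_planted_hub_scene(seed)
        else make_phantom(phantom_spec(seed = seed))
  paths <- c(parc = file.path(out_dir, "parcellation.nii.gz"),
             tract = file.path(out_dir, "tractogram.tck"),
             fc = file.path(out_dir, "fc.csv"),
             sc = file.path(out_dir, "sc.csv"),
             targets = file.path(out_dir, "targets.csv"),
             truth = file.path(out_dir, "ground_truth.json"))
  write_parcellation(ph$parcellation, paths[["parc"]])
  write_tck(ph$tractogram, paths[["tract"]])
  write_connectivity(ph$fc, paths[["fc"]])
  write_connectivity(ph$sc, paths[["sc"]])
  target <- if (preset == "hub") ph$scene$target else c(0, 0, 0)
  utils::write.csv(data.frame(id = "t1", x = target[1L], y = target[2L],
                              z = target[3L]),
                   paths[["targets"]], row.names = FALSE, quote = FALSE)
  truth <- ph$ground_truth
  truth$roi_volumes <- as.list(truth$roi_volumes)
  truth$fcgm <- as.list(truth$fcgm)
  truth$scgm <- as.list(truth$scgm)
  truth$centroids <- apply(truth$centroids, 1L, as.list)
  if (preset == "hub")
    truth$scene <- ph$scene[c("target", "entry_hub", "entry_safe",
                              "hub_label", "safe_label", "radius")]
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  write_manifest(out_dir, c(unclass(config), list(seed = seed,
                                                  preset = preset)),
                 list())
  invisible(paths)
}

#' Compute and write the eloquence score tables
#'
#' @param fc_path,sc_path connectivity CSV/TSV paths.
#' @param parc_path parcellation NIfTI path.
#' @param tract_path tractogram TCK/TRK path.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return named character vector of the written paths, invisibly.
#' @export
run_scores <- function(fc_path, sc_path, parc_path, tract_path, out_dir,
                       config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_pipeline_inputs(fc_path, sc_path, parc_path, tract_path)
  gm <- compute_gm_scores(inp$fc, inp$sc, inp$parc)
  fib <- compute_fiber_scores(inp$tract, inp$parc, gm, step = config$step)
  paths <- c(gm = file.path(out_dir, "gm_scores.csv"),
             fibers = file.path(out_dir, "fiber_scores.csv"))
  write_scores(gm, paths[["gm"]])
  write_scores(fib, paths[["fibers"]])
  write_manifest(out_dir, unclass(config),
                 list(fc_path, sc_path, parc_path, tract_path))
  invisible(paths)
}

#' Evaluate a single trajectory tube and write its damage report
#'
#' Writes `tube_rois.csv` (one row per intersected grey-matter region with
#' its voxel count, volume, scores and contributions), `tube_summary.csv`
#' (the four raw damage components plus fibre count).
#'
#' @inheritParams run_scores
#' @param entry,target world-mm trajectory endpoints.
#' @return named character vector of the written paths, invisibly.
#' @export
run_tube <- function(fc_path, sc_path, parc_path, tract_path, entry, target,
                     out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_pipeline_inputs(fc_path, sc_path, parc_path, tract_path)
  gm <- compute_gm_scores(inp$fc, inp$sc, inp$parc)
  fib <- compute_fiber_scores(inp$tract, inp$parc, gm, step = config$step)
  tube <- trajectory_tube(entry, target, config$radius)
  inv <- extract_tissue(tube, inp$parc, inp$tract, step = config$step)
  dmg <- raw_damage(inv, gm, fib)
  labs <- as.integer(names(inv$gm_voxels))
  pos <- match(labs, gm$label)
  rois <- data.frame(label = labs,
                     voxels = as.integer(inv$gm_voxels),
                     volume_mm3 = as.numeric(inv$gm_volume),
                     fcgm = gm$fcgm[pos], scgm = gm$scgm[pos],
                     fcgm_contrib = as.numeric(inv$gm_volume) * gm$fcgm[pos],
                     scgm_contrib = as.numeric(inv$gm_volume) * gm$scgm[pos])
  paths <- c(rois = file.path(out_dir, "tube_rois.csv"),
             summary = file.path(out_dir, "tube_summary.csv"))
  utils::write.csv(rois, paths[["rois"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(t(dmg), n_fibers = length(inv$fiber_indices)),
                   paths[["summary"]], row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, c(unclass(config),
                            list(entry = entry, target = target)),
                 list(fc_path, sc_path, parc_path, tract_path))
  invisible(paths)
}

#' Run the exhaustive entry-point search and write the risk map
#'
#' @inheritParams run_scores
#' @param target world-mm target point.
#' @return named character vector of the written paths, invisibly.
#' @export
run_search <- function(fc_path, sc_path, parc_path, tract_path, target,
                       out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_pipeline_inputs(fc_path, sc_path, parc_path, tract_path)
  gm <- compute_gm_scores(inp$fc, inp$sc, inp$parc)
  fib <- compute_fiber_scores(inp$tract, inp$parc, gm, step = config$step)
  box <- search_box(inp$parc, margin = config$margin,
                    spacing = config$spacing, base_face = config$base_face)
  rm_ <- exhaustive_search(target, box, inp$parc, inp$tract, gm, fib,
                           radius = config$radius, step = config$step,
                           progress_every = config$progress_every)
  prefix <- file.path(out_dir, "risk_map")
  paths <- write_risk_map(rm_, inp$parc, prefix, scale = config$scale)
  write_manifest(out_dir, c(unclass(config), list(target = target)),
                 list(fc_path, sc_path, parc_path, tract_path))
  invisible(c(paths, manifest = file.path(out_dir, "manifest.json")))
}

#' Compare two trajectories and write the evaluation row
#'
#' @inheritParams run_scores
#' @param entry_a,entry_b entry points of the two trajectories.
#' @param target common target point.
#' @param with_search also run the exhaustive search so damages are reported
#'   as T_scores on the search's normalisation scale.
#' @return path of the written CSV, invisibly.
#' @export
run_compare <- function(fc_path, sc_path, parc_path, tract_path,
                        entry_a, entry_b, target, out_dir,
                        config = run_config(), with_search = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_pipeline_inputs(fc_path, sc_path, parc_path, tract_path)
  gm <- compute_gm_scores(inp$fc, inp$sc, inp$parc)
  fib <- compute_fiber_scores(inp$tract, inp$parc, gm, step = config$step)
  cache <- scene_cache(inp$parc, inp$tract, step = config$step)
  rm_ <- NULL
  if (isTRUE(with_search)) {
    box <- search_box(inp$parc, margin = config$margin,
                      spacing = config$spacing,
                      base_face = config$base_face)
    rm_ <- exhaustive_search(target, box, inp$parc, inp$tract, gm, fib,
                             radius = config$radius, step = config$step,
                             cache = cache)
  }
  cmp <- compare_trajectories(entry_a, entry_b, target, inp$parc,
                              inp$tract, gm, fib, radius = config$radius,
                              risk_map = rm_, cache = cache)
  path <- file.path(out_dir, "comparison.csv")
  utils::write.csv(as.data.frame(cmp), path, row.names = FALSE,
                   quote = FALSE)
  write_manifest(out_dir, c(unclass(config),
                            list(entry_a = entry_a, entry_b = entry_b,
                                 target = target)),
                 list(fc_path, sc_path, parc_path, tract_path))
  invisible(path)
}
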