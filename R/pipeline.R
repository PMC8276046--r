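#' Pipeline configuration
#'
#' Collects every tunable of the rhizotron pipeline in one serializable
#' object; [jsonlite::write_json()]/[read_pipeline_config()] round-trip it.
#'
#' @param mm_per_px calibration (default 300-dpi scan).
#' @param polarity segmentation polarity (`"auto"`, `"bright"`, `"dark"`).
#' @param min_object_px small-object removal threshold (px).
#' @param lookahead ascending-path branch-probe depth (px).
#' @param peak peak parameters, see [peak_params()].
#' @param apical_k tip positions averaged for the apical diameter.
#' @param pixel_count use raw pixel counts for lengths.
#' @param min_component_px smallest skeleton component traced.
#' @param min_lateral_px smallest residual component counted as a lateral.
#' @param overlap_px nominal stitching overlap when two halves are given.
#' @param seed seed for the robust stitching estimator.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mm_per_px = 25.4 / 300, polarity = "auto",
                            min_object_px = 20L, lookahead = 15L,
                            peak = peak_params(), apical_k = 20L,
                            pixel_count = FALSE, min_component_px = 30L,
                            min_lateral_px = 10, overlap_px = 100L,
                            seed = 42L) {
  stopifnot(mm_per_px > 0, lookahead >= 1L, min_object_px >= 0L)
  structure(list(mm_per_px = mm_per_px, polarity = polarity,
                 min_object_px = as.integer(min_object_px),
                 lookahead = as.integer(lookahead), peak = peak,
                 apical_k = as.integer(apical_k), pixel_count = pixel_count,
                 min_component_px = as.integer(min_component_px),
                 min_lateral_px = min_lateral_px,
                 overlap_px = as.integer(overlap_px),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file written from a [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  known <- names(cfg)
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("malformed config: unknown field(s) ", paste(bad, collapse = ", "))
  for (n in intersect(names(x), known)) {
    if (n == "peak") cfg$peak <- do.call(peak_params, as.list(x$peak))
    else cfg[[n]] <- x[[n]]
  }
  pipeline_config(mm_per_px = cfg$mm_per_px, polarity = cfg$polarity,
                  min_object_px = cfg$min_object_px,
                  lookahead = cfg$lookahead, peak = cfg$peak,
                  apical_k = cfg$apical_k, pixel_count = cfg$pixel_count,
                  min_component_px = cfg$min_component_px,
                  min_lateral_px = cfg$min_lateral_px,
                  overlap_px = cfg$overlap_px, seed = cfg$seed)
}

#' Run the full rhizotron image pipeline
#'
#' Executes the processing chain on one image (or a two-half scan pair):
#' stitch (if two inputs) -> segment -> skeletonize and classify points ->
#' trace the ascending path per component -> reconstruct each adventitious
#' root -> extract traits. Optionally writes `traits.csv`, per-stage
#' rasters, a QC overlay (path in white, laterals in mid-gray) and a JSON
#' run log to an output directory.
#'
#' @param inputs a `root_image`/matrix, a list of two halves
#'   (`list(top=, bottom=)`), or one/two file paths.
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` writes nothing.
#' @param timestamp acquisition label recorded with the traits.
#' @param keep_intermediates write per-stage rasters (default TRUE).
#' @return List with `traits` (data.frame, one row per adventitious root),
#'   `mask`, `skeleton_graph`, `paths`, `profiles`, `reconstructions`, and
#'   `alignment` (when stitched).
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL,
                         timestamp = NA, keep_intermediates = TRUE) {
  if (is.character(inputs))
    inputs <- lapply(inputs, read_root_image, mm_per_px = config$mm_per_px)
  if (inherits(inputs, "root_image") || is.matrix(inputs))
    inputs <- list(inputs)
  alignment <- NULL
  if (length(inputs) == 2L) {
    pair <- list(top = inputs[[1]], bottom = inputs[[2]],
                 nominal_overlap_px = config$overlap_px)
    alignment <- estimate_alignment(pair, seed = config$seed)
    img <- merge_halves(pair, alignment, mm_per_px = config$mm_per_px)
  } else {
    img <- inputs[[1]]
    if (!inherits(img, "root_image"))
      img <- root_image(luminance(img), mm_per_px = config$mm_per_px)
  }
  mask <- binarize_clean(img, min_object_px = config$min_object_px,
                         polarity = config$polarity,
                         mm_per_px = config$mm_per_px)
  skel <- skeletonize(mask)
  graph <- classify_points(skel)
  paths <- trace_all_components(graph, lookahead = config$lookahead,
                                min_component_px = config$min_component_px)
  traits <- NULL
  profiles <- list()
  recons <- list()
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    prof <- side_radii(mask, path)
    prof <- detect_classify_peaks(prof, config$peak)
    prof <- suppress_peaks(prof, config$peak)
    rec <- reconstruct_root(mask, path, prof)
    mt <- main_traits(path, rec$diameter, mask, profile = prof,
                      mm_per_px = config$mm_per_px,
                      apical_k = config$apical_k,
                      pixel_count = config$pixel_count)
    lt <- lateral_traits(graph, path, prof, mm_per_px = config$mm_per_px,
                         min_lateral_px = config$min_lateral_px)
    traits <- rbind(traits,
                    cbind(data.frame(root = i, timestamp = timestamp,
                                     arn = length(paths)),
                          mt,
                          data.frame(lrn = lt$lrn, llrl_mm = lt$llrl_mm,
                                     tnn = lt$tnn, pnn = lt$pnn)))
    profiles[[i]] <- prof
    recons[[i]] <- rec
  }
  res <- list(traits = traits, image = img, mask = mask,
              skeleton_graph = graph, paths = paths, profiles = profiles,
              reconstructions = recons, alignment = alignment)
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir,
                                                keep_intermediates)
  res
}

write_pipeline_outputs <- function(res, config, out_dir, keep_intermediates) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
  if (keep_intermediates) {
    write_root_image(res$image, file.path(out_dir, "merged.png"))
    write_root_image(as_grid(res$mask), file.path(out_dir, "mask.png"))
    write_root_image(res$skeleton_graph$raster,
                     file.path(out_dir, "skeleton.png"))
    for (i in seq_along(res$reconstructions))
      write_root_image(as_grid(res$reconstructions[[i]]$mask),
                       file.path(out_dir, sprintf("adventitious_%d.png", i)))
    # QC overlay: skeleton mid-gray, traced path(s) white, on the mask
    ov <- as_grid(res$mask) * 80
    ov[res$skeleton_graph$raster] <- 170
    for (p in res$paths) ov[cbind(p$row, p$col)] <- 255
    write_root_image(ov, file.path(out_dir, "overlay.png"))
  }
  log <- list(package_version = as.character(utils::packageVersion("rootascent")),
              r_version = R.version.string,
              config = unclass(config),
              n_roots = if (is.null(res$traits)) 0L else nrow(res$traits),
              stitched = !is.null(res$alignment))
  if (!is.null(res$alignment))
    log$alignment <- list(homography = res$alignment$homography,
                          n_inliers = nrow(res$alignment$inliers),
                          mean_reproj_error_px =
                            res$alignment$mean_reproj_error_px)
  jsonlite::write_json(log, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
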