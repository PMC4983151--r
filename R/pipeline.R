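#' Pipeline configuration
#'
#' Collects the input paths and analysis parameters of a full run. Flat
#' key-value config files (`key = value`, `#` comments) are accepted via
#' [read_pipeline_config()].
#'
#' @param surface_left,surface_right,tractogram,mask paths to the inputs.
#' @param labels_left,labels_right per-hemisphere plain-text label files.
#' @param mapping path to a 17-to-7 mapping CSV (`NULL` for the default).
#' @param out_dir output directory.
#' @param k number of CC segments.
#' @param extents resection extents (default `1/k .. k/k`).
#' @param rule involvement rule, `"median"` or `"any"`.
#' @param area_weighted area-weighted hemisphere coverage flag.
#' @param max_distance_mm optional endpoint assignment distance cap.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(surface_left, surface_right, tractogram, mask,
                            labels_left, labels_right, mapping = NULL,
                            out_dir = ".", k = 5L, extents = NULL,
                            rule = "median", area_weighted = FALSE,
                            max_distance_mm = NULL, seed = 1L) {
  cfg <- list(surface_left = surface_left, surface_right = surface_right,
              tractogram = tractogram, mask = mask,
              labels_left = labels_left, labels_right = labels_right,
              mapping = mapping, out_dir = out_dir, k = as.integer(k),
              extents = extents, rule = rule,
              area_weighted = isTRUE(area_weighted),
              max_distance_mm = max_distance_mm, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key = value pipeline config file
#' @param path config file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  get_ <- function(key, default = NULL) if (key %in% names(vals)) vals[[key]] else default
  num_ <- function(key, default = NULL) {
    v <- get_(key); if (is.null(v)) default else as.numeric(v)
  }
  extents <- get_("extents")
  if (!is.null(extents)) extents <- as.numeric(strsplit(extents, "[,;]")[[1L]])
  pipeline_config(
    surface_left = get_("surface_left"), surface_right = get_("surface_right"),
    tractogram = get_("tractogram"), mask = get_("mask"),
    labels_left = get_("labels_left"), labels_right = get_("labels_right"),
    mapping = get_("mapping"), out_dir = get_("out_dir", "."),
    k = num_("k", 5), extents = extents, rule = get_("rule", "median"),
    area_weighted = identical(get_("area_weighted", "false"), "true"),
    max_distance_mm = num_("max_distance_mm"), seed = num_("seed", 1))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full trans-callosal analysis end-to-end
#'
#' Reads the inputs, assigns endpoints, builds triangle count fields,
#' computes hemisphere coverage, 17-network involvement, the 17- and
#' 7-network vulnerability profiles, and writes every result plus a run
#' manifest to `out_dir`. Identical config and inputs produce identical
#' outputs: the analysis itself is deterministic.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all in-memory results.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_log("load", "reading surfaces, tractogram, mask, labels")
  surfaces <- list(left = read_surface(config$surface_left, "left"),
                   right = read_surface(config$surface_right, "right"))
  tract <- read_tractogram(config$tractogram)
  mask <- read_mask(config$mask)
  labels <- read_labels(config$labels_left, config$labels_right)
  mapping <- read_network_mapping(config$mapping)
  stage_log("load", "%d streamlines read, %d + %d triangles, %d mask voxels",
            length(tract), nrow(surfaces$left$triangles),
            nrow(surfaces$right$triangles), nrow(mask$ijk))

  stage_log("map", "assigning endpoints to nearest vertices")
  assignment <- assign_endpoints(tract, surfaces, config$max_distance_mm)
  stage_log("map", "%d of %d endpoints assigned",
            sum(assignment$endpoints$assigned), nrow(assignment$endpoints))

  stage_log("segment", "subdividing CC into %d segments along the principal axis", config$k)
  segmentation <- segment_cc(mask, config$k)
  segments <- streamline_segments(tract, segmentation, mask)
  stage_log("segment", "%d callosal streamlines, %d non-callosal excluded",
            sum(segments$callosal), sum(!segments$callosal))

  # Fig. 1 / Fig. 2 analogues are computed from callosal streamlines so the
  # full-resection profile column reproduces them exactly
  callosal_assign <- restrict_assignment(assignment, which(segments$callosal))
  fields <- list(left = triangle_counts(callosal_assign, surfaces$left),
                 right = triangle_counts(callosal_assign, surfaces$right))
  coverage <- c(left = hemisphere_coverage(fields$left, surfaces$left,
                                           config$area_weighted, config$rule),
                right = hemisphere_coverage(fields$right, surfaces$right,
                                            config$area_weighted, config$rule))
  stage_log("coverage", "left %.4f, right %.4f", coverage["left"], coverage["right"])

  involvement <- network_involvement(fields, labels, rule = config$rule)
  stage_log("involvement", "%d networks, median involvement %.4f",
            length(involvement), stats::median(involvement, na.rm = TRUE))

  profile17 <- callosotomy_profile(assignment, segments, labels, surfaces,
                                   config$extents, rule = config$rule)
  profile7 <- downsample_17_to_7(profile17, mapping)
  stage_log("profile", "vulnerability profiles built (%d and %d networks x %d extents)",
            nrow(profile17), nrow(profile7), ncol(profile17))

  ## outputs ----------------------------------------------------------------
  od <- config$out_dir
  utils::write.csv(assignment$endpoints, file.path(od, "endpoint_assignment.csv"),
                   row.names = FALSE, quote = FALSE)
  write_triangle_field(fields$left, file.path(od, "triangle_field_left.csv"))
  write_triangle_field(fields$right, file.path(od, "triangle_field_right.csv"))
  utils::write.csv(data.frame(hemisphere = names(coverage),
                              coverage = sprintf("%.6f", coverage)),
                   file.path(od, "coverage.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(network = names(involvement),
                              involvement = ifelse(is.na(involvement), "NA",
                                                   sprintf("%.6f", involvement))),
                   file.path(od, "involvement17.csv"), row.names = FALSE, quote = FALSE)
  write_profile(profile17, file.path(od, "profile17.csv"))
  write_profile(profile7, file.path(od, "profile7.csv"))
  write_streamline_segments(segments, file.path(od, "streamline_segments.csv"))
  manifest <- list(package = "transcallosal",
                   version = as.character(utils::packageVersion("transcallosal")),
                   r_version = R.version.string,
                   seed = config$seed,
                   parameters = config[c("k", "rule", "area_weighted", "max_distance_mm")],
                   extents = attr(profile17, "extents"),
                   inputs = config[c("surface_left", "surface_right", "tractogram",
                                     "mask", "labels_left", "labels_right")],
                   counts = list(streamlines = length(tract),
                                 endpoints_assigned = sum(assignment$endpoints$assigned),
                                 non_callosal_excluded = sum(!segments$callosal)))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(surfaces = surfaces, tract = tract, mask = mask, labels = labels,
                 assignment = assignment, segmentation = segmentation,
                 segments = segments, fields = fields, coverage = coverage,
                 involvement = involvement, profile17 = profile17,
                 profile7 = profile7))
}

#' Scan-rescan style reproducibility between two runs
#'
#' Both bundles must share the surfaces (hence triangle counts are paired
#' element-wise); per-triangle count vectors of both hemispheres are
#' concatenated and compared by Spearman correlation.
#'
#' @param fields_a,fields_b lists of left/right [triangle_counts()] fields
#'   from the two sessions.
#' @param json_out optional path to write the result as JSON.
#' @return A [spearman_reproducibility()] result.
#' @export
run_reproducibility <- function(fields_a, fields_b, json_out = NULL) {
  a <- c(fields_a$left$n, fields_a$right$n)
  b <- c(fields_b$left$n, fields_b$right$n)
  if (length(a) != length(b))
    stop("sessions have mismatched triangle counts; surfaces must be shared")
  res <- spearman_reproducibility(a, b)
  if (!is.null(json_out))
    jsonlite::write_json(unclass(res), json_out, auto_unbox = TRUE, digits = NA)
  res
}
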