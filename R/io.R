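# Formats and the pipeline driver. Sections travel as multi-page TIFF
# (one page per channel) with a JSON sidecar carrying pixel size, section
# metadata and (for synthetic data) the ground truth; point annotations as
# Cell Counter-style XML or CSV; atlases as GeoJSON-style polygon files.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a section image as multi-page TIFF plus JSON sidecar
#'
#' Page 1 is the neuronal channel, page 2 the nuclear channel (16-bit).
#' The sidecar records `pixel_size_um`, section metadata, and the ground
#' truth when supplied. The TIFF itself carries no resolution tags; the
#' sidecar is the authoritative pixel-size record for files written here.
#'
#' @param image a `section_image`.
#' @param path output `.tif` path (sidecar written next to it).
#' @param truth optional `ground_truth` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_section <- function(image, path, truth = NULL) {
  tiff::writeTIFF(list(image$neuronal, image$nuclear), path,
                  bits.per.sample = 16L)
  side <- list(pixel_size_um = image$pixel_size_um,
               section_id = image$section_id,
               condition = image$condition,
               distance_mm = image$distance_mm,
               channels = c("neuronal", "nuclear"))
  if (!is.null(truth)) {
    side$truth <- list(neurons = truth$neurons, artifacts = truth$artifacts,
                       seed = truth$seed)
  }
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

# micron-per-pixel from TIFF resolution attributes, if present
.pixel_size_from_tags <- function(page) {
  xres <- attr(page, "x.resolution")
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit <- attr(page, "resolution.unit")
  per_um <- switch(if (is.null(unit)) "inch" else unit,
                   inch = xres / 25400, cm = xres / 10000, NULL)
  if (is.null(per_um)) return(NULL)
  1 / per_um
}

#' Read a section image from TIFF
#'
#' Accepts (a) a multi-page TIFF whose first two pages are the neuronal
#' and nuclear channels, or (b) a single-page RGB TIFF mapped red ->
#' neuronal, blue -> nuclear (the green channel is ignored with a
#' warning). Pixel size is taken from, in order of precedence: the
#' `pixel_size_um` argument, the TIFF resolution tags, the JSON sidecar;
#' if none is available an error demands an explicit pixel size.
#'
#' @param path `.tif` path.
#' @param pixel_size_um optional explicit override (µm/px).
#' @return A `section_image` (with `truth` attached as attribute
#'   `"truth"` when the sidecar embeds it).
#' @export
read_section <- function(path, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  side <- NULL
  sp <- .sidecar_path(path)
  if (file.exists(sp)) side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (length(pages) >= 2) {
    neuronal <- pages[[1]]; nuclear <- pages[[2]]
    if (length(dim(neuronal)) == 3) neuronal <- neuronal[, , 1]
    if (length(dim(nuclear)) == 3) nuclear <- nuclear[, , 1]
  } else {
    a <- pages[[1]]
    if (length(dim(a)) == 3 && dim(a)[3] >= 3) {
      warning("RGB input: red -> neuronal, blue -> nuclear; green channel ignored")
      neuronal <- a[, , 1]; nuclear <- a[, , 3]
    } else {
      stop("single-page grayscale TIFF: need 2 channel pages or an RGB image")
    }
  }
  s <- pixel_size_um %||% .pixel_size_from_tags(pages[[1]]) %||%
    side$pixel_size_um
  if (is.null(s)) {
    stop("no pixel size available: TIFF has no resolution tags and no ",
         "sidecar; pass `pixel_size_um`")
  }
  img <- structure(list(neuronal = neuronal, nuclear = nuclear,
                        pixel_size_um = s,
                        section_id = side$section_id %||%
                          tools::file_path_sans_ext(basename(path)),
                        condition = side$condition,
                        distance_mm = side$distance_mm, gain = NA_real_),
                   class = "section_image")
  if (!is.null(side$truth)) {
    attr(img, "truth") <- structure(
      list(neurons = as.data.frame(side$truth$neurons),
           artifacts = as.data.frame(side$truth$artifacts),
           section_id = img$section_id, condition = img$condition,
           distance_mm = img$distance_mm, seed = side$truth$seed),
      class = "ground_truth")
  }
  img
}

#' Read a Cell Counter-style XML annotation file
#'
#' Parses the marker dialect exported by the Fiji Cell Counter plugin
#' (`Marker_Data / Marker_Type / Marker / MarkerX, MarkerY`, pixel
#' units) and converts to µm.
#'
#' @param path XML path.
#' @param pixel_size_um microns per pixel used to convert marker
#'   coordinates.
#' @param section_id defaults to the image filename recorded in the file
#'   (or the XML filename).
#' @return A `detection_set` with an extra `marker_type` column.
#' @export
read_cellcounter_xml <- function(path, pixel_size_um, section_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed Cell Counter XML '", path, "': ", conditionMessage(e))
  })
  if (is.null(section_id)) {
    fn <- xml2::xml_find_first(doc, ".//Image_Filename")
    section_id <- if (!is.na(fn)) xml2::xml_text(fn) else
      tools::file_path_sans_ext(basename(path))
  }
  types <- xml2::xml_find_all(doc, ".//Marker_Type")
  rows <- lapply(types, function(tp) {
    type <- xml2::xml_text(xml2::xml_find_first(tp, "./Type"))
    mk <- xml2::xml_find_all(tp, "./Marker")
    if (!length(mk)) return(NULL)
    data.frame(
      x_px = as.numeric(xml2::xml_text(xml2::xml_find_all(mk, "./MarkerX"))),
      y_px = as.numeric(xml2::xml_text(xml2::xml_find_all(mk, "./MarkerY"))),
      marker_type = type, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) rows <- data.frame(x_px = numeric(0), y_px = numeric(0),
                                        marker_type = character(0))
  ds <- detection_set(rows$x_px * pixel_size_um, rows$y_px * pixel_size_um,
                      source_id = tools::file_path_sans_ext(basename(path)),
                      section_id = section_id)
  ds$marker_type <- rows$marker_type
  ds
}

#' Write a detection set as Cell Counter-style XML
#'
#' Coordinates are converted from µm back to pixel units.
#'
#' @param ds a `detection_set`.
#' @param path output XML path.
#' @param pixel_size_um microns per pixel.
#' @param marker_type marker type index to record.
#' @return `path`, invisibly.
#' @export
write_cellcounter_xml <- function(ds, path, pixel_size_um, marker_type = 1L) {
  doc <- xml2::xml_new_root("CellCounter_Marker_File")
  ip <- xml2::xml_add_child(doc, "Image_Properties")
  xml2::xml_add_child(ip, "Image_Filename", attr(ds, "section_id"))
  md <- xml2::xml_add_child(doc, "Marker_Data")
  mt <- xml2::xml_add_child(md, "Marker_Type")
  xml2::xml_add_child(mt, "Type", as.character(marker_type))
  for (i in seq_len(nrow(ds))) {
    mk <- xml2::xml_add_child(mt, "Marker")
    xml2::xml_add_child(mk, "MarkerX",
                        format(ds$x[i] / pixel_size_um, digits = 15))
    xml2::xml_add_child(mk, "MarkerY",
                        format(ds$y[i] / pixel_size_um, digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write detections as CSV (µm, 3 decimals)
#'
#' @param ds a `detection_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(ds, path) {
  out <- data.frame(x_um = round(ds$x, 3), y_um = round(ds$y, 3),
                    area_um2 = round(ds$area_um2, 3),
                    source_id = attr(ds, "source_id"),
                    section_id = attr(ds, "section_id"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read detections from CSV written by [write_detections_csv()]
#'
#' @param path CSV path.
#' @return A `detection_set`.
#' @export
read_detections_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  detection_set(d$x_um, d$y_um, d$area_um2,
                source_id = d$source_id[1] %||% "unknown",
                section_id = d$section_id[1] %||% "S1")
}

#' Pipeline configuration
#'
#' Bundles every knob of the synthetic end-to-end run: atlas geometry,
#' simulation parameters, cohort design, detection route and parameters,
#' matching radius, and output location. The master `seed` expands into
#' deterministic per-section child seeds.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed.
#' @param frame_um,n_laminae atlas geometry.
#' @param sim a `simulation_config`.
#' @param design cohort design data.frame (`section_id`, `individual`,
#'   `condition`, `distance_mm`); default: 4 control sections + 2
#'   sections per distance 0.6/0.8/1.0/1.2 mm.
#' @param detect_method `"probmap"` (pixel-classifier route) or
#'   `"threshold"` (macro route).
#' @param miscalibration probability-map miscalibration sd.
#' @param radius_um consensus matching radius.
#' @param write_images write per-section TIFF + sidecar files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, frame_um = c(2000, 1500),
                            n_laminae = 10L, sim = simulation_config(),
                            design = NULL,
                            detect_method = c("probmap", "threshold"),
                            miscalibration = 0.1, radius_um = 10,
                            write_images = FALSE) {
  detect_method <- match.arg(detect_method)
  if (is.null(design)) design <- default_cohort_design()
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 frame_um = frame_um, n_laminae = n_laminae, sim = sim,
                 design = design, detect_method = detect_method,
                 miscalibration = miscalibration, radius_um = radius_um,
                 write_images = write_images),
            class = "pipeline_config")
}

#' Default synthetic cohort design
#'
#' Mirrors the study layout at desk scale: a few uninjured control
#' sections plus injured sections at 0.6, 0.8, 1.0 and 1.2 mm caudal to
#' the epicenter, one condition per individual.
#'
#' @param n_control number of control sections.
#' @param distances_mm injured section distances.
#' @param n_per_distance sections per distance per condition.
#' @param conditions injured condition labels.
#' @return data.frame with `section_id`, `individual`, `condition`,
#'   `distance_mm`.
#' @export
default_cohort_design <- function(n_control = 4,
                                  distances_mm = c(0.6, 0.8, 1.0, 1.2),
                                  n_per_distance = 2,
                                  conditions = "injury_vehicle") {
  rows <- list(data.frame(
    section_id = sprintf("ctrl_%02d", seq_len(n_control)),
    individual = sprintf("C%d", rep(1:2, length.out = n_control)),
    condition = "control", distance_mm = NA_real_))
  for (cond in conditions) {
    for (d in distances_mm) {
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = sprintf("%s_%0.1fmm_%02d", cond, d,
                             seq_len(n_per_distance)),
        individual = sprintf("%s_I%d", cond, seq_len(n_per_distance)),
        condition = cond, distance_mm = d)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort of sections
#'
#' One call of [simulate_section()] per design row, with per-section
#' seeds derived deterministically from `seed`.
#'
#' @param atlas a `toy_atlas`.
#' @param config a `simulation_config`.
#' @param design a cohort design data.frame (see
#'   [default_cohort_design()]).
#' @param seed master seed (defaults to `config$seed`).
#' @return Named list (by section id) of `list(image, truth)`.
#' @export
simulate_cohort <- function(atlas, config, design = default_cohort_design(),
                            seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  out <- lapply(seq_len(nrow(design)), function(i) {
    simulate_section(atlas, config,
                     distance_mm = design$distance_mm[i],
                     section_id = design$section_id[i],
                     condition = design$condition[i],
                     seed = .child_seed(seed, i))
  })
  stats::setNames(out, design$section_id)
}

#' Run the end-to-end synthetic pipeline
#'
#' simulate -> detect -> assign-to-regions -> quantify. Writes the atlas,
#' per-section detections, the sections x regions count matrix, survival
#' and distance-profile tables, Kruskal-Wallis tests per distance, and a
#' provenance record (seed, configuration, package version, per-stage
#' counts). Region assignment uses the atlas in place (identity
#' registration), which is exact for synthetic sections; supply warped
#' regions through [warp_regions()] for registered real data.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, a list with the `region_counts`, the
#'   `survival_profile`, the distance profile, the Kruskal-Wallis table,
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- build_toy_atlas(config$frame_um, config$n_laminae)
  write_atlas_geojson(atlas, file.path(config$out_dir, "atlas.geojson"))
  cohort <- simulate_cohort(atlas, config$sim, config$design, config$seed)
  if (config$write_images) {
    dir.create(file.path(config$out_dir, "sections"), showWarnings = FALSE)
  }
  assignments <- list(); all_det <- list()
  for (sid in names(cohort)) {
    sec <- cohort[[sid]]
    if (config$write_images) {
      write_section(sec$image,
                    file.path(config$out_dir, "sections",
                              paste0(sid, ".tif")), sec$truth)
    }
    det <- if (config$detect_method == "probmap") {
      pm <- simulate_probability_map(sec$truth, sec$image,
                                     config$miscalibration)
      probmap_to_detections(pm, sec$image$pixel_size_um, section_id = sid)
    } else {
      segment_neurons(sec$image,
                      detect_params(grey_mask = atlas$grey_outline))$detections
    }
    regions <- assign_to_regions(det, atlas$regions)
    message(sprintf("[%s] truth=%d detected=%d assigned=%d outside=%d",
                    sid, nrow(sec$truth$neurons), nrow(det),
                    sum(regions != "outside"), sum(regions == "outside")))
    all_det[[sid]] <- det
    assignments[[sid]] <- data.frame(section_id = sid, region_id = regions,
                                     x = det$x, y = det$y)
  }
  assignments <- do.call(rbind, assignments)
  det_df <- do.call(rbind, lapply(names(all_det), function(sid) {
    d <- all_det[[sid]]
    data.frame(section_id = sid, x_um = round(d$x, 3), y_um = round(d$y, 3),
               area_um2 = round(d$area_um2, 3))
  }))
  utils::write.csv(det_df, file.path(config$out_dir, "detections.csv"),
                   row.names = FALSE)
  rc <- region_counts(assignments, config$design,
                      region_ids = atlas$region_info$region_id)
  write_region_counts_csv(rc, file.path(config$out_dir, "region_counts.csv"))
  sp <- survival_percent(rc)
  dp <- distance_profile(sp)
  utils::write.csv(dp, file.path(config$out_dir, "distance_profile.csv"),
                   row.names = FALSE)
  # group comparison at each distance: control vs each injured condition
  meta <- config$design
  totals <- rowSums(rc$counts)
  kw <- list()
  for (d in sort(unique(meta$distance_mm[!is.na(meta$distance_mm)]))) {
    sel <- is.na(meta$distance_mm) | meta$distance_mm == d
    groups <- split(totals[sel], meta$condition[sel])
    if (length(groups) >= 2 && all(lengths(groups) > 0)) {
      res <- kruskal_wallis(groups)
      kw[[length(kw) + 1L]] <- data.frame(distance_mm = d, H = res$H,
                                          df = res$df, p_value = res$p_value)
    }
  }
  kw <- if (length(kw)) do.call(rbind, kw) else NULL
  if (!is.null(kw)) {
    utils::write.csv(kw, file.path(config$out_dir, "kruskal_wallis.csv"),
                     row.names = FALSE)
  }
  prov <- list(seed = config$seed,
               package_version = as.character(utils::packageVersion("laminacount")),
               detect_method = config$detect_method,
               radius_um = config$radius_um,
               miscalibration = config$miscalibration,
               n_sections = nrow(config$design),
               n_tests = if (is.null(kw)) 0L else nrow(kw),
               frame_um = unname(config$frame_um),
               n_laminae = config$n_laminae)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  surv_json <- list(reference_total = sp$total_reference,
                    by_condition = sp$by_condition)
  jsonlite::write_json(surv_json,
                       file.path(config$out_dir, "survival_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(region_counts = rc, survival = sp, distance_profile = dp,
                 kruskal_wallis = kw, out_dir = config$out_dir))
}
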