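# Procedural toy atlas: a butterfly-symmetric grey-matter outline
# partitioned into horizontal laminar bands (dorsal L1 .. ventral Ln) plus a
# band of named nuclei (IML, ICI, IMM, D, LDCom) in the intermediate zone.
# It stands in for a reference spinal-cord atlas section (Rexed laminae and
# nuclei) so that registration and quantification can be exercised against
# known geometry.

# Half-width (µm) of the grey outline at relative depth t in [0, 1]
# (0 = dorsal edge, 1 = ventral edge). Two bumps give the dorsal and the
# wider ventral horn, with a waist in between: a stylized cross-section.
.grey_halfwidth <- function(t, width_um) {
  width_um * (0.10 +
    0.14 * exp(-((t - 0.18) / 0.16)^2) +
    0.22 * exp(-((t - 0.80) / 0.20)^2))
}

#' Build a procedural Rexed-laminae toy atlas
#'
#' Constructs a deterministic, butterfly-symmetric grey-matter outline
#' inside the given frame and partitions it into `n_laminae` horizontal
#' laminar bands (`"L1"` dorsal to `"L<n>"` ventral) plus five nucleus
#' polygons (`"IML"`, `"ICI"`, `"IMM"`, `"D"`, `"LDCom"`) occupying one
#' intermediate band. Regions tile the outline without overlap; every
#' region is a simple polygon. Laminar bands are classed `dorsal` /
#' `intermediate` / `ventral` by depth; nuclei are `intermediate`
#' (they sit in the intermediate grey, where injury-induced neuronal loss
#' concentrates).
#'
#' @param frame_um numeric length-2, frame width and height in µm (> 0).
#' @param n_laminae integer number of laminar bands, between 3 and 15.
#' @return A `toy_atlas` object: list with `regions` (named list of
#'   two-column vertex matrices, in atlas order), `region_info`
#'   (data.frame `region_id`, `class`), `grey_outline`, `frame_um`,
#'   `n_laminae`.
#' @examples
#' atl <- build_toy_atlas(c(2000, 1500), 10)
#' names(atl$regions)
#' @export
build_toy_atlas <- function(frame_um = c(2000, 1500), n_laminae = 10L) {
  if (length(frame_um) != 2 || any(!is.finite(frame_um)) || any(frame_um <= 0)) {
    stop("`frame_um` must be two positive dimensions (width, height) in um")
  }
  n_laminae <- as.integer(n_laminae)
  if (is.na(n_laminae) || n_laminae < 3L || n_laminae > 15L) {
    stop("`n_laminae` must be an integer between 3 and 15")
  }
  W <- frame_um[1]; H <- frame_um[2]
  cx <- W / 2
  yd <- 0.12 * H; yv <- 0.88 * H
  n_slices <- n_laminae + 1L          # one slice is given over to the nuclei
  m <- 10L                             # y-subdivisions per slice
  ys <- seq(yd, yv, length.out = n_slices * m + 1L)
  t <- (ys - yd) / (yv - yd)
  hw <- .grey_halfwidth(t, W)

  band_poly <- function(rows, fl = -1, fr = 1) {
    # polygon between fraction curves fl..fr of the halfwidth over ys[rows]
    right <- cbind(cx + fr * hw[rows], ys[rows])
    left <- cbind(cx + fl * hw[rows], ys[rows])
    rbind(right, left[rev(seq_len(nrow(left))), , drop = FALSE])
  }

  all_rows <- seq_along(ys)
  grey_outline <- band_poly(all_rows)

  # which slice hosts the nuclei: intermediate depth
  nuc_slice <- max(2L, min(n_slices - 1L, as.integer(round(0.55 * n_slices))))
  regions <- list()
  info <- list()
  li <- 0L
  n_dorsal <- ceiling(0.4 * n_laminae)
  n_interm <- ceiling(0.7 * n_laminae)
  for (s in seq_len(n_slices)) {
    rows <- ((s - 1L) * m + 1L):(s * m + 1L)
    if (s == nuc_slice) {
      cuts <- c(-1, -0.6, -0.2, 0.2, 0.6, 1)
      nuc_ids <- c("IML", "ICI", "IMM", "D", "LDCom")
      for (q in seq_along(nuc_ids)) {
        regions[[nuc_ids[q]]] <- band_poly(rows, cuts[q], cuts[q + 1L])
        info[[nuc_ids[q]]] <- "intermediate"
      }
    } else {
      li <- li + 1L
      id <- paste0("L", li)
      regions[[id]] <- band_poly(rows)
      info[[id]] <- if (li <= n_dorsal) "dorsal"
        else if (li <= n_interm) "intermediate" else "ventral"
    }
  }
  structure(list(
    regions = regions,
    region_info = data.frame(region_id = names(regions),
                             class = unlist(info, use.names = FALSE),
                             stringsAsFactors = FALSE),
    grey_outline = grey_outline,
    frame_um = c(width = W, height = H),
    n_laminae = n_laminae
  ), class = "toy_atlas")
}

#' @export
print.toy_atlas <- function(x, ...) {
  cat(sprintf("toy_atlas: %d regions (%d laminae + %d nuclei), frame %g x %g um\n",
              length(x$regions), x$n_laminae,
              length(x$regions) - x$n_laminae,
              x$frame_um[1], x$frame_um[2]))
  invisible(x)
}

#' Areas of atlas regions
#'
#' @param atlas a `toy_atlas` (or any named list of polygons in `$regions`).
#' @return Named numeric vector of areas in µm².
#' @export
region_areas <- function(atlas) {
  vapply(atlas$regions, polygon_area, numeric(1))
}

#' Default per-region neuron densities
#'
#' Calibrates class-weighted densities (dorsal laminae rich, nuclei sparse,
#' mirroring the observed distribution in thoracic cord sections) so that
#' the expected total over the whole grey matter equals `total_neurons`
#' (default 283, a typical control-section census).
#'
#' @param atlas a `toy_atlas`.
#' @param total_neurons expected neurons per uninjured section.
#' @return Named vector, neurons per mm² for each region.
#' @export
default_densities <- function(atlas, total_neurons = 283) {
  w <- c(dorsal = 1.6, intermediate = 0.9, ventral = 1.2)
  weight <- w[atlas$region_info$class]
  is_nucleus <- !grepl("^L[0-9]+$", atlas$region_info$region_id)
  weight[is_nucleus] <- 0.5
  area_mm2 <- region_areas(atlas) / 1e6
  k <- total_neurons / sum(weight * area_mm2)
  stats::setNames(k * weight, atlas$region_info$region_id)
}

#' Write an atlas (or any region set) as a GeoJSON-style file
#'
#' One `Polygon` feature per region with `region_id` and `class`
#' properties; the grey outline is stored as a feature with
#' `region_id = ".grey"`. Coordinates are µm in frame space.
#'
#' @param atlas a `toy_atlas`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atlas_geojson <- function(atlas, path) {
  feat <- function(id, poly, class = NA_character_) {
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(region_id = id, class = class),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1, as.numeric,
                                                         simplify = FALSE)))))
  }
  feats <- Map(feat, atlas$region_info$region_id, atlas$regions,
               atlas$region_info$class)
  feats <- c(unname(feats), list(feat(".grey", atlas$grey_outline)))
  obj <- list(type = "FeatureCollection",
              properties = list(frame_um = unname(atlas$frame_um),
                                n_laminae = atlas$n_laminae),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas written by [write_atlas_geojson()]
#'
#' @param path GeoJSON-style file path.
#' @return A `toy_atlas` object.
#' @export
read_atlas_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  regions <- list(); classes <- character(0); grey <- NULL
  for (f in obj$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    id <- f$properties$region_id
    if (identical(id, ".grey")) {
      grey <- ring
    } else {
      regions[[id]] <- ring
      classes[id] <- f$properties$class
    }
  }
  structure(list(
    regions = regions,
    region_info = data.frame(region_id = names(regions),
                             class = unname(classes[names(regions)]),
                             stringsAsFactors = FALSE),
    grey_outline = grey,
    frame_um = c(width = obj$properties$frame_um[[1]],
                 height = obj$properties$frame_um[[2]]),
    n_laminae = if (!is.null(obj$properties$n_laminae))
      obj$properties$n_laminae else sum(grepl("^L[0-9]+$", names(regions)))
  ), class = "toy_atlas")
}
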