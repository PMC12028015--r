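# Threshold-based neuron identification: re-implements the semi-automated
# macro logic (threshold the neuronal channel, restrict to grey matter,
# require nuclear colocalization, size-filter the particles) plus the
# post-processing rule applied to pixel-classifier probability maps
# (particles above 25 um^2 of pixels above 50% probability).

#' Construct a detection set
#'
#' A set of point identifications of neurons from one source (an observer
#' or an automated method) on one section. Coordinates are µm in frame
#' space.
#'
#' @param x,y numeric coordinate vectors (µm).
#' @param area_um2 optional per-object segmented areas.
#' @param source_id label of the producing source.
#' @param section_id section identifier.
#' @return A `detection_set`: data.frame `x, y, area_um2` with attributes
#'   `source_id`, `section_id`.
#' @export
detection_set <- function(x, y, area_um2 = NULL, source_id = "unknown",
                          section_id = "S1") {
  stopifnot(length(x) == length(y))
  if (is.null(area_um2)) area_um2 <- rep(NA_real_, length(x))
  ds <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   area_um2 = as.numeric(area_um2))
  attr(ds, "source_id") <- source_id
  attr(ds, "section_id") <- section_id
  class(ds) <- c("detection_set", "data.frame")
  ds
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("detection_set '%s' on '%s': %d points\n",
              attr(x, "source_id"), attr(x, "section_id"), nrow(x)))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' 8-connectivity labeling built on `EBImage::bwlabel` (4-connected)
#' followed by a union-find merge of labels that touch diagonally.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer label matrix (0 = background), labels compacted to
#'   1..n in raster order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- as.matrix(EBImage::bwlabel(m))
  nl <- max(lab)
  if (connectivity == 8 && nl > 1) {
    parent <- seq_len(nl)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
    h <- nrow(lab); w <- ncol(lab)
    # diagonal neighbour pairs: (i, j) with (i+1, j+1) and (i+1, j-1)
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]
    a2 <- lab[-h, -1]; b2 <- lab[-1, -w]
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                            pairs[, 1] != pairs[, 2], , drop = FALSE])
    for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
    root <- vapply(seq_len(nl), find, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  # compact labels in raster order of first occurrence
  u <- unique(as.vector(t(lab))); u <- u[u > 0]
  remap <- integer(max(lab, 1L)); remap[u] <- seq_along(u)
  lab[lab > 0] <- remap[lab[lab > 0]]
  storage.mode(lab) <- "integer"
  lab
}

#' Select an intensity threshold for a channel
#'
#' Implements the standard histogram criteria used by the semi-automated
#' macro's selectable thresholding algorithms. Images are expected in
#' \[0, 1\]; histograms use 256 bins. `"auto"` tries all histogram methods
#' and keeps the one maximizing foreground/background contrast
#' (between-class variance at the resulting cut), replacing the original
#' per-image manual choice with a reproducible rule.
#'
#' @param channel numeric matrix in \[0, 1\].
#' @param method one of `"otsu"`, `"triangle"`, `"isodata"`, `"mean"`,
#'   `"fixed"`, `"auto"`.
#' @param fixed_threshold required when `method = "fixed"`.
#' @return Scalar threshold; pixels strictly above it are foreground.
#' @export
select_threshold <- function(channel,
                             method = c("otsu", "triangle", "isodata",
                                        "mean", "fixed", "auto"),
                             fixed_threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) stop("`fixed_threshold` required for method 'fixed'")
    return(fixed_threshold)
  }
  v <- as.vector(channel)
  if (length(v) == 0) stop("empty channel")
  if (method == "auto") {
    cands <- c("otsu", "triangle", "isodata", "mean")
    thr <- vapply(cands, function(m) select_threshold(channel, m), numeric(1))
    contrast <- vapply(thr, function(t) {
      fg <- v > t
      if (!any(fg) || all(fg)) return(-Inf)
      mean(fg) * (1 - mean(fg)) * (mean(v[fg]) - mean(v[!fg]))^2
    }, numeric(1))
    return(unname(thr[which.max(contrast)]))
  }
  if (method == "mean") return(mean(v))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    # degenerate histogram: documented fallback, return max intensity
    warning("constant image: threshold set to its single intensity")
    return(rng[2])
  }
  if (method == "otsu") {
    return(EBImage::otsu(EBImage::Image(channel), range = c(0, 1), levels = 256))
  }
  breaks <- seq(0, 1, length.out = 257)
  h <- tabulate(pmin(256L, pmax(1L, findInterval(v, breaks,
                                                 rightmost.closed = TRUE))), 256L)
  mids <- (breaks[-1] + breaks[-257]) / 2
  if (method == "isodata") {
    t <- mean(v)
    for (it in 1:100) {
      lo <- v <= t; hi <- !lo
      if (!any(lo) || !any(hi)) break
      t_new <- (mean(v[lo]) + mean(v[hi])) / 2
      if (abs(t_new - t) < 1e-8) { t <- t_new; break }
      t <- t_new
    }
    return(t)
  }
  # triangle: line from histogram peak to the far end of the longer tail;
  # threshold at the bin with maximum perpendicular distance to that line
  pk <- which.max(h)
  nz <- which(h > 0)
  lo <- min(nz); hi <- max(nz)
  end <- if ((hi - pk) >= (pk - lo)) hi else lo
  idx <- if (end > pk) pk:end else end:pk
  x1 <- pk; y1 <- h[pk]; x2 <- end; y2 <- h[end]
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1)
  mids[idx[which.max(d)]]
}

#' Detection parameters for threshold-based segmentation
#'
#' @param threshold_method method passed to [select_threshold()].
#' @param fixed_threshold scalar, required iff `threshold_method = "fixed"`.
#' @param require_nuclear_colocalization drop somas whose component does
#'   not intersect the (1 px dilated) thresholded nuclear mask.
#' @param min_area_um2 strict lower area bound for particles: objects are
#'   kept only if area > `min_area_um2` (default 25 µm²).
#' @param grey_mask polygon (two-column matrix), logical raster, or `NULL`
#'   (no restriction, logged with a message).
#' @param split_touching apply a watershed split on the distance
#'   transform before size filtering.
#' @param watershed_tolerance minimum depth between watershed seeds, in
#'   distance-map units (px); larger values split less aggressively.
#' @return A `detect_params` list.
#' @export
detect_params <- function(threshold_method = "otsu", fixed_threshold = NULL,
                          require_nuclear_colocalization = TRUE,
                          min_area_um2 = 25, grey_mask = NULL,
                          split_touching = FALSE, watershed_tolerance = 1) {
  if (min_area_um2 <= 0) stop("`min_area_um2` must be > 0")
  if (identical(threshold_method, "fixed") && is.null(fixed_threshold)) {
    stop("`fixed_threshold` required when threshold_method = 'fixed'")
  }
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 require_nuclear_colocalization = require_nuclear_colocalization,
                 min_area_um2 = min_area_um2, grey_mask = grey_mask,
                 split_touching = split_touching,
                 watershed_tolerance = watershed_tolerance),
            class = "detect_params")
}

# Rasterize a grey-matter polygon to a pixel-center mask.
.rasterize_mask <- function(poly, dim_hw, pixel_size_um) {
  h <- dim_hw[1]; w <- dim_hw[2]
  px <- ((seq_len(w)) - 0.5) * pixel_size_um
  py <- ((seq_len(h)) - 0.5) * pixel_size_um
  gx <- rep(px, each = h); gy <- rep(py, times = w)
  matrix(points_in_polygon(gx, gy, poly), h, w)
}

# Centroids and areas from a label matrix (label ids may have gaps, e.g.
# after the colocalization filter); returns data.frame in label order.
.component_stats <- function(lab, pixel_size_um) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_um2 = numeric(0)))
  }
  l <- lab[idx]
  i <- ((idx - 1L) %% nrow(lab)) + 1L
  j <- ((idx - 1L) %/% nrow(lab)) + 1L
  fl <- factor(l)
  npx <- as.vector(table(fl))
  sx <- as.vector(tapply((j - 0.5) * pixel_size_um, fl, sum))
  sy <- as.vector(tapply((i - 0.5) * pixel_size_um, fl, sum))
  data.frame(label = as.integer(levels(fl)),
             x = sx / npx, y = sy / npx,
             area_um2 = npx * pixel_size_um^2)
}

#' Threshold-based neuron segmentation
#'
#' Pipeline: threshold the neuronal channel, restrict to the grey-matter
#' mask, label 8-connected components (optionally watershed-split touching
#' somas), drop components without nuclear colocalization (component must
#' intersect the thresholded nuclear mask dilated by 1 px), and discard
#' particles with area not strictly above `min_area_um2`.
#'
#' @param image a `section_image`.
#' @param params a `detect_params`.
#' @return List with `labels` (integer raster of surviving components,
#'   relabeled 1..n) and `detections` (a `detection_set` of component
#'   centroids with areas, `source_id = "threshold"`).
#' @export
segment_neurons <- function(image, params = detect_params()) {
  s <- image$pixel_size_um
  neuronal <- image$neuronal
  thr <- select_threshold(neuronal, params$threshold_method,
                          params$fixed_threshold)
  mask <- neuronal > thr
  if (is.null(params$grey_mask)) {
    message("no grey-matter mask provided; detections are not restricted")
  } else {
    gm <- params$grey_mask
    if (is.matrix(gm) && ncol(gm) == 2 && !is.logical(gm)) {
      gm <- .rasterize_mask(gm, dim(neuronal), s)
    }
    mask <- mask & gm
  }
  if (params$split_touching) {
    dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
    lab <- as.matrix(EBImage::watershed(dm, tolerance = params$watershed_tolerance))
  } else {
    lab <- label_components(mask, 8)
  }
  if (params$require_nuclear_colocalization) {
    if (is.null(image$nuclear)) {
      stop("nuclear channel required for colocalization but absent")
    }
    thr_n <- select_threshold(image$nuclear, params$threshold_method,
                              params$fixed_threshold)
    nuc <- EBImage::dilate(matrix(as.numeric(image$nuclear > thr_n),
                                  nrow(neuronal)),
                           EBImage::makeBrush(3, "box"))
    nuc <- as.matrix(nuc) > 0
    keep_coloc <- unique(lab[lab > 0 & nuc])
    lab[!(lab %in% keep_coloc)] <- 0L
  }
  st <- .component_stats(lab, s)
  st <- st[st$area_um2 > params$min_area_um2, , drop = FALSE]
  # relabel surviving components 1..n
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_len(nrow(st))) out[lab == st$label[k]] <- k
  list(labels = out,
       detections = detection_set(st$x, st$y, st$area_um2,
                                  source_id = "threshold",
                                  section_id = image$section_id))
}

#' Post-process a probability map into neuron detections
#'
#' Applies the particle rule used on pixel-classifier output: keep
#' 8-connected components of pixels with probability above `p_cut`
#' whose area exceeds `min_area_um2`, and report their centroids.
#'
#' @param probmap matrix of probabilities in \[0, 1\].
#' @param pixel_size_um microns per pixel.
#' @param p_cut probability cut (default 0.5; pixels with `p > p_cut`).
#' @param min_area_um2 strict area cut (default 25 µm²).
#' @param section_id carried into the result.
#' @return A `detection_set` (`source_id = "probmap"`).
#' @export
probmap_to_detections <- function(probmap, pixel_size_um, p_cut = 0.5,
                                  min_area_um2 = 25, section_id = "S1") {
  if (any(probmap < 0 | probmap > 1)) stop("probabilities must lie in [0, 1]")
  lab <- label_components(probmap > p_cut, 8)
  st <- .component_stats(lab, pixel_size_um)
  st <- st[st$area_um2 > min_area_um2, , drop = FALSE]
  detection_set(st$x, st$y, st$area_um2, source_id = "probmap",
                section_id = section_id)
}
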