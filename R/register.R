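# Landmark-based thin-plate-spline registration between atlas space and
# section space, transfer of atlas region polygons onto sections, and
# assignment of detections to laminae/nuclei. The atlas is treated as the
# moving image mapped onto the section, so detections are never deformed;
# the inverse direction is available for atlas-space analyses.

#' Read landmark pairs from CSV
#'
#' Expected columns: `name`, `fixed_x`, `fixed_y`, `moving_x`, `moving_y`
#' and optional `active` (0/1); inactive rows are dropped. Coordinates in
#' µm. This is a readable equivalent of the exports produced by
#' landmark-placement GUIs.
#'
#' @param path CSV path.
#' @return data.frame of active landmark pairs.
#' @export
read_landmarks <- function(path) {
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fixed_x", "fixed_y", "moving_x", "moving_y")
  if (!all(need %in% names(lm))) {
    stop("landmark CSV must contain columns: ", paste(need, collapse = ", "))
  }
  if ("active" %in% names(lm)) lm <- lm[lm$active != 0, , drop = FALSE]
  lm
}

#' Write landmark pairs to CSV
#'
#' @param landmarks data.frame with `fixed_x`, `fixed_y`, `moving_x`,
#'   `moving_y` (optional `name`, `active`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  if (is.null(landmarks$name)) landmarks$name <- paste0("lm", seq_len(nrow(landmarks)))
  if (is.null(landmarks$active)) landmarks$active <- 1L
  utils::write.csv(landmarks[, c("name", "fixed_x", "fixed_y",
                                 "moving_x", "moving_y", "active")],
                   path, row.names = FALSE)
  invisible(path)
}

# TPS radial kernel U(r) = r^2 log r^2, with U(0) = 0, on squared distances.
.tps_kernel <- function(r2) {
  u <- numeric(length(r2))
  pos <- r2 > 0
  u[pos] <- r2[pos] * log(r2[pos])
  dim(u) <- dim(r2)
  u
}

.pairwise_r2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

#' Fit a thin-plate-spline transform to landmark pairs
#'
#' Solves the standard TPS linear system with kernel U(r) = r² log r²
#' (U(0) = 0) and an affine part. With `lambda = 0` the transform
#' interpolates every landmark exactly; `lambda > 0` smooths. By default
#' the transform maps moving-space coordinates (the atlas) onto
#' fixed-space coordinates (the section); set
#' `direction = "fixed_to_moving"` for the inverse fit.
#'
#' @param landmarks data.frame with `fixed_x`, `fixed_y`, `moving_x`,
#'   `moving_y` (µm); at least 3 non-collinear pairs, no duplicated
#'   source positions.
#' @param lambda regularization (>= 0).
#' @param direction which way the fitted map goes.
#' @return A `tps_transform`: `affine` (3x2: intercept, x, y
#'   coefficients per output coordinate), `kernel_weights` (n x 2),
#'   `source_landmarks`, `lambda`, `residuals` (per-landmark Euclidean
#'   residual, µm).
#' @export
fit_tps <- function(landmarks, lambda = 0,
                    direction = c("moving_to_fixed", "fixed_to_moving")) {
  direction <- match.arg(direction)
  if (lambda < 0) stop("`lambda` must be >= 0")
  src <- if (direction == "moving_to_fixed") {
    cbind(landmarks$moving_x, landmarks$moving_y)
  } else {
    cbind(landmarks$fixed_x, landmarks$fixed_y)
  }
  dst <- if (direction == "moving_to_fixed") {
    cbind(landmarks$fixed_x, landmarks$fixed_y)
  } else {
    cbind(landmarks$moving_x, landmarks$moving_y)
  }
  n <- nrow(src)
  if (n < 3) stop("at least 3 landmark pairs are required")
  dup <- duplicated(src) | duplicated(src, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicated source landmark positions at rows: ",
         paste(which(dup), collapse = ", "))
  }
  P <- cbind(1, src)
  qrp <- qr(P)
  if (qrp$rank < 3) {
    stop("landmarks are collinear; TPS system is singular")
  }
  K <- .tps_kernel(.pairwise_r2(src, src))
  # null-space formulation: restrict the kernel system to the orthogonal
  # complement of the affine space, which enforces sum(w) = 0 and
  # sum(w * x) = 0 exactly and keeps the solve well conditioned in µm
  Q <- qr.Q(qrp, complete = TRUE)
  R <- qr.R(qrp)
  Q1 <- Q[, 1:3, drop = FALSE]
  Q2 <- Q[, -(1:3), drop = FALSE]
  Kl <- K + lambda * diag(n)
  gamma <- tryCatch(solve(t(Q2) %*% Kl %*% Q2, t(Q2) %*% dst),
                    error = function(e) {
                      stop("TPS system is singular: ", conditionMessage(e))
                    })
  w <- Q2 %*% gamma
  a <- solve(R, t(Q1) %*% (dst - Kl %*% w))
  tf <- structure(list(affine = a, kernel_weights = w,
                       source_landmarks = src, lambda = lambda,
                       direction = direction),
                  class = "tps_transform")
  pred <- apply_tps(tf, src)
  tf$residuals <- sqrt(rowSums((pred - dst)^2))
  tf
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("tps_transform (%s): %d landmarks, lambda=%g, max residual %.3g um\n",
              x$direction, nrow(x$source_landmarks), x$lambda,
              max(x$residuals)))
  invisible(x)
}

#' Apply a thin-plate-spline transform to points
#'
#' f(p) = affine · (1, x, y) + Σᵢ wᵢ U(‖p − cᵢ‖), evaluated for both
#' output coordinates, vectorized over points.
#'
#' @param transform a `tps_transform`.
#' @param points two-column matrix (or data.frame with `x`, `y`) in the
#'   transform's source space, µm.
#' @return Two-column matrix of transformed coordinates.
#' @export
apply_tps <- function(transform, points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- matrix(as.numeric(points), ncol = 2)
  U <- .tps_kernel(.pairwise_r2(points, transform$source_landmarks))
  cbind(1, points) %*% transform$affine + U %*% transform$kernel_weights
}

#' Warp atlas region polygons into section space
#'
#' Edges are subdivided so no segment exceeds `densify_um` before
#' vertex-wise mapping, preserving curved deformations of straight atlas
#' edges. Warped polygons that self-intersect are flagged (their counts
#' should be treated as low confidence) with a warning.
#'
#' @param atlas a `toy_atlas`, or a named list of polygons.
#' @param transform a `tps_transform` mapping atlas (moving) space to
#'   section (fixed) space.
#' @param densify_um maximum pre-warp segment length (> 0).
#' @return Named list of warped polygons with attribute `flagged`
#'   (logical vector: self-intersecting after warp).
#' @export
warp_regions <- function(atlas, transform, densify_um = 25) {
  stopifnot(densify_um > 0)
  regions <- if (inherits(atlas, "toy_atlas")) atlas$regions else atlas
  warped <- lapply(regions, function(poly) {
    apply_tps(transform, densify_polygon(poly, densify_um))
  })
  flagged <- !vapply(warped, polygon_is_simple, logical(1))
  if (any(flagged)) {
    warning("warped polygon(s) self-intersect: ",
            paste(names(warped)[flagged], collapse = ", "))
  }
  attr(warped, "flagged") <- flagged
  warped
}

#' Assign detections to atlas regions
#'
#' Even-odd point-in-polygon test against each region polygon in atlas
#' order; the first containing region wins (this resolves shared
#' boundaries deterministically), and points contained by no region are
#' assigned `"outside"`.
#'
#' @param detections a `detection_set` (coordinates in section space, µm).
#' @param regions named list of (possibly warped) region polygons, in
#'   atlas order.
#' @return Character vector of region ids (or `"outside"`), one per
#'   detection, plus a `data.frame` method-friendly attribute-free result.
#' @export
assign_to_regions <- function(detections, regions) {
  n <- nrow(detections)
  out <- rep("outside", n)
  un <- rep(TRUE, n)
  for (id in names(regions)) {
    if (!any(un)) break
    hit <- points_in_polygon(detections$x[un], detections$y[un], regions[[id]])
    out[which(un)[hit]] <- id
    un[which(un)[hit]] <- FALSE
  }
  out
}
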