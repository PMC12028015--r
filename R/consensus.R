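# Multi-analysis consensus: overlap the point identifications from K
# analyses (observers and/or automated methods) into matched objects, count
# for each object the number of manual analyses that identified it
# (agreement class k in 0..K), and derive the Reference Number of Neurons
# (RNN) as the weighted consensus of the manual estimations.

# Ensure every set has a unique source name.
.named_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- vapply(seq_along(sets), function(i) {
      sid <- attr(sets[[i]], "source_id")
      if (is.null(sid) || sid == "unknown") paste0("src", i) else sid
    }, character(1))
  }
  if (anyDuplicated(names(sets))) {
    names(sets) <- make.unique(names(sets), sep = "_")
  }
  sets
}

# Pool a list of detection sets into one data.frame with source indices.
.pool_sets <- function(sets) {
  do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (nrow(s) == 0) return(NULL)
    data.frame(x = s$x, y = s$y, src = i, stringsAsFactors = FALSE)
  }))
}

# Build an agreement_table from a pooled point table and a partition
# (list of integer index vectors into `pts`).
.partition_to_table <- function(pts, partition, sources, manual, radius,
                                section_id) {
  K <- sum(manual)
  if (length(partition)) {
    # deterministic object order: by (y, x) of centroid
    cx <- vapply(partition, function(ix) mean(pts$x[ix]), numeric(1))
    cy <- vapply(partition, function(ix) mean(pts$y[ix]), numeric(1))
    ord <- order(cy, cx)
    partition <- partition[ord]; cx <- cx[ord]; cy <- cy[ord]
    k <- vapply(partition, function(ix) sum(manual[pts$src[ix]]), numeric(1))
    objects <- data.frame(object_id = seq_along(partition),
                          x = cx, y = cy, k = as.integer(k))
    members <- do.call(rbind, lapply(seq_along(partition), function(o) {
      ix <- partition[[o]]
      data.frame(object_id = o, source_id = sources[pts$src[ix]],
                 x = pts$x[ix], y = pts$y[ix],
                 manual = manual[pts$src[ix]], stringsAsFactors = FALSE)
    }))
    cost <- radius * length(partition) +
      sum(vapply(seq_along(partition), function(o) {
        ix <- partition[[o]]
        sum(sqrt((pts$x[ix] - cx[o])^2 + (pts$y[ix] - cy[o])^2))
      }, numeric(1)))
  } else {
    objects <- data.frame(object_id = integer(0), x = numeric(0),
                          y = numeric(0), k = integer(0))
    members <- data.frame(object_id = integer(0), source_id = character(0),
                          x = numeric(0), y = numeric(0), manual = logical(0))
    cost <- 0
  }
  structure(list(objects = objects, members = members, K = K,
                 sources = sources, manual_sources = sources[manual],
                 radius = radius, section_id = section_id, cost = cost),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("agreement_table '%s': %d objects from %d sources (K=%d manual), radius %g um\n",
              x$section_id, nrow(x$objects), length(x$sources), x$K, x$radius))
  if (nrow(x$objects)) {
    tb <- table(factor(x$objects$k, levels = 0:x$K))
    cat("  agreement classes:", paste(sprintf("%s:%d", names(tb), tb),
                                      collapse = " "), "\n")
  }
  invisible(x)
}

#' Match detection sets from several analyses into consensus objects
#'
#' Partitions all points into objects so that within an object (i) every
#' pair of points lies within `radius_um` of each other and (ii) each
#' source contributes at most one point. Linking is greedy over all
#' cross-source candidate pairs in increasing distance (ties broken by
#' source index, then coordinates), merging two groups only when the
#' one-per-source and complete-linkage constraints hold — a global rule
#' that is independent of the order in which the sets are supplied.
#'
#' @param sets named list of `detection_set`s on the same section.
#' @param radius_um linking radius (> 0); about one soma radius.
#' @param manual logical vector (one per set): which sets are manual
#'   analyses (count toward the agreement class k). Default all manual.
#' @return An `agreement_table`: `objects` (consensus centroid and class
#'   `k`), `members` (contributing points), `K`, `radius`, total matching
#'   `cost` (radius x objects + point-to-centroid distances).
#' @export
match_detection_sets <- function(sets, radius_um = 10, manual = NULL) {
  if (!is.numeric(radius_um) || radius_um <= 0) stop("`radius_um` must be > 0")
  if (is.null(manual)) manual <- rep(TRUE, length(sets))
  stopifnot(length(manual) == length(sets))
  sets <- .named_sets(sets)
  section_id <- attr(sets[[1]], "section_id") %||% "S1"
  pts <- .pool_sets(sets)
  sources <- names(sets)
  if (is.null(pts) || nrow(pts) == 0) {
    return(.partition_to_table(data.frame(x = numeric(0), y = numeric(0),
                                          src = integer(0)),
                               list(), sources, manual, radius_um, section_id))
  }
  n <- nrow(pts)
  parent <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
    cand <- which(upper.tri(d) & d <= radius_um, arr.ind = TRUE)
    if (nrow(cand)) {
      cross <- pts$src[cand[, 1]] != pts$src[cand[, 2]]
      cand <- cand[cross, , drop = FALSE]
    }
    if (nrow(cand)) {
      i1 <- cand[, 1]; i2 <- cand[, 2]
      s1 <- pmin(pts$src[i1], pts$src[i2]); s2 <- pmax(pts$src[i1], pts$src[i2])
      dd <- d[cand]
      ord <- order(dd, s1, s2, pts$x[i1], pts$y[i1], pts$x[i2], pts$y[i2])
      for (q in ord) {
        a <- find(i1[q]); b <- find(i2[q])
        if (a == b) next
        ma <- members[[a]]; mb <- members[[b]]
        if (length(intersect(pts$src[ma], pts$src[mb]))) next
        if (max(d[ma, mb]) > radius_um) next   # complete linkage
        parent[b] <- a
        members[[a]] <- c(ma, mb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  partition <- unname(split(seq_len(n), roots))
  .partition_to_table(pts, partition, sources, manual, radius_um, section_id)
}

#' Exhaustive minimum-cost matching (brute-force reference)
#'
#' Enumerates every feasible partition (one point per source per object,
#' all pairwise distances within the radius) and returns the one with
#' minimum cost, where cost = `radius_um` x number of objects + the sum of
#' point-to-centroid distances. Feasible objects are confined to connected
#' components of the within-radius graph, so enumeration is exact and
#' affordable on small instances; components larger than `max_component`
#' points raise an error. Intended as an independent check of
#' [match_detection_sets()].
#'
#' @inheritParams match_detection_sets
#' @param max_component guard on enumeration size.
#' @return An `agreement_table` with the optimal partition and `cost`.
#' @export
match_detection_sets_exhaustive <- function(sets, radius_um = 10,
                                            manual = NULL,
                                            max_component = 14L) {
  if (!is.numeric(radius_um) || radius_um <= 0) stop("`radius_um` must be > 0")
  if (is.null(manual)) manual <- rep(TRUE, length(sets))
  sets <- .named_sets(sets)
  section_id <- attr(sets[[1]], "section_id") %||% "S1"
  pts <- .pool_sets(sets)
  sources <- names(sets)
  if (is.null(pts) || nrow(pts) == 0) {
    return(.partition_to_table(data.frame(x = numeric(0), y = numeric(0),
                                          src = integer(0)),
                               list(), sources, manual, radius_um, section_id))
  }
  n <- nrow(pts)
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  adj <- d <= radius_um & outer(pts$src, pts$src, "!=")
  # connected components of the cross-source within-radius graph
  comp <- integer(n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      queue <- i; comp[i] <- cid
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cid; queue <- c(queue, nb)
      }
    }
  }
  part_cost <- function(groups, idx) {
    radius_um * length(groups) + sum(vapply(groups, function(g) {
      ix <- idx[g]
      cx <- mean(pts$x[ix]); cy <- mean(pts$y[ix])
      sum(sqrt((pts$x[ix] - cx)^2 + (pts$y[ix] - cy)^2))
    }, numeric(1)))
  }
  partition <- list()
  for (c_ in seq_len(cid)) {
    idx <- which(comp == c_)
    m <- length(idx)
    if (m > max_component) {
      stop("component of ", m, " points exceeds exhaustive enumeration guard")
    }
    best <- NULL; best_cost <- Inf
    recurse <- function(p, groups) {
      if (p > m) {
        cst <- part_cost(groups, idx)
        if (cst < best_cost) { best_cost <<- cst; best <<- groups }
        return(invisible())
      }
      for (g in seq_along(groups)) {
        ix <- idx[groups[[g]]]
        if (any(pts$src[ix] == pts$src[idx[p]])) next
        if (any(d[ix, idx[p]] > radius_um)) next
        groups[[g]] <- c(groups[[g]], p)
        recurse(p + 1L, groups)
        groups[[g]] <- groups[[g]][-length(groups[[g]])]
      }
      recurse(p + 1L, c(groups, list(p)))
    }
    recurse(1L, list())
    partition <- c(partition, lapply(best, function(g) idx[g]))
  }
  .partition_to_table(pts, partition, sources, manual, radius_um, section_id)
}

#' Agreement-class histogram
#'
#' Counts matched objects by agreement class: class k (1..K) = objects
#' identified in exactly k manual analyses; class 0 = objects contributed
#' only by non-manual (automated) sets. When `extra_sets` is supplied, the
#' match is recomputed over the manual points stored in `table` plus the
#' extra sets. With `normalize = TRUE`, frequencies are scaled so classes
#' 1..K sum to 100 ("per 100 neurons in manual analyses").
#'
#' @param table an `agreement_table` from manual analyses.
#' @param extra_sets optional list of automated `detection_set`s.
#' @param normalize scale classes so that the manual classes sum to 100.
#' @return Named numeric vector of frequencies for classes `0..K`.
#' @export
agreement_histogram <- function(table, extra_sets = NULL, normalize = FALSE) {
  if (!is.null(extra_sets)) {
    manual_sets <- .table_to_sets(table)
    sets <- c(manual_sets, extra_sets)
    manual <- c(rep(TRUE, length(manual_sets)), rep(FALSE, length(extra_sets)))
    table <- match_detection_sets(sets, radius_um = table$radius,
                                  manual = manual)
  }
  freq <- table(factor(table$objects$k, levels = 0:table$K))
  freq <- stats::setNames(as.numeric(freq), names(freq))
  if (normalize) {
    tot <- sum(freq[-1])
    if (tot > 0) freq <- freq / tot * 100
  }
  freq
}

# Reconstruct per-source detection sets from a table's member points.
.table_to_sets <- function(table) {
  srcs <- table$manual_sources
  sets <- lapply(srcs, function(s) {
    mm <- table$members[table$members$source_id == s, , drop = FALSE]
    detection_set(mm$x, mm$y, source_id = s, section_id = table$section_id)
  })
  stats::setNames(sets, srcs)
}

#' Reference Number of Neurons (RNN)
#'
#' The weighted consensus of the manual estimations: each matched object
#' contributes its agreement fraction k/K, so the RNN equals the
#' arithmetic mean of the K per-analyst counts.
#'
#' @param table an `agreement_table` with `K >= 1` manual analyses.
#' @return Non-negative scalar.
#' @export
reference_number_of_neurons <- function(table) {
  if (table$K < 1) stop("RNN requires at least one manual analysis (K >= 1)")
  sum(table$objects$k) / table$K
}

#' Overlap of an automated method with the manual consensus
#'
#' Matches the method's detections one-to-one to consensus objects
#' (greedy by increasing distance, within `radius_um`) and reports, per
#' manual agreement class k, the fraction of class-k objects the method
#' detected, plus the percentage of method detections not matching any
#' manual object (expressed per 100 manually identified objects).
#'
#' @param method_set a `detection_set` from an automated method.
#' @param table an `agreement_table` of the manual analyses on the same
#'   section.
#' @param radius_um matching radius (defaults to the table's radius).
#' @return List with `class_fraction` (named vector over k = 1..K),
#'   `extra_percent`, `n_extra`, `n_method`.
#' @export
method_overlap_stats <- function(method_set, table, radius_um = table$radius) {
  objs <- table$objects[table$objects$k >= 1, , drop = FALSE]
  nm <- nrow(method_set)
  matched_obj <- integer(0)
  if (nm > 0 && nrow(objs) > 0) {
    dx <- outer(method_set$x, objs$x, "-")
    dy <- outer(method_set$y, objs$y, "-")
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= radius_um, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      used_m <- logical(nm); used_o <- logical(nrow(objs))
      for (q in ord) {
        i <- cand[q, 1]; j <- cand[q, 2]
        if (used_m[i] || used_o[j]) next
        used_m[i] <- TRUE; used_o[j] <- TRUE
        matched_obj <- c(matched_obj, j)
      }
    }
  }
  ks <- seq_len(max(1L, table$K))
  class_fraction <- vapply(ks, function(k) {
    sel <- objs$k == k
    if (!any(sel)) return(NA_real_)
    mean(which(sel) %in% matched_obj)
  }, numeric(1))
  names(class_fraction) <- as.character(ks)
  n_extra <- if (nm > 0) nm - length(matched_obj) else 0L
  denom <- nrow(objs)
  extra_percent <- if (nm == 0 || denom == 0) 0 else 100 * n_extra / denom
  list(class_fraction = class_fraction, extra_percent = extra_percent,
       n_extra = n_extra, n_method = nm)
}

#' Write an agreement table as CSV
#'
#' One row per object: id, consensus position, class k, and one 0/1 flag
#' column per source.
#'
#' @param table an `agreement_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(table, path) {
  out <- table$objects
  for (s in table$sources) {
    hit <- table$members$object_id[table$members$source_id == s]
    out[[s]] <- as.integer(out$object_id %in% hit)
  }
  out$x <- round(out$x, 3); out$y <- round(out$y, 3)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
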