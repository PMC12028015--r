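# Independent oracles used to cross-check package implementations.
# These deliberately use naive algorithms (BFS flood fill, exhaustive
# search, direct summation) and share no code with the package internals.

# 8-connected component labeling by BFS flood fill.
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# component count after the particle rule, from the flood-fill labels
flood_fill_particle_count <- function(probmap, pixel_size_um, p_cut = 0.5,
                                      min_area_um2 = 25) {
  lab <- flood_fill_label(probmap > p_cut)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes * pixel_size_um^2 > min_area_um2)
}

# exhaustive between-class-variance maximization over 256 histogram cuts
brute_force_otsu <- function(channel) {
  v <- as.vector(channel)
  breaks <- seq(0, 1, length.out = 257)
  h <- tabulate(pmin(256L, pmax(1L, findInterval(v, breaks,
                                                 rightmost.closed = TRUE))),
                256L)
  mids <- (breaks[-1] + breaks[-257]) / 2
  bc <- rep(NA_real_, 255)
  for (t in 1:255) {
    w0 <- sum(h[1:t]); w1 <- sum(h[(t + 1):256])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):256] * mids[(t + 1):256]) / w1
    bc[t] <- w0 * w1 * (mu0 - mu1)^2
  }
  # argmax plateau (ties arise from empty bins between modes): midpoint
  top <- which(bc >= max(bc, na.rm = TRUE) * (1 - 1e-12))
  (mids[top[1]] + mids[top[length(top)]]) / 2
}

# direct (loop-based) TPS evaluation, independent of apply_tps
tps_direct_eval <- function(transform, pts) {
  src <- transform$source_landmarks
  out <- matrix(NA_real_, nrow(pts), 2)
  for (p in seq_len(nrow(pts))) {
    for (c_ in 1:2) {
      acc <- transform$affine[1, c_] +
        transform$affine[2, c_] * pts[p, 1] +
        transform$affine[3, c_] * pts[p, 2]
      for (i in seq_len(nrow(src))) {
        r2 <- (pts[p, 1] - src[i, 1])^2 + (pts[p, 2] - src[i, 2])^2
        if (r2 > 0) acc <- acc + transform$kernel_weights[i, c_] * r2 * log(r2)
      }
      out[p, c_] <- acc
    }
  }
  out
}

# random multi-set matching instance: n_true well-separated cluster
# centers, K sets each detecting a cluster with prob `sens` plus jitter,
# and occasional far-away singletons (radius >> jitter regime)
random_match_instance <- function(seed, radius = 10) {
  set.seed(seed)
  K <- sample(2:5, 1)
  n_true <- sample(3:8, 1)
  # centers separated by at least 4 * radius
  centers <- matrix(NA_real_, 0, 2)
  while (nrow(centers) < n_true) {
    cand <- cbind(runif(1, 0, 500), runif(1, 0, 500))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > 4 * radius) {
      centers <- rbind(centers, cand)
    }
  }
  sets <- lapply(seq_len(K), function(k) {
    hit <- runif(n_true) < 0.8
    x <- centers[hit, 1] + rnorm(sum(hit), 0, radius / 6)
    y <- centers[hit, 2] + rnorm(sum(hit), 0, radius / 6)
    if (runif(1) < 0.3) {            # an isolated extra point
      x <- c(x, runif(1, 600, 700)); y <- c(y, runif(1, 600, 700))
    }
    detection_set(x, y, source_id = paste0("s", k))
  })
  list(sets = sets, radius = radius)
}

# small atlas + quiet configs shared across tests
tiny_atlas <- function() build_toy_atlas(c(800, 600), 4)

noiseless_config <- function(pixel_size_um = 2, seed = 1L, ...) {
  simulation_config(pixel_size_um = pixel_size_um, noise_sd = 0,
                    psf_sigma_px = 0, staining_gain_sd = 0, seed = seed, ...)
}
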