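# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: ring means by direct lattice enumeration,
# Spearman via the classical d^2 formula on brute-force ranks, and B3
# convolution by direct summation.

# point-sampled centred isotropic Gaussian on an odd-sided lattice
gauss_image <- function(side, sd_px) {
  half <- (side - 1) / 2
  offs <- seq(-half, half)
  outer(offs, offs, function(a, b) exp(-(a^2 + b^2) / (2 * sd_px^2)))
}

# periphery/centre ratio of f(d) on the lattice, integer-radius binning
oracle_ring_ratio <- function(f, half = 50, ring = c(35, 45), centre_max = 9) {
  offs <- seq(-half, half)
  d <- sqrt(outer(offs^2, offs^2, "+"))
  r <- round(d)
  vals <- f(d)
  ring_means <- tapply(vals, r, mean)
  rr <- as.integer(names(ring_means))
  mean(ring_means[rr >= ring[1] & rr <= ring[2]]) /
    mean(ring_means[rr <= centre_max])
}

# Spearman rho by brute-force ranks (counting) and the d^2 formula;
# valid for tie-free data, which is all the oracle is used for
brute_spearman_rho <- function(x, y) {
  rx <- vapply(x, function(v) sum(x < v) + 1, numeric(1))
  ry <- vapply(y, function(v) sum(y < v) + 1, numeric(1))
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# direct 2-D convolution of an impulse response with the holed B3 kernel
# (mirror boundary ignored: impulse placed centrally, support stays inside)
oracle_b3_smooth_central <- function(img, h) {
  k <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2, -1, 0, 1, 2) * h
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    acc <- 0
    for (a in 1:5) for (b in 1:5) {
      ii <- i + offs[a]; jj <- j + offs[b]
      if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img))
        acc <- acc + k[a] * k[b] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# greedy matching of detections to ground-truth positions
match_detections <- function(spots, truth, tol_px = 3) {
  used <- rep(FALSE, nrow(spots))
  tp <- 0L
  for (j in seq_len(nrow(truth))) {
    if (nrow(spots)) {
      dd <- sqrt((spots$row - truth[j, 1])^2 + (spots$col - truth[j, 2])^2)
      m <- which(!used & dd <= tol_px)
      if (length(m)) {
        tp <- tp + 1L
        used[m[which.min(dd[m])]] <- TRUE
      }
    }
  }
  list(tp = tp, fp = sum(!used), fn = nrow(truth) - tp)
}

# minimal valid synapse_crop for binning/averaging tests
make_crop <- function(arrays, experiment_id = "exp01", field_id = "f01") {
  side <- nrow(arrays[[1]])
  structure(list(arrays = arrays, centre = c((side + 1) %/% 2, (side + 1) %/% 2),
                 side_px = as.integer(side),
                 mean_intensity = vapply(arrays, mean, numeric(1)),
                 valid = TRUE, field_id = field_id,
                 experiment_id = experiment_id),
            class = "synapse_crop")
}
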