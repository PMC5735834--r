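# Independent reference implementations used only to check the package's
# optimized code paths.

# Brute-force voxelwise ORNLM: explicit loop over every voxel and every
# neighbor in the clipped search window, patch distances on the magnitude
# image with Gaussian offset weights and edge-replicated patch reads,
# averaging on the squared image.
ornlm_oracle <- function(vol, search_radius = 5L, patch_radius = 1L,
                         h, sigma, patch_sigma = 1.0) {
  d <- dim(vol)
  u2 <- vol^2
  pr <- patch_radius
  # normalized 1D taps, identical construction to the optimized kernel
  tap <- exp(-0.5 * ((-pr):pr)^2 / patch_sigma^2)
  tap <- tap / sum(tap)
  offs <- expand.grid(ox = (-pr):pr, oy = (-pr):pr, oz = (-pr):pr)
  wp <- tap[offs$ox + pr + 1] * tap[offs$oy + pr + 1] * tap[offs$oz + pr + 1]

  clamp <- function(v, n) pmin(pmax(v, 1L), n)
  # patch-value matrix: one row per voxel, one column per patch offset
  P <- matrix(0, prod(d), nrow(offs))
  lin <- function(x, y, z) (z - 1L) * d[1] * d[2] + (y - 1L) * d[1] + x
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  for (k in seq_len(nrow(offs))) {
    P[, k] <- vol[lin(clamp(grid$x + offs$ox[k], d[1]),
                      clamp(grid$y + offs$oy[k], d[2]),
                      clamp(grid$z + offs$oz[k], d[3]))]
  }

  out <- numeric(prod(d))
  sr <- search_radius
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- max(1L, x - sr):min(d[1], x + sr)
    ys <- max(1L, y - sr):min(d[2], y + sr)
    zs <- max(1L, z - sr):min(d[3], z + sr)
    win <- expand.grid(x = xs, y = ys, z = zs)
    widx <- lin(win$x, win$y, win$z)
    i <- lin(x, y, z)
    d2 <- as.vector((P[widx, , drop = FALSE] -
                       rep(P[i, ], each = length(widx)))^2 %*% wp)
    w <- exp(-d2 / h^2)
    v <- sum(w * u2[widx]) / sum(w) - 2 * sigma^2
    out[i] <- if (v > 0) sqrt(v) else 0
  }
  array(out, d)
}

# Reference TV denoiser: scikit-image's denoise_tv_chambolle run out of
# process (volume exchanged as plain text).
tv_reference <- function(vol, weight, max_iter = 2000L, eps = 1e-12) {
  d <- dim(vol)
  infile <- tempfile(fileext = ".txt")
  outfile <- tempfile(fileext = ".txt")
  writeLines(format(c(d, as.vector(vol)), digits = 17), infile)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage.restoration import denoise_tv_chambolle\n",
    "v = np.loadtxt('%s'); d = v[:3].astype(int); a = v[3:].reshape(d, order='F')\n",
    "out = denoise_tv_chambolle(a, weight=%.17g, eps=%.17g, max_num_iter=%d)\n",
    "np.savetxt('%s', out.flatten(order='F'))\n"),
    infile, weight, eps, max_iter, outfile)
  status <- system2("python", "-", input = script,
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("reference TV run failed")
  array(scan(outfile, quiet = TRUE), d)
}

has_python_skimage <- function() {
  isTRUE(system2("python", c("-c", shQuote("import skimage")),
                 stdout = FALSE, stderr = FALSE) == 0L)
}

# spreadsheet-style recomputation of paired difference summaries
paired_differences_oracle <- function(ref, oth) {
  d <- ref - oth
  rel <- 100 * d / ((ref + oth) / 2)
  m <- function(v) sum(v) / length(v)
  s <- function(v) sqrt(sum((v - m(v))^2) / (length(v) - 1))
  list(mean_diff = m(d), sd_diff = s(d), mean_rel_pct = m(rel),
       sd_rel_pct = s(rel))
}

pearson_oracle <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
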