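# Shared fixtures: small phantoms and random masks, built in code.

fast_phantom <- function(seed = 1, noise_sd = 0.02, deformation = 3, ...) {
  generate_phantom(phantom_spec(seed = seed, noise_sd = noise_sd,
                                deformation_amplitude = deformation, ...),
                   subject_id = paste0("S", seed))
}

# a random logical mask on a small grid
random_mask <- function(n = 12, p = 0.2) {
  array(runif(n^3) < p, dim = c(n, n, n))
}

# brute-force Dice on logical arrays
dice_oracle <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# brute-force Hausdorff over boundary voxel centres (mm)
hausdorff_oracle <- function(a, b, spacing = c(1, 1, 1)) {
  bnd <- function(m) {
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      nb <- FALSE
      for (dd in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + dd[1]; jj <- j + dd[2]; kk <- k + dd[3]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3] ||
            !m[ii, jj, kk]) { nb <- TRUE; break }
      }
      keep[r] <- nb
    }
    sweep(idx[keep, , drop = FALSE] - 1, 2, spacing, `*`)
  }
  pa <- bnd(a); pb <- bnd(b)
  dmat <- as.matrix(dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                         nrow(pa) + seq_len(nrow(pb)),
                                         drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}
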