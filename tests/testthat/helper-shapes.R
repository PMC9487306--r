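# Shape builders and independent oracles shared across tests.

PX <- 0.5  # BEV pixel size used by the direct mask builders

# disk mask built directly on the canonical centered grid
disk_mask <- function(r, cu = 0, cv = 0, n = 400, px = PX) {
  uc <- (seq_len(n) - n / 2 - 0.5) * px
  m <- outer(uc, uc, function(u, v) (u - cu)^2 + (v - cv)^2 <= r^2)
  bev_mask(m, px)
}

# axis-aligned rectangle mask (edges on pixel-grid multiples of px)
rect_mask <- function(w, h, n = 400, px = PX) {
  uc <- (seq_len(n) - n / 2 - 0.5) * px
  m <- matrix(FALSE, n, n)
  m[abs(uc) < w / 2, abs(uc) < h / 2] <- TRUE
  bev_mask(m, px)
}

union_masks <- function(a, b) bev_mask(a$pixels | b$pixels, a$pixel_spacing)

# brute-force per-band pixel-scan aperture area (cm^2): independent of
# fit_aperture's snapping code path
oracle_amlc <- function(bev, mlc = mlc_model()) {
  idx <- which(bev$pixels, arr.ind = TRUE)
  uu <- bev$u_centers[idx[, 1]]
  vv <- bev$v_centers[idx[, 2]]
  band <- findInterval(vv, mlc$edges)
  px <- bev$pixel_spacing
  tot <- 0
  for (b in unique(band)) {
    u <- uu[band == b]
    tot <- tot + (max(u) - min(u) + px) * mlc$leaf_widths[b]
  }
  tot / 100
}

mci_of <- function(bev, ...) compute_mci(bev, fit_aperture(bev, ...))$mci

# circular distance between angles on the 180-degree collimator circle
theta_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# seeded random heatmap for segmentation tests
random_heatmap <- function(seed, n_min = 20, n_max = 40) {
  withr::with_seed(seed, {
    n <- sample(n_min:n_max, 1)
    nT <- sample(6:12, 1)
    M <- matrix(runif(n * nT, 0.3, 0.95), n, nT)
    gant <- (179 - 2 * (seq_len(n) - 1)) %% 360
    as_mci_heatmap(M, gant, seq(0, 170, length.out = nT))
  })
}
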