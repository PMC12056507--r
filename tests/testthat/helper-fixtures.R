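# Shared fixtures and independent oracles, all built in code.

# rasterized disk of radius r centered in an n x n frame
disk_mask <- function(r, n = 2 * r + 11, center = c((n + 1) / 2,
                                                    (n + 1) / 2)) {
  outer(seq_len(n), seq_len(n), function(i, j)
    sqrt((i - center[1])^2 + (j - center[2])^2) <= r)
}

# random blobby mask: thresholded smoothed noise (may have several
# components or none)
random_mask <- function(h, w, density = 0.35) {
  m <- matrix(runif(h * w) < density, h, w)
  m
}

# brute-force 8-connected flood fill, independent of the C++ labelling
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  k <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    k <- k + 1L
    frontier <- cbind(r0, c0)
    lab[r0, c0] <- k
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        for (dr in -1:1) for (dc in -1:1) {
          rr <- frontier[i, 1] + dr; cc <- frontier[i, 2] + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- k
            nxt <- rbind(nxt, c(rr, cc))
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(0, 0, 2) else nxt
    }
  }
  areas <- if (k > 0) as.integer(tabulate(lab[lab > 0], k)) else integer(0)
  list(labels = lab, areas = areas, k = k)
}

# set-arithmetic metric oracle working on explicit coordinate sets
oracle_overlap <- function(p, t) {
  sp <- which(p); st <- which(t)
  c(intersection = length(intersect(sp, st)),
    union = length(union(sp, st)))
}

oracle_jcd <- function(p, t) {
  ov <- oracle_overlap(p, t)
  1 - ov[["intersection"]] / ov[["union"]]
}

oracle_delta_r <- function(p, t) {
  ov <- oracle_overlap(p, t)
  mism <- ov[["union"]] - ov[["intersection"]]
  dt <- 2 * sqrt(length(which(t)) / pi)
  sqrt(mism / pi + dt^2 / 4) - dt / 2
}

# two-blob fixture: 12 px and 7 px, separated
two_blob_mask <- function() {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:5] <- TRUE    # 12 px, first in raster order
  m[8:10, 8:9] <- TRUE   # 6 px
  m[10, 10] <- TRUE      # joins to 7 px
  m
}

# small clean / debris-laden synthetic configs shared by tests
# diameter range scales with the frame so the spheroid always fits
clean_cfg <- function(seed = 11, n = 64)
  synth_config(image_size = c(n, n),
               spheroid_diameter_range = c(0.45, 0.68) * n * 2.04,
               debris_extent_factor = 0, debris_opacity = 0,
               double_spheroid_prob = 0, seed = seed)

debris_cfg <- function(seed = 0, opacity = 0.5, extent = 1.8, n = 128)
  synth_config(image_size = c(n, n),
               spheroid_diameter_range = c(100, 200),
               debris_extent_factor = extent, debris_opacity = opacity,
               double_spheroid_prob = 0, seed = seed)

make_samples <- function(cfg, n, offset = 0, prefix = "S")
  lapply(seq_len(n), function(i)
    generate_sample(cfg, offset + i,
                    spheroid_id = sprintf("%s%03d", prefix, i)))
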