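# Seeded generator of synthetic brightfield-like spheroid images with
# ground-truth masks.  It emulates the phenomenology of treated
# spheroids: a dark compact body with center darkening and an irregular
# rim, surrounded by a grainy cloud of dead-cell debris that can extend
# well beyond the spheroid and be locally darker than it, on a bright
# background with an illumination ramp and Gaussian noise confined to a
# narrow band of the 16-bit range.

#' Configuration of the synthetic spheroid generator
#'
#' Defaults emulate a typical brightfield acquisition: 1300 x 1030 px
#' frames at 2.04 um/px, background gray level 1300 +/- 130 in 16-bit
#' units (a narrow band of the dynamic range), spheroid diameters of
#' 200-1000 um.
#'
#' @param image_size c(rows, cols) in px.
#' @param pixel_size um/px.
#' @param spheroid_diameter_range c(min, max) true mean diameter in um.
#' @param boundary_irregularity dimensionless amplitude of the radial
#'   rim perturbation (0 = perfect disk).
#' @param debris_extent_factor debris-cloud radius as a multiple of the
#'   spheroid radius (0 = no debris).
#' @param debris_opacity peak attenuation of debris patches in [0, 1];
#'   above ~0.6 the darkest debris patches are darker than the spheroid
#'   rim.
#' @param debris_graininess correlation length of the debris texture in
#'   px.
#' @param double_spheroid_prob probability of a second, touching
#'   spheroid (included in the target mask).
#' @param background_level mean background intensity, 16-bit units.
#' @param background_sd Gaussian noise standard deviation, 16-bit units.
#' @param illumination_gradient maximum relative intensity slope across
#'   the frame.
#' @param growth_factor_range per-time-step diameter multiplier range
#'   used by [generate_dataset()] time series.
#' @param n_raters number of synthetic rater masks per sample (boundary
#'   jitter around the ground truth).
#' @param rater_jitter_px radial jitter amplitude of rater masks, px.
#' @param seed integer master seed; each sample derives its own stream
#'   from (seed, index).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(image_size = c(1030, 1300),
                         pixel_size = 2.04,
                         spheroid_diameter_range = c(200, 1000),
                         boundary_irregularity = 0.06,
                         debris_extent_factor = 2.0,
                         debris_opacity = 0.6,
                         debris_graininess = 8,
                         double_spheroid_prob = 0.05,
                         background_level = 1300,
                         background_sd = 130,
                         illumination_gradient = 0.05,
                         growth_factor_range = c(1.0, 1.08),
                         n_raters = 0,
                         rater_jitter_px = 3,
                         seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            pixel_size > 0,
            length(spheroid_diameter_range) == 2,
            all(spheroid_diameter_range > 0),
            diff(spheroid_diameter_range) >= 0,
            debris_extent_factor >= 0,
            debris_opacity >= 0, debris_opacity <= 1,
            double_spheroid_prob >= 0, double_spheroid_prob <= 1,
            background_level > 0, background_sd >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# Smooth periodic radial perturbation, RMS-normalized to 1.
fourier_field <- function(theta, harmonics = 2:5) {
  a <- rnorm(length(harmonics)); b <- rnorm(length(harmonics))
  f <- rep(0, length(theta))
  for (i in seq_along(harmonics))
    f <- f + a[i] * cos(harmonics[i] * theta) +
             b[i] * sin(harmonics[i] * theta)
  nrm <- sqrt(sum(a^2 + b^2) / 2)
  if (nrm < 1e-12) rep(0, length(theta)) else f / nrm
}

# Render one spheroid body: star-shaped mask {rho <= r(theta)} with an
# area-preserving rim perturbation, plus radial position for shading.
render_spheroid <- function(rr, cc, center, r_px, irregularity) {
  dr <- rr - center[1]; dc <- cc - center[2]
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  h <- 2:5
  a <- rnorm(length(h)); b <- rnorm(length(h))
  nrm <- sqrt(sum(a^2 + b^2) / 2)
  if (nrm < 1e-12) nrm <- 1
  a <- a / nrm; b <- b / nrm
  shape <- function(tt) {
    f <- rep(0, length(tt))
    for (i in seq_along(h))
      f <- f + a[i] * cos(h[i] * tt) + b[i] * sin(h[i] * tt)
    1 + pmax(pmin(irregularity * f, 0.6), -0.6)
  }
  # area-preserving normalization: mean of r(theta)^2 equals r_px^2
  tt <- seq(0, 2 * pi, length.out = 721)[-721]
  scale <- 1 / sqrt(mean(shape(tt)^2))
  rb <- r_px * scale * shape(theta)
  mask <- rho <= rb
  # relative radial position in [0,1] inside the body
  rel <- ifelse(mask, pmin(rho / pmax(rb, 1e-9), 1), 1)
  list(mask = mask, rel = rel, boundary = rb, rho = rho)
}

#' Generate one synthetic spheroid image with ground truth
#'
#' Deterministic for a fixed (config seed, index) pair.  The target
#' mask covers the spheroid body only; debris is rendered in the image
#' but never part of the target.
#'
#' @param config a [synth_config()].
#' @param index sample index (>= 1); selects the per-sample random
#'   stream.
#' @param diameter_um optional fixed true diameter (drawn from the
#'   configured range when `NULL`).
#' @param spheroid_id identifier stored with the sample.
#' @return Object of class `synth_sample`: list with `image`
#'   (16-bit `gray_image`), `target` (logical mask), `spheroid_id`,
#'   `rater_masks` (list, possibly empty) and `metadata`.
#' @export
generate_sample <- function(config, index = 1, diameter_um = NULL,
                            spheroid_id = sprintf("S%04d", index)) {
  stopifnot(inherits(config, "synth_config"))
  s <- derive_seed(config$seed, index)
  with_seed(s, {
    H <- config$image_size[1]; W <- config$image_size[2]
    px <- config$pixel_size
    drng <- config$spheroid_diameter_range
    # keep one pixel of rasterization margin inside the configured range
    lo <- min(drng[1] + px, mean(drng)); hi <- max(drng[2] - px, mean(drng))
    d_um <- if (is.null(diameter_um)) runif(1, lo, hi) else diameter_um
    r_px <- d_um / (2 * px)
    if (2 * r_px * (1 + config$boundary_irregularity) >= min(H, W))
      stop("spheroid diameter exceeds the frame")
    lim <- function(n) min(n * 0.05, n / 2 - r_px * 1.05 - 1)
    center <- c(H / 2 + runif(1, -1, 1) * max(lim(H), 0),
                W / 2 + runif(1, -1, 1) * max(lim(W), 0))
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)

    body <- render_spheroid(rr, cc, center, r_px,
                            config$boundary_irregularity)
    target <- body$mask
    double <- runif(1) < config$double_spheroid_prob
    if (double) {
      ang <- runif(1, 0, 2 * pi)
      r2 <- r_px * runif(1, 0.5, 0.8)
      ctr2 <- center + 0.95 * (r_px + r2) * c(cos(ang), sin(ang))
      ctr2 <- pmin(pmax(ctr2, r2 + 2), c(H, W) - r2 - 2)
      body2 <- render_spheroid(rr, cc, ctr2, r2,
                               config$boundary_irregularity)
      target <- target | body2$mask
    }

    # background with linear illumination ramp
    gdir <- runif(1, 0, 2 * pi)
    ramp <- ((rr - H / 2) / H) * cos(gdir) + ((cc - W / 2) / W) * sin(gdir)
    base <- config$background_level *
      (1 + config$illumination_gradient * ramp)

    # spheroid attenuation: darker towards the center (thickness proxy)
    att <- matrix(0, H, W)
    rim <- 0.30; core <- 0.55
    att[body$mask] <- rim + (core - rim) * (1 - body$rel[body$mask]^2)
    if (double)
      att[body2$mask] <- pmax(att[body2$mask],
                              rim + (core - rim) *
                                (1 - body2$rel[body2$mask]^2))

    # debris: grainy annular cloud, patches can be darker than the rim
    debris_r <- config$debris_extent_factor * r_px
    if (config$debris_extent_factor > 0 && config$debris_opacity > 0) {
      tex <- matrix(rnorm(H * W), H, W)
      tex <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(tex),
                       sigma = max(config$debris_graininess / 2, 0.5)))
      tex <- matrix(tex, H, W)
      tex <- (tex - min(tex)) / max(max(tex) - min(tex), 1e-12)
      taper <- pmax(1 - pmax(body$rho - body$boundary, 0) /
                      pmax(debris_r - body$boundary, 1e-9), 0)
      cloud <- !target & body$rho <= debris_r
      datt <- config$debris_opacity * tex^1.5 * taper
      att[cloud] <- pmax(att[cloud], datt[cloud])
    }

    img <- base * (1 - att) + rnorm(H * W, sd = config$background_sd)
    img <- matrix(pmin(pmax(round_half_up(img), 0), 65535), H, W)

    raters <- list()
    if (config$n_raters > 0)
      raters <- lapply(seq_len(config$n_raters), function(k)
        perturb_as_rater(target, config$rater_jitter_px,
                         seed = derive_seed(s, 1000 + k)))

    structure(list(
      image = gray_image(img, bit_depth = 16, pixel_size = px),
      target = target,
      spheroid_id = spheroid_id,
      rater_masks = raters,
      metadata = list(diameter_um = d_um, radius_px = r_px,
                      center = center, debris_radius_px = debris_r,
                      double_spheroid = double, seed = s, index = index)),
      class = "synth_sample")
  })
}

#' Generate a dataset of synthetic spheroid time series
#'
#' `n` spheroid IDs with `images_per_spheroid` images each; images of
#' one ID share the underlying spheroid (its diameter grows by a
#' per-step factor drawn from `growth_factor_range`), emulating an
#' imaging time series so that split hygiene can be exercised.
#'
#' @param config a [synth_config()].
#' @param n number of spheroids (>= 1).
#' @param images_per_spheroid images per spheroid.
#' @return List with `samples` (length `n * images_per_spheroid`) and
#'   `manifest` (data.frame image, mask, spheroid_id).
#' @export
generate_dataset <- function(config, n, images_per_spheroid = 1) {
  stopifnot(n >= 1, images_per_spheroid >= 1)
  samples <- vector("list", n * images_per_spheroid)
  rows <- vector("list", n * images_per_spheroid)
  idx <- 0L
  for (i in seq_len(n)) {
    id <- sprintf("S%04d", i)
    base_seed <- derive_seed(config$seed, i)
    d0 <- with_seed(base_seed, {
      drng <- config$spheroid_diameter_range
      px <- config$pixel_size
      gmax <- max(config$growth_factor_range)^(images_per_spheroid - 1)
      runif(1, min(drng[1] + px, mean(drng)),
            max((drng[2] - px) / gmax, mean(drng) / gmax))
    })
    d <- d0
    for (j in seq_len(images_per_spheroid)) {
      idx <- idx + 1L
      samples[[idx]] <- generate_sample(config,
                                        index = (i - 1L) * 10000L + j,
                                        diameter_um = d, spheroid_id = id)
      rows[[idx]] <- data.frame(
        image = sprintf("%s_t%02d.tiff", id, j),
        mask = sprintf("%s_t%02d_mask.png", id, j),
        spheroid_id = id, stringsAsFactors = FALSE)
      d <- d * with_seed(derive_seed(base_seed, j),
                         runif(1, config$growth_factor_range[1],
                               config$growth_factor_range[2]))
    }
  }
  list(samples = samples, manifest = do.call(rbind, rows))
}

#' Perturb a ground-truth mask like an independent human rater
#'
#' Displaces the mask boundary by a smooth random radial field of the
#' given amplitude (signed-distance level-set shift), emulating
#' interobserver boundary jitter.  Amplitude 0 returns the target
#' unchanged; the output is always a non-empty single component
#' overlapping the target.
#'
#' @param target non-empty logical mask.
#' @param jitter_amplitude RMS boundary displacement in px.
#' @param seed integer seed.
#' @return logical mask.
#' @export
perturb_as_rater <- function(target, jitter_amplitude, seed = 1) {
  target <- as_mask(target)
  if (!any(target)) stop("target mask is empty")
  if (jitter_amplitude == 0) return(target)
  with_seed(seed, {
    di <- matrix(EBImage::imageData(EBImage::distmap(
      EBImage::Image(target * 1.0))), nrow(target))
    do <- matrix(EBImage::imageData(EBImage::distmap(
      EBImage::Image((!target) * 1.0))), nrow(target))
    signed <- di - do  # > 0 inside, < 0 outside
    idx <- which(target, arr.ind = TRUE)
    ctr <- colMeans(idx)
    theta <- atan2(col(target) - ctr[2], row(target) - ctr[1])
    delta <- jitter_amplitude * fourier_field(as.vector(theta),
                                              harmonics = 1:4)
    # never carve deeper than most of the mask's inradius
    delta <- pmax(delta, -0.8 * max(di))
    out <- matrix(signed + delta > 0, nrow(target))
    out <- out & (do <= max(2 * jitter_amplitude, 2) | target)
    lc <- largest_component(out)
    if (!any(lc$mask)) target else lc$mask
  })
}
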