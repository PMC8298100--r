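# Synthetic-data generators.
#
# Every input the pipeline consumes can be generated here with the statistical
# structure the analyses assume: movies of diffusing diffraction-limited
# puncta, mitochondrial network vs aggregated-blob masks, persistent random
# walk migration tracks with per-experiment effects, perturbed-ellipse cell
# contours with controllable mirror asymmetry, and vesicle-capture screen
# tables with planted corerouting effect sizes. All generators take an
# explicit `seed` and are bit-reproducible for a fixed seed.

#' Simulate a movie of diffusing sub-resolution puncta
#'
#' Renders `n_puncta` isotropic Gaussian spots (the PSF image of point-like
#' vesicles) on a constant background with Gaussian read noise. Motile puncta
#' perform a Brownian walk with per-axis step SD `sqrt(2 * D * dt)`; positions
#' wrap periodically so punctum density stays constant over the movie.
#' Gaussians are evaluated directly on the pixel grid (no sub-pixel
#' integration), which is adequate for variance scoring.
#'
#' @param n_puncta Number of puncta.
#' @param diffusion_coeff Diffusion coefficient D in um^2/s.
#' @param psf_sigma Gaussian PSF sigma in um.
#' @param punctum_amplitude Peak amplitude of one punctum (a.u.).
#' @param background Constant background intensity (a.u.).
#' @param noise_sd SD of additive Gaussian read noise (a.u.).
#' @param frames Number of frames (>= 2).
#' @param frame_interval Seconds per frame. Default 0.3 s (300-ms exposure
#'   protocol); Rab-type movies use 0.1775 s.
#' @param pixel_size um per pixel.
#' @param field_size `c(height, width)` in pixels.
#' @param motile If `FALSE`, puncta are frozen in place.
#' @param seed Integer seed.
#' @return A [frame_stack()].
#' @examples
#' mov <- simulate_vesicle_movie(n_puncta = 5, frames = 4, field_size = c(32, 32),
#'                               seed = 1)
#' dim(mov)
#' @export
simulate_vesicle_movie <- function(n_puncta = 40, diffusion_coeff = 0.5,
                                   psf_sigma = 0.15, punctum_amplitude = 150,
                                   background = 100, noise_sd = 5,
                                   frames = 30, frame_interval = 0.3,
                                   pixel_size = 0.1, field_size = c(128, 128),
                                   motile = TRUE, seed = NULL) {
  check_number(n_puncta, "n_puncta", 0, integer = TRUE)
  check_number(diffusion_coeff, "diffusion_coeff", 0)
  check_number(psf_sigma, "psf_sigma", 0, strict = TRUE)
  check_number(punctum_amplitude, "punctum_amplitude", 0)
  check_number(background, "background", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(frames, "frames", 2, integer = TRUE)
  check_number(frame_interval, "frame_interval", 0, strict = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_flag(motile, "motile")
  if (length(field_size) != 2L || any(field_size < 1)) {
    stop("`field_size` must be two positive pixel counts", call. = FALSE)
  }
  h <- as.integer(field_size[1L]); w <- as.integer(field_size[2L])

  with_seed(seed, {
    sigma_px <- psf_sigma / pixel_size
    step_sd_px <- sqrt(2 * diffusion_coeff * frame_interval) / pixel_size
    # positions in pixel units on [0, h) x [0, w)
    py <- runif(n_puncta, 0, h)
    px <- runif(n_puncta, 0, w)
    half <- ceiling(4 * sigma_px)
    out <- array(background, dim = c(h, w, frames))
    for (t in seq_len(frames)) {
      if (motile && t > 1L && n_puncta > 0L) {
        py <- (py + rnorm(n_puncta, 0, step_sd_px)) %% h
        px <- (px + rnorm(n_puncta, 0, step_sd_px)) %% w
      }
      if (n_puncta > 0L) {
        frame <- matrix(0, h, w)
        for (p in seq_len(n_puncta)) {
          rows <- (floor(py[p]) - half):(floor(py[p]) + half)
          cols <- (floor(px[p]) - half):(floor(px[p]) + half)
          gy <- exp(-(rows - py[p])^2 / (2 * sigma_px^2))
          gx <- exp(-(cols - px[p])^2 / (2 * sigma_px^2))
          ri <- (rows %% h) + 1L
          ci <- (cols %% w) + 1L
          frame[ri, ci] <- frame[ri, ci] + punctum_amplitude * outer(gy, gx)
        }
        out[, , t] <- out[, , t] + frame
      }
      if (noise_sd > 0) {
        out[, , t] <- out[, , t] + rnorm(h * w, 0, noise_sd)
      }
    }
    frame_stack(out, frame_interval = frame_interval, pixel_size = pixel_size)
  })
}

#' Simulate mitochondrial morphology masks
#'
#' `"network"` mode draws thin curvilinear strokes (elongated objects with low
#' circularity, emulating a tubular mitochondrial network); `"aggregated"`
#' mode draws near-circular blobs (the collapsed morphology after vesicle
#' capture). Objects are placed without contact so the ground truth is
#' unambiguous.
#'
#' @param mode `"network"` or `"aggregated"`.
#' @param n_objects Number of objects to place (>= 1).
#' @param pixel_size um per pixel.
#' @param field_size `c(height, width)` in pixels.
#' @param seed Integer seed.
#' @return A list with `mask` (logical matrix), `objects` (data frame with the
#'   analytic `area_um2` of each object as drawn), and `pixel_size`.
#' @examples
#' f <- simulate_mito_masks("aggregated", n_objects = 3, seed = 1)
#' sum(f$mask)
#' @export
simulate_mito_masks <- function(mode = c("network", "aggregated"), n_objects = 12,
                                pixel_size = 0.05, field_size = c(256, 256),
                                seed = NULL) {
  mode <- match.arg(mode)
  check_number(n_objects, "n_objects", 1, integer = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  h <- as.integer(field_size[1L]); w <- as.integer(field_size[2L])

  with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    occupied <- matrix(FALSE, h, w)  # mask dilated by a safety margin
    objects <- vector("list", n_objects)

    stamp_disc <- function(cy, cx, r, target) {
      rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
      cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
      d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
      target[rows, cols] <- target[rows, cols] | (d2 <= r^2)
      target
    }

    placed <- 0L
    attempts <- 0L
    while (placed < n_objects) {
      attempts <- attempts + 1L
      if (attempts > 200L * n_objects) {
        stop("could not place all objects without contact; reduce `n_objects`",
             call. = FALSE)
      }
      if (mode == "aggregated") {
        r <- runif(1, 4, 9)
        cy <- runif(1, r + 2, h - r - 2); cx <- runif(1, r + 2, w - r - 2)
        cand <- stamp_disc(cy, cx, r, matrix(FALSE, h, w))
        guard <- stamp_disc(cy, cx, r + 3, matrix(FALSE, h, w))
        area_um2 <- pi * r^2 * pixel_size^2
      } else {
        # curvilinear stroke: a gently turning path thickened to `width` px
        width <- 3
        len <- runif(1, 8 * width * 2, 12 * width * 2)  # aspect >= 8:1 pre-thickening
        theta <- runif(1, 0, 2 * pi)
        n_steps <- ceiling(len)
        turns <- rnorm(n_steps, 0, 0.06)
        ang <- theta + cumsum(turns)
        ys <- runif(1, width + 6, h - width - 6) + c(0, cumsum(sin(ang)))
        xs <- runif(1, width + 6, w - width - 6) + c(0, cumsum(cos(ang)))
        if (any(ys < width + 2) || any(ys > h - width - 2) ||
            any(xs < width + 2) || any(xs > w - width - 2)) next
        cand <- matrix(FALSE, h, w)
        guard <- matrix(FALSE, h, w)
        for (i in seq_along(ys)) {
          cand <- stamp_disc(ys[i], xs[i], width / 2, cand)
          guard <- stamp_disc(ys[i], xs[i], width / 2 + 3, guard)
        }
        area_um2 <- len * width * pixel_size^2
      }
      if (any(guard & mask) || any(cand & occupied)) next
      mask <- mask | cand
      occupied <- occupied | guard
      placed <- placed + 1L
      objects[[placed]] <- data.frame(label = placed, mode = mode,
                                      area_um2 = area_um2)
    }
    list(mask = mask, objects = do.call(rbind, objects), pixel_size = pixel_size)
  })
}

#' Simulate persistent random walk migration tracks
#'
#' Each cell's heading performs angular diffusion with correlation time
#' `persistence_time` (so the direction autocorrelation decays as
#' `exp(-lag / persistence_time)`), at a per-cell base speed drawn around its
#' experiment's mean. Positions are reported every `frame_interval` with
#' optional positional (tracking) noise.
#'
#' @param n_cells Cells per experiment.
#' @param n_experiments Number of experimental repeats.
#' @param mean_speed Population mean speed, um/min. Default 0.4 um/min
#'   (typical epithelial 2D migration).
#' @param speed_sd_between_cells Between-cell speed SD, um/min.
#' @param experiment_effect_sd SD of the per-experiment speed offset, um/min.
#' @param persistence_time Direction correlation time, min (may be `Inf`).
#' @param frame_interval Minutes between positions. Default 10 min.
#' @param duration Track duration in minutes.
#' @param positional_noise_sd SD of additive positional noise, um.
#' @param condition Condition label attached to every track.
#' @param seed Integer seed.
#' @return A tidy data frame with columns `cell_id`, `experiment_id`,
#'   `condition`, `t`, `x`, `y` (minutes and um).
#' @examples
#' tr <- simulate_tracks(n_cells = 3, duration = 60, seed = 1)
#' head(tr)
#' @export
simulate_tracks <- function(n_cells = 50, n_experiments = 1, mean_speed = 0.4,
                            speed_sd_between_cells = 0.08,
                            experiment_effect_sd = 0, persistence_time = 40,
                            frame_interval = 10, duration = 600,
                            positional_noise_sd = 0, condition = "sim",
                            seed = NULL) {
  check_number(n_cells, "n_cells", 1, integer = TRUE)
  check_number(n_experiments, "n_experiments", 1, integer = TRUE)
  check_number(mean_speed, "mean_speed", 0)
  check_number(speed_sd_between_cells, "speed_sd_between_cells", 0)
  check_number(experiment_effect_sd, "experiment_effect_sd", 0)
  if (!identical(persistence_time, Inf)) {
    check_number(persistence_time, "persistence_time", 0, strict = TRUE)
  }
  check_number(frame_interval, "frame_interval", 0, strict = TRUE)
  check_number(duration, "duration", 0, strict = TRUE)
  check_number(positional_noise_sd, "positional_noise_sd", 0)
  n_steps <- floor(duration / frame_interval)
  if (n_steps < 2) stop("`duration`/`frame_interval` must allow >= 2 steps", call. = FALSE)

  with_seed(seed, {
    heading_sd <- if (is.infinite(persistence_time)) 0 else
      sqrt(2 * frame_interval / persistence_time)
    out <- vector("list", n_experiments * n_cells)
    k <- 0L
    for (e in seq_len(n_experiments)) {
      exp_effect <- if (experiment_effect_sd > 0) rnorm(1, 0, experiment_effect_sd) else 0
      for (c in seq_len(n_cells)) {
        k <- k + 1L
        v <- max(mean_speed + exp_effect + rnorm(1, 0, speed_sd_between_cells), 0)
        phi0 <- runif(1, 0, 2 * pi)
        # heading during step i takes the walker from position i to i+1
        phi <- phi0 + c(0, cumsum(rnorm(n_steps - 1L, 0, heading_sd)))
        dx <- v * frame_interval * cos(phi)
        dy <- v * frame_interval * sin(phi)
        x <- c(0, cumsum(dx))
        y <- c(0, cumsum(dy))
        if (positional_noise_sd > 0) {
          x <- x + rnorm(length(x), 0, positional_noise_sd)
          y <- y + rnorm(length(y), 0, positional_noise_sd)
        }
        out[[k]] <- data.frame(
          cell_id = sprintf("e%d_c%03d", e, c),
          experiment_id = sprintf("e%d", e),
          condition = condition,
          t = seq(0, by = frame_interval, length.out = n_steps + 1L),
          x = x, y = y)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "frame_interval") <- frame_interval
    res
  })
}

#' Simulate a cell outline contour
#'
#' The contour is a perturbed ellipse: the radius function is the ellipse
#' radius times `1 + sum of low-order Fourier perturbations`. Cosine orders
#' preserve mirror symmetry about the major (x) axis; sine orders break it,
#' and their amplitude is scaled by `asymmetry`, so `asymmetry = 0` yields an
#' exactly mirror-symmetric outline and larger values depart monotonically
#' from symmetry on matched seeds. Self-intersecting draws are retried with
#' damped perturbations.
#'
#' @param base_major,base_minor Full axis lengths of the base ellipse, um.
#' @param n_vertices Number of polygon vertices (>= 8).
#' @param fourier_orders Number of perturbation orders (k = 2, 3, ...).
#' @param perturbation_amplitude Typical relative radius perturbation.
#' @param asymmetry In `[0, 1]`; scales the mirror-breaking sine terms.
#' @param cell_id,experiment_id,condition Labels attached to the contour.
#' @param seed Integer seed.
#' @param max_retries Retries with damped perturbation before failing.
#' @return A [cell_contour()].
#' @examples
#' ct <- simulate_contour(seed = 1)
#' shape_descriptors(ct)$aspect_ratio
#' @export
simulate_contour <- function(base_major = 40, base_minor = 25, n_vertices = 180,
                             fourier_orders = 4, perturbation_amplitude = 0.06,
                             asymmetry = 0, cell_id = NA, experiment_id = NA,
                             condition = NA, seed = NULL, max_retries = 5) {
  check_number(base_minor, "base_minor", 0, strict = TRUE)
  check_number(base_major, "base_major", base_minor)
  check_number(n_vertices, "n_vertices", 8, integer = TRUE)
  check_number(fourier_orders, "fourier_orders", 0, integer = TRUE)
  check_number(perturbation_amplitude, "perturbation_amplitude", 0)
  check_number(asymmetry, "asymmetry", 0)
  if (asymmetry > 1) stop("`asymmetry` must be in [0, 1]", call. = FALSE)

  with_seed(seed, {
    a <- base_major / 2; b <- base_minor / 2
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    orders <- if (fourier_orders > 0) seq(2L, length.out = fourier_orders) else integer(0)
    ac <- if (length(orders)) rnorm(length(orders), 0, perturbation_amplitude / orders) else numeric(0)
    bs <- if (length(orders)) rnorm(length(orders), 0, perturbation_amplitude / orders) else numeric(0)
    damp <- 1
    for (try in seq_len(max_retries + 1L)) {
      pert <- rep(0, n_vertices)
      for (i in seq_along(orders)) {
        pert <- pert + damp * (ac[i] * cos(orders[i] * theta) +
                               asymmetry * bs[i] * sin(orders[i] * theta))
      }
      r <- r_ell * (1 + pert)
      if (all(r > 0)) {
        ct <- try(cell_contour(r * cos(theta), r * sin(theta), cell_id = cell_id,
                               experiment_id = experiment_id, condition = condition),
                  silent = TRUE)
        if (!inherits(ct, "try-error")) return(ct)
      }
      damp <- damp * 0.6
    }
    stop("failed to generate a simple contour after retries; reduce ",
         "`perturbation_amplitude`", call. = FALSE)
  })
}

#' Simulate a vesicle-capture screen measurement table
#'
#' Per-cell pre-rapamycin mitochondrial intensities `F_pre` are drawn around a
#' baseline; `F_post = F_pre * (true_ratio + noise)`. The table is keyed by
#' construct, Rab and cell id and feeds [build_screen_matrix()],
#' [dunnett_vs_control()] and [bootstrap_bca_diff()].
#'
#' @param constructs Character vector of construct labels.
#' @param rabs Character vector of Rab labels; include the fluorophore control
#'   (e.g. `"GFP"`).
#' @param true_ratio Expected `F_post / F_pre` per (rab, construct): a single
#'   number, or a matrix with `rabs` rows and `constructs` columns
#'   (dimnames honored when present).
#' @param cell_noise_sd Per-cell SD of the realized ratio.
#' @param n_cells_per_condition Cells per (construct, rab) pair (>= 3).
#' @param baseline,baseline_sd Mean and SD of `F_pre` (a.u.).
#' @param seed Integer seed.
#' @return A data frame with columns `construct`, `rab`, `cell_id`, `F_pre`,
#'   `F_post`.
#' @examples
#' tab <- simulate_screen(rabs = c("GFP", "Rab30"), true_ratio = 1, seed = 1)
#' head(tab)
#' @export
simulate_screen <- function(constructs = c("TPD52", "TPD53", "TPD54"),
                            rabs = c("GFP", "Rab30", "Rab25", "Rab11a"),
                            true_ratio = 1, cell_noise_sd = 0.3,
                            n_cells_per_condition = 20, baseline = 100,
                            baseline_sd = 10, seed = NULL) {
  check_number(cell_noise_sd, "cell_noise_sd", 0)
  check_number(n_cells_per_condition, "n_cells_per_condition", 3, integer = TRUE)
  check_number(baseline, "baseline", 0, strict = TRUE)
  check_number(baseline_sd, "baseline_sd", 0)
  if (is.matrix(true_ratio)) {
    if (!is.null(rownames(true_ratio)) && !is.null(colnames(true_ratio))) {
      ratio_at <- function(rab, con) true_ratio[rab, con]
    } else {
      if (nrow(true_ratio) != length(rabs) || ncol(true_ratio) != length(constructs)) {
        stop("`true_ratio` matrix must be rabs x constructs", call. = FALSE)
      }
      ratio_at <- function(rab, con) true_ratio[match(rab, rabs), match(con, constructs)]
    }
  } else {
    check_number(true_ratio, "true_ratio", 0)
    ratio_at <- function(rab, con) true_ratio
  }

  with_seed(seed, {
    grid <- expand.grid(construct = constructs, rab = rabs,
                        cell = seq_len(n_cells_per_condition),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(grid)
    f_pre <- pmax(rnorm(n, baseline, baseline_sd), 1)
    ratio <- mapply(ratio_at, grid$rab, grid$construct) +
      rnorm(n, 0, cell_noise_sd)
    data.frame(construct = grid$construct, rab = grid$rab,
               cell_id = sprintf("%s_%s_c%02d", grid$construct, grid$rab, grid$cell),
               F_pre = f_pre, F_post = pmax(f_pre * ratio, 0))
  })
}
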