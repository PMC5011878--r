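#' Synthetic scene and trial generators
#'
#' Every input the pipeline consumes can be generated with known ground
#' truth: dual-illumination root scenes with matching RSML traces, blue-
#' background shoot views, linear growth series, and trial trait tables with
#' the full genotype x nitrogen variance structure. All generators are
#' seed-deterministic and return their truth alongside the rendered output.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# separable gaussian blur with reflected edges
gaussian_blur <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(mat) {
    h <- nrow(mat)
    pad <- rbind(mat[r:1, , drop = FALSE], mat, mat[h:(h - r + 1L), , drop = FALSE])
    out <- matrix(0, h, ncol(mat))
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + h - 1L), , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(m))))
}

# rasterize a polyline (px coordinates, row = y, col = x) into an h x w
# intensity mask in [0, 1] with the given stroke half-width
rasterize_polyline <- function(poly_px, h, w, halfwidth = 1) {
  m <- matrix(0, h, w)
  for (i in seq_len(nrow(poly_px) - 1L)) {
    a <- poly_px[i, ]; b <- poly_px[i + 1L, ]
    steps <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))))
    tt <- seq(0, 1, length.out = steps)
    xs <- a[1] + tt * (b[1] - a[1])
    ys <- a[2] + tt * (b[2] - a[2])
    for (dx in -halfwidth:halfwidth) for (dy in -halfwidth:halfwidth) {
      cc <- round(xs) + dx; rr <- round(ys) + dy
      keep <- cc >= 1 & cc <= w & rr >= 1 & rr <= h
      m[cbind(rr[keep], cc[keep])] <- 1
    }
  }
  m
}

#' Render a synthetic dual-illumination root scene
#'
#' Dark, slightly blurred polyline roots on a textured bright paper
#' background, photographed twice: the left-lit exposure carries a one-sided
#' brightness gradient peaking at the left edge, the right-lit exposure its
#' mirror image, each with independent additive Gaussian channel noise. The
#' planted polylines are returned as a `root_system` (and optionally written
#' to RSML) whose arc lengths are the exact ground truth.
#'
#' @param params list; recognized entries (with defaults): `width`, `height`
#'   (256 px), `scale` (0.13 mm/px), `n_roots` (3), `n_laterals_per_root`
#'   (2), `background_level` (210), `texture_sd` (5), `gradient_strength`
#'   (40), `glare_wash` (0.9, fraction of root darkness lost under full
#'   glare), `noise_sd` (3), `root_darkness` (120), `blur_sigma` (1 px).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param rsml_path optional path to write the matching RSML trace.
#' @param timepoint day index stamped on the root system.
#' @return List: `left_lit`, `right_lit` ([rgb_image]s), `system`
#'   (`root_system`, coordinates in cm), `truth` (list with `root_mask`,
#'   `lengths_cm`, `params`, `seed`).
#' @export
render_root_scene <- function(params = list(), seed = 1L, rsml_path = NULL,
                              timepoint = NA_integer_) {
  p <- utils::modifyList(list(
    width = 256L, height = 256L, scale = 0.13, n_roots = 3L,
    n_laterals_per_root = 2L, background_level = 210, texture_sd = 5,
    gradient_strength = 40, glare_wash = 0.9, noise_sd = 3,
    root_darkness = 120, blur_sigma = 1), params)
  with_seed(seed, {
    h <- p$height; w <- p$width
    roots <- list()
    dark <- matrix(0, h, w)
    for (i in seq_len(p$n_roots)) {
      # fan the axile roots across the paper width, with jitter
      x0 <- w * (0.15 + 0.7 * (i - 0.5) / p$n_roots) + stats::rnorm(1, 0, 0.02 * w)
      n_seg <- 6L
      ys <- seq(0.05 * h, stats::runif(1, 0.6, 0.9) * h, length.out = n_seg + 1L)
      xs <- x0 + cumsum(c(0, stats::rnorm(n_seg, 0, 0.03 * w)))
      poly_px <- cbind(xs, ys)
      laterals <- list()
      if (p$n_laterals_per_root > 0L) {
        for (j in seq_len(p$n_laterals_per_root)) {
          tt <- stats::runif(1, 0.3, 0.8)
          k <- 1L + floor(tt * n_seg)
          base <- poly_px[k, ]
          dir <- sample(c(-1, 1), 1L)
          lat <- rbind(base,
                       base + c(dir * stats::runif(1, 0.05, 0.15) * w,
                                stats::runif(1, 0.02, 0.08) * h))
          laterals[[j]] <- list(id = sprintf("r%d_l%d", i, j),
                                root_class = "lateral", polyline_px = lat)
          dark <- pmax(dark, rasterize_polyline(lat, h, w, halfwidth = 0L))
        }
      }
      roots[[i]] <- list(id = sprintf("r%d", i), root_class = "crown_whorl1",
                         polyline_px = poly_px, laterals_px = laterals)
      dark <- pmax(dark, rasterize_polyline(poly_px, h, w, halfwidth = 1L))
    }
    root_mask <- dark
    dark_soft <- gaussian_blur(dark, p$blur_sigma)

    texture <- matrix(stats::rnorm(h * w, 0, p$texture_sd), h, w)
    bg <- p$background_level + texture
    # one-sided glare: brightens the background and washes out root darkness
    # on the lit side (veiling reflection on the cover sheet)
    wgt_l <- matrix(rep(1 - (seq_len(w) - 1) / max(1, w - 1), each = h), h, w)
    wgt_r <- wgt_l[, w:1, drop = FALSE]
    make_img <- function(wgt) {
      wash <- p$glare_wash * min(1, p$gradient_strength / 40) * wgt
      plane <- bg + p$gradient_strength * wgt -
        p$root_darkness * dark_soft * (1 - wash)
      img <- array(0, c(h, w, 3))
      for (ch in 1:3)
        img[, , ch] <- pmin(255, pmax(0, round(
          plane + matrix(stats::rnorm(h * w, 0, p$noise_sd), h, w))))
      rgb_image(img, scale = p$scale)
    }
    left_lit <- make_img(wgt_l)
    right_lit <- make_img(wgt_r)

    to_cm <- p$scale / 10
    sys_roots <- lapply(roots, function(r) {
      poly_cm <- r$polyline_px * to_cm
      lats <- lapply(r$laterals_px, function(l) {
        lp <- l$polyline_px * to_cm
        list(id = l$id, polyline = lp, length = polyline_arclength(lp),
             insertion_position = project_arclength(poly_cm, lp[1, ]),
             emergence_timepoint = timepoint, root_class = "lateral")
      })
      list(id = r$id, root_class = r$root_class, polyline = poly_cm,
           length = polyline_arclength(poly_cm), laterals = lats)
    })
    system <- structure(list(timepoint = timepoint, slide_id = "synthetic",
                             side = "front", roots = sys_roots),
                        class = "root_system")
    if (!is.null(rsml_path)) write_rsml(system, rsml_path)
    list(left_lit = left_lit, right_lit = right_lit, system = system,
         truth = list(root_mask = root_mask,
                      lengths_cm = vapply(sys_roots, `[[`, numeric(1), "length"),
                      params = p, seed = seed))
  })
}

#' Render synthetic shoot views
#'
#' A green shoot (vertical stem plus leaf straps) on the blue imaging
#' background, with independent Gaussian channel noise per view. The exact
#' foreground pixel count of each rendered view is returned as truth.
#'
#' @param params list; recognized entries (defaults): `width`, `height`
#'   (128 px), `n_views` (4), `shoot_rgb` (c(60, 170, 60)), `background_rgb`
#'   (c(30, 40, 200)), `noise_sd` (10), `n_leaves` (3), `stem_height_frac`
#'   (0.5). Set `empty = TRUE` for background-only views.
#' @param seed RNG seed.
#' @return List: `views` (list of [rgb_image]), `truth` (list with `areas`
#'   pixel counts per view, `masks`, `params`, `seed`).
#' @export
render_shoot_scene <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    width = 128L, height = 128L, n_views = 4L,
    shoot_rgb = c(60, 170, 60), background_rgb = c(30, 40, 200),
    noise_sd = 10, n_leaves = 3L, stem_height_frac = 0.5,
    empty = FALSE), params)
  with_seed(seed, {
    h <- p$height; w <- p$width
    views <- vector("list", p$n_views)
    masks <- vector("list", p$n_views)
    areas <- numeric(p$n_views)
    for (v in seq_len(p$n_views)) {
      mask <- matrix(0, h, w)
      if (!p$empty) {
        cx <- round(w / 2 + stats::runif(1, -0.1, 0.1) * w)
        top <- round(h * (1 - p$stem_height_frac))
        stem <- rasterize_polyline(rbind(c(cx, h - 2), c(cx, top)), h, w,
                                   halfwidth = 1L)
        mask <- pmax(mask, stem)
        for (l in seq_len(p$n_leaves)) {
          y0 <- round(stats::runif(1, top, h - 10))
          dir <- if (l %% 2 == 0) 1 else -1
          tipx <- cx + dir * round(stats::runif(1, 0.15, 0.35) * w)
          tipy <- y0 - round(stats::runif(1, 0.1, 0.25) * h)
          leaf <- rasterize_polyline(rbind(c(cx, y0), c(tipx, tipy)), h, w,
                                     halfwidth = 1L)
          mask <- pmax(mask, leaf)
        }
      }
      img <- array(0, c(h, w, 3))
      for (ch in 1:3) {
        plane <- ifelse(mask == 1, p$shoot_rgb[ch], p$background_rgb[ch]) +
          matrix(stats::rnorm(h * w, 0, p$noise_sd), h, w)
        img[, , ch] <- pmin(255, pmax(0, round(plane)))
      }
      views[[v]] <- rgb_image(img, scale = NA_real_)
      masks[[v]] <- mask
      areas[v] <- sum(mask)
    }
    names(views) <- c("side_front", "side_back", "top_front", "top_back")[seq_len(p$n_views)]
    list(views = views,
         truth = list(areas = areas, masks = masks, params = p, seed = seed))
  })
}

#' Simulate a linear growth series
#'
#' `L(t) = a + b t + e`, `e ~ N(0, sigma^2)` independent per timepoint.
#'
#' @param a intercept at solution change (cm or pixels).
#' @param b slope (per day).
#' @param sigma observation noise SD (>= 0).
#' @param timepoints vector of days since solution change (>= 2 values).
#' @param seed RNG seed.
#' @return Data frame `t`, `length` with attribute `truth = c(a, b, sigma)`.
#' @export
simulate_growth_series <- function(a, b, sigma, timepoints, seed = 1L) {
  stopifnot(sigma >= 0, length(timepoints) >= 2L)
  with_seed(seed, {
    y <- a + b * timepoints + stats::rnorm(length(timepoints), 0, sigma)
    structure(data.frame(t = timepoints, length = y),
              truth = c(a = a, b = b, sigma = sigma))
  })
}

#' Ground truth for a simulated genotype x nitrogen trial
#'
#' Draws (or accepts) sum-to-zero fixed effects and the variance components
#' of the split-nitrogen model: `y = mu + G + N + G:N + R + S + GR + e`,
#' with `GR ~ N(0, sigma2_GR)` and `e ~ N(0, sigma2_e[N])`.
#'
#' @param n_genotypes,n_reps trial dimensions (>= 2 each).
#' @param mu general mean.
#' @param sd_g,sd_gn SDs used to draw genotype and interaction effects
#'   (sum-to-zero); alternatively pass explicit `genotype_effects` /
#'   `gn_effects`.
#' @param n_effect total high-minus-low nitrogen difference (split as +/-
#'   half, sum-to-zero).
#' @param rep_effects,side_effects explicit sum-to-zero effect vectors, or
#'   `NULL` for zeros.
#' @param sigma2_GR slide (genotype x replicate) variance.
#' @param sigma2_e residual variances, named `c(high = , low = )`.
#' @param genotype_effects,gn_effects optional explicit effects (length
#'   `n_genotypes`; `gn_effects` an `n_genotypes x 2` matrix, columns high/low).
#' @param missing_rate probability a root record is missing (root never
#'   established), applied per (genotype, rep, side, N) record; may be a
#'   named vector `c(high = , low = )`.
#' @param seed RNG seed for the effect draws.
#' @return A `trial_truth` list.
#' @export
trial_truth <- function(n_genotypes = 24L, n_reps = 4L, mu = 10,
                        sd_g = 1, sd_gn = 0, n_effect = 0,
                        rep_effects = NULL, side_effects = NULL,
                        sigma2_GR = 0, sigma2_e = c(high = 1, low = 1),
                        genotype_effects = NULL, gn_effects = NULL,
                        missing_rate = 0, seed = 1L) {
  stopifnot(n_genotypes >= 2L, n_reps >= 2L)
  ctr <- function(x) x - mean(x)
  with_seed(seed, {
    if (is.null(genotype_effects))
      genotype_effects <- if (sd_g > 0) ctr(stats::rnorm(n_genotypes, 0, sd_g)) else rep(0, n_genotypes)
    if (is.null(gn_effects)) {
      gn <- if (sd_gn > 0) stats::rnorm(n_genotypes, 0, sd_gn) else rep(0, n_genotypes)
      gn <- ctr(gn)
      gn_effects <- cbind(high = gn, low = -gn)
    }
    if (is.null(rep_effects)) rep_effects <- rep(0, n_reps)
    if (is.null(side_effects)) side_effects <- c(front = 0, back = 0)
    if (length(missing_rate) == 1L)
      missing_rate <- c(high = missing_rate, low = missing_rate)
    structure(list(
      n_genotypes = n_genotypes, n_reps = n_reps, mu = mu,
      genotype_effects = ctr(genotype_effects),
      n_effects = c(high = n_effect / 2, low = -n_effect / 2),
      gn_effects = gn_effects, rep_effects = ctr(rep_effects),
      side_effects = ctr(side_effects),
      sigma2_GR = sigma2_GR, sigma2_e = sigma2_e,
      missing_rate = missing_rate, seed = seed), class = "trial_truth")
  })
}

#' Simulate a split-nitrogen trial trait table
#'
#' Generates the fully crossed genotype x nitrogen x replicate x side table
#' from a [trial_truth], drawing slide effects and residuals, and optionally
#' deleting root records completely at random (roots that never established).
#'
#' @param truth a [trial_truth].
#' @param trait trait name for the records.
#' @param units unit string.
#' @param seed RNG seed for the noise draws (independent of the effect draws
#'   in [trial_truth]).
#' @return A [trait_table]; attribute `truth` carries the generating values.
#' @export
simulate_trial <- function(truth, trait = "ER_Cr", units = "cm/d", seed = 1L) {
  stopifnot(inherits(truth, "trial_truth"))
  g <- truth$n_genotypes; r <- truth$n_reps
  genos <- sprintf("G%02d", seq_len(g))
  grid <- expand.grid(genotype = genos, replicate = seq_len(r),
                      side = c("front", "back"), n_level = c("high", "low"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$genotype, genos)
  with_seed(seed, {
    gr <- matrix(stats::rnorm(g * r, 0, sqrt(truth$sigma2_GR)), g, r)
    eps <- stats::rnorm(nrow(grid), 0,
                        sqrt(truth$sigma2_e[grid$n_level]))
    y <- truth$mu +
      truth$genotype_effects[gi] +
      truth$n_effects[grid$n_level] +
      truth$gn_effects[cbind(gi, match(grid$n_level, c("high", "low")))] +
      truth$rep_effects[grid$replicate] +
      truth$side_effects[match(grid$side, c("front", "back"))] +
      gr[cbind(gi, grid$replicate)] + eps
    tab <- trait_table(grid$genotype, grid$n_level, grid$replicate, grid$side,
                       trait, as.numeric(y), units)
    if (any(truth$missing_rate > 0)) {
      drop <- stats::runif(nrow(tab)) < truth$missing_rate[tab$n_level]
      tab <- tab[!drop, , drop = FALSE]
      class(tab) <- c("trait_table", "data.frame")
    }
    attr(tab, "truth") <- truth
    tab
  })
}
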