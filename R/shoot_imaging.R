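#' Excess-green feature map
#'
#' Computes the colour feature `f = 2*G - R - B` per pixel, in signed integer
#' arithmetic (values in `[-510, 510]`, no 8-bit wraparound). Green vegetation
#' scores high; the blue imaging background scores strongly negative, grey
#' surfaces score zero.
#'
#' @param img an [rgb_image].
#' @return An integer matrix of class `feature_map`.
#' @export
#' @examples
#' px <- rgb_image(array(c(10L, 50L, 20L), c(1, 1, 3)))
#' excess_green(px)  # 2*50 - 10 - 20 = 70
excess_green <- function(img) {
  stopifnot(is_rgb_image(img))
  x <- unclass(img)
  f <- 2L * x[, , 2L] - x[, , 1L] - x[, , 3L]
  if (!is.matrix(f)) f <- matrix(f, dim(img)[1], dim(img)[2])
  structure(f, class = "feature_map")
}

#' Coarse shoot segmentation by fixed excess-green threshold
#'
#' Pixels with feature value greater than or equal to the threshold (55 by
#' default, the value calibrated for the platform's blue-background shoot
#' images) are foreground. The high threshold reliably hits all plant regions
#' but clips their borders; the fine Otsu pass recovers the full extent.
#'
#' @param f a `feature_map` (see [excess_green]).
#' @param threshold integer threshold; foreground is `f >= threshold`.
#' @return A [binary_mask].
#' @export
coarse_segment <- function(f, threshold = 55L) {
  stopifnot(inherits(f, "feature_map") || is.matrix(f))
  binary_mask(unclass(f) >= threshold)
}

#' Fine shoot segmentation by Otsu's method
#'
#' Chooses the threshold maximizing the between-class variance of the full
#' signed feature-value histogram (no rescaling to 0-255); foreground is
#' `f >= threshold`. Ties in between-class variance are broken toward the
#' lower threshold.
#'
#' @param f a `feature_map`.
#' @return A [binary_mask].
#' @export
otsu_segment <- function(f) {
  v <- as.vector(unclass(f))
  lev <- sort(unique(v))
  if (length(lev) < 2L)
    stop("constant feature map: Otsu threshold is undefined", call. = FALSE)
  cnt <- tabulate(match(v, lev))
  n <- length(v)
  # candidate thresholds: each level above the minimum (mask = f >= t)
  cs <- cumsum(cnt)                # pixels with value <= lev[i]
  csv <- cumsum(cnt * lev)         # sum of values <= lev[i]
  tot <- csv[length(csv)]
  k <- seq_len(length(lev) - 1L)   # split after level k
  w0 <- cs[k] / n
  w1 <- 1 - w0
  m0 <- csv[k] / cs[k]
  m1 <- (tot - csv[k]) / (n - cs[k])
  bcv <- w0 * w1 * (m1 - m0)^2
  best <- which.max(bcv)           # first maximum = lowest threshold on ties
  thr <- lev[best + 1L]
  binary_mask(unclass(f) >= thr)
}

#' 8-connected component labeling
#'
#' Labels connected foreground components of a binary mask using
#' 8-connectivity (diagonal neighbours connect). Labels are consecutive
#' integers starting at 1; background is 0.
#'
#' @param mask a [binary_mask] or 0/1 matrix.
#' @return An integer matrix of component labels.
#' @export
label_components <- function(mask) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  lab[m == 1L] <- which(m == 1L)
  if (!any(m == 1L)) return(lab)
  # iterative max-propagation over the 8-neighbourhood until fixpoint
  repeat {
    p <- matrix(0L, h + 2L, w + 2L)
    p[2:(h + 1L), 2:(w + 1L)] <- lab
    nb <- pmax(
      p[1:h, 2:(w + 1L)],     p[3:(h + 2L), 2:(w + 1L)],
      p[2:(h + 1L), 1:w],     p[2:(h + 1L), 3:(w + 2L)],
      p[1:h, 1:w],            p[1:h, 3:(w + 2L)],
      p[3:(h + 2L), 1:w],     p[3:(h + 2L), 3:(w + 2L)]
    )
    new <- lab
    fg <- m == 1L
    new[fg] <- pmax(lab, nb)[fg]
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Merge coarse and fine shoot segmentations
#'
#' Selects all regions of the coarse mask `s_c` and enlarges them to all
#' connected regions of the fine mask `s_f`: the output is the union of `s_c`
#' with every 8-connected component of `s_f` that touches `s_c` or its
#' 8-neighbourhood. Components of `s_f` with no connection to `s_c`
#' (background clutter picked up by Otsu) are dropped.
#'
#' @param s_c coarse [binary_mask] (seed regions).
#' @param s_f fine [binary_mask] (accurate borders plus clutter).
#' @return A [binary_mask], a sub-mask of `s_f | s_c`.
#' @export
merge_segmentations <- function(s_c, s_f) {
  c_ <- unclass(s_c); f_ <- unclass(s_f)
  if (!identical(dim(c_), dim(f_)))
    stop("mask dimensions differ: cannot merge", call. = FALSE)
  if (!any(c_ == 1L)) return(binary_mask(matrix(0L, nrow(c_), ncol(c_))))
  lab <- label_components(f_)
  seed <- dilate3x3(c_)
  keep <- unique(lab[seed == 1L & lab > 0L])
  out <- matrix(0L, nrow(c_), ncol(c_))
  if (length(keep)) out[lab %in% keep] <- 1L
  out[c_ == 1L] <- 1L
  binary_mask(out)
}

# 3x3 (8-neighbourhood) binary dilation
dilate3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  d <- pmax(
    p[2:(h + 1L), 2:(w + 1L)],
    p[1:h, 2:(w + 1L)],     p[3:(h + 2L), 2:(w + 1L)],
    p[2:(h + 1L), 1:w],     p[2:(h + 1L), 3:(w + 2L)],
    p[1:h, 1:w],            p[1:h, 3:(w + 2L)],
    p[3:(h + 2L), 1:w],     p[3:(h + 2L), 3:(w + 2L)]
  )
  d
}

#' Two-step shoot segmentation
#'
#' Runs the full pipeline on one view: optional background subtraction
#' (a plant-free reference image of the imaging station), excess-green
#' feature map, coarse fixed-threshold segmentation, fine Otsu segmentation,
#' and region merge. If the feature map is constant (e.g. an empty view) the
#' fine mask is taken to be empty.
#'
#' @param img an [rgb_image] shoot view.
#' @param background optional plant-free reference [rgb_image]; subtracted
#'   channel-wise (signed) before feature mapping.
#' @param coarse_threshold threshold for the coarse pass.
#' @return A [binary_mask] of shoot pixels.
#' @export
segment_shoot <- function(img, background = NULL, coarse_threshold = 55L) {
  stopifnot(is_rgb_image(img))
  if (!is.null(background)) {
    stopifnot(is_rgb_image(background))
    if (!identical(dim(img), dim(background)))
      stop("background dimensions differ from image", call. = FALSE)
    x <- unclass(img) - unclass(background)
    f <- 2L * x[, , 2L] - x[, , 1L] - x[, , 3L]
    f <- structure(matrix(f, dim(img)[1], dim(img)[2]), class = "feature_map")
  } else {
    f <- excess_green(img)
  }
  s_c <- coarse_segment(f, coarse_threshold)
  s_f <- tryCatch(otsu_segment(f), error = function(e) {
    binary_mask(matrix(0L, nrow(f), ncol(f)))
  })
  merge_segmentations(s_c, s_f)
}

#' Multi-view canopy-size proxy in pixels
#'
#' The number of shoot pixels, averaged over the available side and top
#' views, is the platform's non-destructive proxy for canopy size. Each view
#' is segmented with [segment_shoot] and the arithmetic mean of the
#' foreground pixel counts is returned. Any subset of the four standard views
#' (side front/back, top front/back) is accepted.
#'
#' @param views a list of [rgb_image] views (optionally named).
#' @param background optional reference image, passed to [segment_shoot];
#'   either one image used for all views or a list parallel to `views`.
#' @param coarse_threshold threshold for the coarse pass.
#' @return Mean foreground pixel count (a single number).
#' @export
canopy_pixel_proxy <- function(views, background = NULL, coarse_threshold = 55L) {
  if (is_rgb_image(views)) views <- list(views)
  if (length(views) == 0L)
    stop("canopy proxy requires at least one view", call. = FALSE)
  counts <- vapply(seq_along(views), function(i) {
    bg <- if (is.null(background)) NULL
          else if (is_rgb_image(background)) background
          else background[[i]]
    sum(unclass(segment_shoot(views[[i]], background = bg,
                              coarse_threshold = coarse_threshold)))
  }, numeric(1))
  mean(counts)
}
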