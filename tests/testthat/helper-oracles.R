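# Independent brute-force oracles and fixture builders used across tests.

random_rgb <- function(h = 16, w = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

# Exhaustive Otsu: for every candidate threshold, compute the two class means
# directly from the pixel vector and score the between-class variance.
oracle_otsu_mask <- function(f) {
  v <- as.vector(unclass(f))
  lev <- sort(unique(v))
  best_bcv <- -Inf
  best_thr <- NA
  for (thr in lev[-1]) {     # mask = f >= thr, both classes non-empty
    hi <- v[v >= thr]; lo <- v[v < thr]
    w1 <- length(hi) / length(v); w0 <- 1 - w1
    bcv <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (bcv > best_bcv + 1e-12) { best_bcv <- bcv; best_thr <- thr }
  }
  matrix(as.integer(v >= best_thr), nrow(f), ncol(f))
}

# Brute-force queue flood fill from every coarse-mask pixel over the union
# mask, 8-connectivity; returns the reachable set.
oracle_merge_mask <- function(s_c, s_f) {
  cm <- unclass(s_c); fm <- unclass(s_f)
  h <- nrow(cm); w <- ncol(cm)
  un <- pmax(cm, fm)
  visited <- matrix(FALSE, h, w)
  queue <- which(cm == 1L)
  visited[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    r <- ((idx - 1L) %% h) + 1L
    cc <- ((idx - 1L) %/% h) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
      if (un[rr, c2] == 1L && !visited[rr, c2]) {
        visited[rr, c2] <- TRUE
        queue <- c(queue, (c2 - 1L) * h + rr)
      }
    }
  }
  matrix(as.integer(visited & un == 1L), h, w)
}

# ANOVA method-of-moments components for a balanced one-way random layout
oracle_oneway_components <- function(y, g) {
  g <- factor(g)
  r <- length(y) / nlevels(g)
  fit <- stats::anova(stats::lm(y ~ g))
  msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
  c(sigma2_g = (msb - msw) / r, sigma2_e = msw)
}

# Closed-form OLS line fit via the normal equations
oracle_ols_line <- function(t, y) {
  sxx <- sum((t - mean(t))^2)
  b <- sum((t - mean(t)) * (y - mean(y))) / sxx
  c(a = mean(y) - b * mean(t), b = b)
}

# Hand-built multi-timepoint root systems (no RSML involved) for zone tests
make_axile <- function(id, length_cm, laterals = list(), class = "crown_whorl1") {
  poly <- cbind(c(0, 0), c(0, length_cm))  # straight vertical root at x = 0
  list(id = id, root_class = class, polyline = poly, length = length_cm,
       laterals = laterals)
}

make_lateral <- function(id, insertion, length_cm) {
  poly <- cbind(c(0, length_cm), c(insertion, insertion))
  list(id = id, polyline = poly, length = length_cm,
       insertion_position = insertion, emergence_timepoint = NA_integer_)
}

make_system <- function(timepoint, roots) {
  structure(list(timepoint = timepoint, slide_id = "fix", side = "front",
                 roots = roots), class = "root_system")
}
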