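#' Fuse two differently illuminated root images by minimum tonal value
#'
#' Each rhizoslide side is photographed twice, once lit by the left LED bar
#' and once by the right. Either exposure carries a one-sided glare gradient
#' on the bright germination-paper background; the roots themselves are dark
#' under both. Keeping, per pixel and per channel, the minimum tonal value of
#' the two exposures suppresses the glare while preserving the dark root
#' signal, yielding a single high-contrast 24-bit RGB image.
#'
#' No registration is performed: the slide and camera do not move between the
#' two exposures, so pixel alignment is a precondition.
#'
#' @param left_lit,right_lit [rgb_image]s of identical dimensions and scale.
#' @return The fused [rgb_image].
#' @export
#' @examples
#' a <- rgb_image(array(200L, c(4, 4, 3)))
#' b <- rgb_image(array(rep(c(50L, 80L, 90L), each = 16), c(4, 4, 3)))
#' fuse_min_tonal(a, b)[1, 1, ]  # 50 80 90
fuse_min_tonal <- function(left_lit, right_lit) {
  stopifnot(is_rgb_image(left_lit), is_rgb_image(right_lit))
  if (!identical(dim(left_lit), dim(right_lit)))
    stop("image dimensions differ: cannot fuse", call. = FALSE)
  if (!isTRUE(all.equal(attr(left_lit, "scale"), attr(right_lit, "scale"))))
    stop("image scale metadata differs: cannot fuse", call. = FALSE)
  rgb_image(pmin(unclass(left_lit), unclass(right_lit)),
            scale = attr(left_lit, "scale"))
}
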