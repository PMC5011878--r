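test_that("excess green evaluates 2G - R - B in signed arithmetic", {
  px <- function(r, g, b) rgb_image(array(c(r, g, b), c(1, 1, 3)))
  expect_equal(excess_green(px(10, 50, 20))[1, 1], 70L)
  expect_equal(excess_green(px(100, 100, 100))[1, 1], 0L)
  expect_equal(excess_green(px(0, 0, 255))[1, 1], -255L)
  expect_equal(excess_green(px(0, 255, 0))[1, 1], 510L)
})

test_that("coarse segmentation marks exactly f >= threshold", {
  f <- structure(matrix(c(54L, 55L, 56L, 0L), 2, 2), class = "feature_map")
  m <- coarse_segment(f, 55L)
  expect_equal(as.integer(m), as.integer(unclass(f) >= 55L))
  expect_equal(sum(coarse_segment(structure(matrix(0L, 4, 4), class = "feature_map"))), 0L)
  expect_equal(sum(coarse_segment(f, -511L)), 4L)
  # monotone decreasing in threshold: higher threshold gives a subset mask
  set.seed(21)
  f2 <- structure(matrix(sample(-510:510, 256, TRUE), 16, 16), class = "feature_map")
  lo <- coarse_segment(f2, 10L); hi <- coarse_segment(f2, 120L)
  expect_true(all(unclass(hi) <= unclass(lo)))
})

test_that("Otsu segmentation splits two-valued maps and rejects constant maps", {
  f <- structure(matrix(c(rep(10L, 100), rep(200L, 100)), 10, 20),
                 class = "feature_map")
  m <- otsu_segment(f)
  expect_equal(unclass(m), matrix(as.integer(unclass(f) == 200L), 10, 20))
  # extreme class imbalance: same split
  v <- c(rep(5L, 1), rep(90L, 9999))
  f2 <- structure(matrix(v, 100, 100), class = "feature_map")
  m2 <- otsu_segment(f2)
  expect_equal(unclass(m2), matrix(as.integer(v == 90L), 100, 100))
  expect_error(otsu_segment(structure(matrix(7L, 4, 4), class = "feature_map")),
               "constant")
})

test_that("Otsu agrees with the exhaustive between-class-variance search", {
  set.seed(31)
  for (i in 1:20) {
    f <- structure(matrix(sample(-100:100, 256, TRUE), 16, 16),
                   class = "feature_map")
    expect_equal(unclass(otsu_segment(f)), oracle_otsu_mask(f))
  }
})

test_that("segmentation merge keeps exactly the fine regions connected to coarse seeds", {
  z <- matrix(0L, 8, 8)
  # no seeds -> empty
  expect_equal(sum(merge_segmentations(binary_mask(z), binary_mask(z + 1L))), 0L)
  # single fine component containing the coarse component -> whole component
  sf <- z; sf[2:6, 2:6] <- 1L
  sc <- z; sc[4, 4] <- 1L
  expect_equal(unclass(merge_segmentations(binary_mask(sc), binary_mask(sf))), sf)
  # two fine components, one connected -> only that one
  sf2 <- z; sf2[1:2, 1:2] <- 1L; sf2[6:8, 6:8] <- 1L
  sc2 <- z; sc2[2, 2] <- 1L
  out <- merge_segmentations(binary_mask(sc2), binary_mask(sf2))
  expect_equal(sum(unclass(out)[6:8, 6:8]), 0L)
  expect_equal(sum(unclass(out)[1:2, 1:2]), 4L)
})

test_that("merge matches brute-force flood fill and is monotone in the seed mask", {
  set.seed(41)
  for (i in 1:15) {
    sf <- binary_mask(matrix(rbinom(32 * 32, 1, 0.45), 32, 32))
    sc_small <- matrix(rbinom(32 * 32, 1, 0.02), 32, 32)
    sc_big <- pmax(sc_small, matrix(rbinom(32 * 32, 1, 0.03), 32, 32))
    m_small <- merge_segmentations(binary_mask(sc_small), sf)
    m_big <- merge_segmentations(binary_mask(sc_big), sf)
    expect_equal(unclass(m_small), oracle_merge_mask(binary_mask(sc_small), sf))
    # monotone: growing the seed mask never shrinks the output
    expect_true(all(unclass(m_small) <= unclass(m_big)))
    # output within the union of the two masks
    expect_true(all(unclass(m_big) <= pmax(sc_big, unclass(sf))))
  }
})

test_that("canopy proxy averages foreground counts over views", {
  # construct views with exact rectangular shoots of known pixel area
  mk_view <- function(area_rows) {
    img <- array(0, c(32, 32, 3))
    img[, , 1] <- 30; img[, , 2] <- 40; img[, , 3] <- 200
    if (area_rows > 0) {
      img[1:area_rows, 1:10, 1] <- 60
      img[1:area_rows, 1:10, 2] <- 170
      img[1:area_rows, 1:10, 3] <- 60
    }
    rgb_image(img)
  }
  views <- list(mk_view(10), mk_view(20), mk_view(15), mk_view(15))
  expect_equal(canopy_pixel_proxy(views), mean(c(100, 200, 150, 150)))
  expect_equal(canopy_pixel_proxy(list(mk_view(32))), 320)
  expect_error(canopy_pixel_proxy(list()), "at least one view")
})

test_that("canopy proxy recovers planted area exactly on noiseless scenes", {
  sc <- render_shoot_scene(list(noise_sd = 0), seed = 5)
  expect_equal(canopy_pixel_proxy(sc$views), mean(sc$truth$areas))
  empty <- render_shoot_scene(list(noise_sd = 0, empty = TRUE), seed = 5)
  expect_equal(canopy_pixel_proxy(empty$views), 0)
})
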