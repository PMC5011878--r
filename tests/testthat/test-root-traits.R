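rsml_px_file <- function(points_xml, resolution = "0.13", with_res = TRUE) {
  path <- withr::local_tempfile(fileext = ".rsml", .local_envir = parent.frame())
  res_line <- if (with_res) sprintf("<resolution>%s</resolution>", resolution) else ""
  writeLines(sprintf(
    '<?xml version="1.0"?><rsml><metadata><unit>pixel</unit>%s</metadata><scene><plant>%s</plant></scene></rsml>',
    res_line, points_xml), path)
  path
}

test_that("RSML parsing converts pixel coordinates to cm via the image scale", {
  p <- rsml_px_file(paste0(
    '<root ID="r1" label="crown_whorl1"><geometry><polyline>',
    '<point x="0" y="0"/><point x="100" y="0"/></polyline></geometry></root>'))
  rs <- read_rsml(p, timepoint = 14L)
  expect_equal(rs$roots[[1]]$length, 1.3)  # 100 px * 0.13 mm/px / 10
  # missing resolution metadata -> default scale with warning
  p2 <- rsml_px_file(paste0(
    '<root ID="r1"><geometry><polyline>',
    '<point x="0" y="0"/><point x="100" y="0"/></polyline></geometry></root>'),
    with_res = FALSE)
  expect_warning(rs2 <- read_rsml(p2), "resolution")
  expect_equal(rs2$roots[[1]]$length, 1.3)
})

test_that("RSML hierarchy and parent references are validated", {
  p <- rsml_px_file(paste0(
    '<root ID="ax1" label="crown_whorl1"><geometry><polyline>',
    '<point x="50" y="0"/><point x="50" y="500"/></polyline></geometry>',
    '<root ID="l1"><geometry><polyline><point x="50" y="100"/><point x="90" y="120"/></polyline></geometry></root>',
    '<root ID="l2"><geometry><polyline><point x="50" y="200"/><point x="20" y="230"/></polyline></geometry></root>',
    '<root ID="l3"><geometry><polyline><point x="50" y="300"/><point x="80" y="340"/></polyline></geometry></root>',
    '</root>'))
  rs <- read_rsml(p)
  expect_length(rs$roots, 1L)
  expect_length(rs$roots[[1]]$laterals, 3L)
  ins <- vapply(rs$roots[[1]]$laterals, `[[`, numeric(1), "insertion_position")
  expect_equal(ins, c(100, 200, 300) * 0.013)
  # flat lateral referencing a missing parent
  p_bad <- rsml_px_file(paste0(
    '<root ID="ax1"><geometry><polyline><point x="0" y="0"/><point x="0" y="10"/></polyline></geometry></root>',
    '<root ID="lx" parent="nope"><geometry><polyline><point x="0" y="5"/><point x="3" y="6"/></polyline></geometry></root>'))
  expect_error(read_rsml(p_bad), "integrity")
  # malformed XML
  p_mal <- withr::local_tempfile(fileext = ".rsml")
  writeLines("<rsml><scene>", p_mal)
  expect_error(read_rsml(p_mal))
})

test_that("RSML write/read round-trips arc lengths to 1e-6 cm", {
  sc <- render_root_scene(list(width = 128L, height = 128L), seed = 7)
  path <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(sc$system, path)
  back <- read_rsml(path)
  lens <- vapply(back$roots, `[[`, numeric(1), "length")
  expect_equal(lens, sc$truth$lengths_cm, tolerance = 1e-9)
  expect_true(all(abs(lens - sc$truth$lengths_cm) <= 1e-6))
})

test_that("crown-root eligibility applies barrier, edge and baseline rules", {
  geom <- list(paper_width_cm = 20, paper_height_cm = 30, barrier_x_cm = 10,
               n_level_left = "high", n_level_right = "low")
  straight <- function(id, x, y_end, class = "crown_whorl1")
    list(id = id, root_class = class,
         polyline = cbind(c(x, x), c(0, y_end)),
         length = y_end, laterals = list())
  crossing <- list(id = "rX", root_class = "crown_whorl1",
                   polyline = cbind(c(8, 12), c(0, 10)),
                   length = sqrt(16 + 100), laterals = list())
  sys14 <- make_system(14, list(straight("rA", 5, 10), crossing,
                                straight("rB", 15, 10)))
  sys26 <- make_system(26, list(straight("rA", 5, 20), crossing,
                                straight("rB", 15, 29.8)))
  elig <- filter_traceable(list(sys14, sys26), geom, baseline_day = 14)
  expect_true(elig$eligible[elig$root_id == "rA"])
  expect_equal(elig$compartment[elig$root_id == "rA"], "high")
  expect_false(elig$eligible[elig$root_id == "rX"])  # crosses barrier
  expect_false(elig$eligible[elig$root_id == "rB"])  # tip 0.2 cm from bottom
  expect_match(attr(elig, "flags"), "low")
  # invariant to timepoint ordering of the input
  elig_rev <- filter_traceable(list(sys26, sys14), geom, baseline_day = 14)
  expect_identical(elig, elig_rev)
  # root absent at baseline is ineligible
  sys14b <- make_system(14, list(straight("rA", 5, 10)))
  sys26b <- make_system(26, list(straight("rA", 5, 20), straight("rC", 5, 12)))
  e2 <- filter_traceable(list(sys14b, sys26b), geom, baseline_day = 14)
  expect_false(e2$eligible[e2$root_id == "rC"])
})

test_that("length series re-origin to the solution change and flag shrinkage", {
  syss <- list(
    make_system(14, list(make_axile("r1", 5))),
    make_system(16, list(make_axile("r1", 8))),
    make_system(18, list(make_axile("r1", 11))))
  s <- crown_length_series(syss, "r1", solution_change_day = 14)
  expect_equal(s$t, c(0, 2, 4))
  expect_equal(s$length, c(5, 8, 11))
  expect_length(attr(s, "qc"), 0L)
  expect_error(crown_length_series(syss, "nope", 14), "lookup")
  expect_error(crown_length_series(syss[1], "r1", 14), "single timepoint")
  # shrinking series kept with QC warning
  syss2 <- list(make_system(14, list(make_axile("r1", 5))),
                make_system(16, list(make_axile("r1", 4))))
  s2 <- crown_length_series(syss2, "r1", 14)
  expect_equal(nrow(s2), 2L)
  expect_match(attr(s2, "qc"), "decreases")
})

test_that("branching zone spans change-to-harvest distal laterals, split in two", {
  syss <- list(
    make_system(14, list(make_axile("r1", 6, list(make_lateral("l1", 4, 1))))),
    make_system(26, list(make_axile("r1", 15, list(
      make_lateral("l1", 4, 2), make_lateral("l2", 12, 1.5))))))
  z <- branching_zone("r1", syss, 14, 26)
  expect_equal(z$proximal_pos, 4)
  expect_equal(z$distal_pos, 12)
  expect_equal(z$segment1, c(4, 8))
  expect_equal(z$segment2, c(8, 12))
  # multiple laterals on both sides
  syss2 <- list(
    make_system(14, list(make_axile("r1", 8, list(
      make_lateral("a", 3, 1), make_lateral("b", 6, 1))))),
    make_system(26, list(make_axile("r1", 20, list(
      make_lateral("a", 3, 1), make_lateral("b", 6, 1),
      make_lateral("c", 9, 1), make_lateral("d", 14, 1))))))
  z2 <- branching_zone("r1", syss2, 14, 26)
  expect_equal(c(z2$proximal_pos, z2$distal_pos), c(6, 14))
  expect_equal(z2$segment1, c(6, 10))
  expect_equal(z2$segment2, c(10, 14))
  # segments always partition the zone exactly
  expect_equal(z2$segment1[2], z2$segment2[1])
  expect_equal(diff(z2$segment1), diff(z2$segment2))
  # no new distal laterals -> zone-empty
  syss3 <- list(
    make_system(14, list(make_axile("r1", 8, list(make_lateral("a", 6, 1))))),
    make_system(26, list(make_axile("r1", 20, list(make_lateral("a", 6, 1))))))
  expect_error(branching_zone("r1", syss3, 14, 26), "zone-empty")
  # no laterals at change -> zone undefined
  syss4 <- list(
    make_system(14, list(make_axile("r1", 8))),
    make_system(26, list(make_axile("r1", 20, list(make_lateral("a", 6, 1))))))
  expect_error(branching_zone("r1", syss4, 14, 26), "zone-undefined")
})

test_that("lateral metrics use the lower median and the distal tie-break", {
  root <- make_axile("r1", 20, list(
    make_lateral("a", 4.0, 1.0), make_lateral("b", 5.0, 2.0),
    make_lateral("c", 7.0, 3.0),                       # segment 1: [4, 8)
    make_lateral("d", 8.0, 9.9),                       # boundary -> segment 2
    make_lateral("e", 10.0, 0.5), make_lateral("f", 12.0, 4.0)))
  zone <- structure(list(proximal_pos = 4, distal_pos = 12, midpoint = 8,
                         segment1 = c(4, 8), segment2 = c(8, 12)),
                    class = "branching_zone")
  m <- lateral_metrics(root, zone)
  expect_equal(m$No_Lat_1st, 3)
  expect_equal(m$Max_Lat_1st, 3.0)
  expect_equal(m$Med_Lat_1st, 2.0)
  expect_equal(m$density_1st, 3 / 4)
  expect_equal(m$No_Lat_2nd, 3)          # boundary lateral counted distal
  expect_equal(m$Max_Lat_2nd, 9.9)
  expect_equal(m$Med_Lat_2nd, 4.0)
  expect_equal(m$density_2nd, 3 / 4)
  expect_lte(m$Med_Lat_1st, m$Max_Lat_1st)
  # even count: lower median
  root2 <- make_axile("r2", 20, list(
    make_lateral("a", 4.5, 1.0), make_lateral("b", 5.0, 2.0),
    make_lateral("c", 6.0, 3.0), make_lateral("d", 7.0, 4.0)))
  m2 <- lateral_metrics(root2, zone)
  expect_equal(m2$No_Lat_1st, 4)
  expect_equal(m2$Med_Lat_1st, 2.0)
  # empty segment
  expect_equal(m2$No_Lat_2nd, 0)
  expect_true(is.na(m2$Max_Lat_2nd) && is.na(m2$Med_Lat_2nd))
})

test_that("pre-change-zone lateral counts compare change and harvest", {
  at_change <- lapply(1:5, function(i) make_lateral(paste0("l", i), i, 1))
  at_harvest_same <- at_change
  at_harvest_more <- c(at_change, list(make_lateral("new", 2.5, 0.5)))
  syss <- list(make_system(14, list(make_axile("r1", 10, at_change))),
               make_system(26, list(make_axile("r1", 20, at_harvest_same))))
  expect_equal(laterals_in_pre_change_zone("r1", syss, 14, 26),
               c(change = 5L, harvest = 5L))
  syss2 <- list(make_system(14, list(make_axile("r1", 10, at_change))),
                make_system(26, list(make_axile("r1", 20, at_harvest_more))))
  expect_equal(laterals_in_pre_change_zone("r1", syss2, 14, 26),
               c(change = 5L, harvest = 6L))
  syss3 <- list(make_system(14, list(make_axile("r1", 10))),
                make_system(26, list(make_axile("r1", 20))))
  expect_equal(laterals_in_pre_change_zone("r1", syss3, 14, 26),
               c(change = 0L, harvest = 0L))
})
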