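# Boundary detection on shapes with exactly known geometry (constructed
# directly, independent of the synthetic generator).

test_that("segmentation finds a centred disc and its centroid", {
  img <- section_image(list(hypoxia = disc_mat(201, 101, 101, 80, 0.9)), 2)
  seg <- segment_and_centroid(img)
  expect_equal(seg$centroid[["x"]], 101, tolerance = 0.5 / 101)
  expect_equal(seg$centroid[["y"]], 101, tolerance = 0.5 / 101)
  # translation equivariance
  img2 <- section_image(list(hypoxia = disc_mat(201, 116, 91, 80, 0.9)), 2)
  seg2 <- segment_and_centroid(img2)
  expect_equal(seg2$centroid[["x"]] - seg$centroid[["x"]], 15, tolerance = 0.01)
  expect_equal(seg2$centroid[["y"]] - seg$centroid[["y"]], -10, tolerance = 0.01)
  # ellipse: centroid at the known centre within 1 px
  img3 <- section_image(list(hypoxia = ellipse_mat(241, 121, 121, 110, 90, 0.8)), 2)
  seg3 <- segment_and_centroid(img3)
  expect_equal(unname(seg3$centroid), c(121, 121), tolerance = 1 / 121)
  # empty mask is an explicit measurement failure
  blank <- section_image(list(hypoxia = matrix(0, 50, 50)), 2)
  expect_error(segment_and_centroid(blank, threshold = 0.5),
               class = "spheroido2_measurement")
})

test_that("small detached components are removed before boundary detection", {
  m <- disc_mat(201, 101, 101, 70, 0.9)
  m <- m + disc_mat(201, 15, 15, 4, 0.9) # artefact blob far outside
  img <- section_image(list(hypoxia = pmin(m, 1)), 2)
  seg <- segment_and_centroid(img)
  expect_false(seg$mask[15, 15])
  expect_true(seg$mask[101, 101])
  r_o <- detect_outer_boundary(seg$mask, seg$centroid)
  expect_equal(mean(r_o), 70, tolerance = 1 / 70)
})

test_that("outer boundary: disc, annulus (hole-insensitive) and ellipse", {
  img <- section_image(list(hypoxia = disc_mat(301, 151, 151, 120, 0.9)), 2)
  seg <- segment_and_centroid(img)
  r_o <- detect_outer_boundary(seg$mask, seg$centroid)
  expect_equal(mean(r_o), 120, tolerance = 1 / 120)
  expect_lt(sd(r_o), 1)

  # annulus: outer radius unaffected by the hollow core (mask fills holes)
  ann <- section_image(list(hypoxia = annulus_mat(301, 151, 151, 50, 120, 0.9)), 2)
  sega <- segment_and_centroid(ann)
  r_oa <- detect_outer_boundary(sega$mask, sega$centroid)
  expect_equal(mean(r_oa), 120, tolerance = 1 / 120)

  # ellipse a = 120, b = 100: per-angle r_o spans [b, a], mean in between
  ell <- section_image(list(hypoxia = ellipse_mat(301, 151, 151, 120, 100, 0.9)), 2)
  sege <- segment_and_centroid(ell)
  r_oe <- detect_outer_boundary(sege$mask, sege$centroid)
  expect_gt(min(r_oe), 99)
  expect_lt(max(r_oe), 121)
  expect_gt(mean(r_oe), 100)
  expect_lt(mean(r_oe), 120)
  # oracle: ellipse radial function r(theta) = ab/sqrt((b cos)^2 + (a sin)^2)
  th <- (0:359) * pi / 180
  oracle <- 120 * 100 / sqrt((100 * cos(th))^2 + (120 * sin(th))^2)
  expect_lt(max(abs(r_oe - oracle)), 1)
})

test_that("anoxic boundary: annulus inner radius, no-core disc, rotation", {
  ann <- section_image(list(hypoxia = annulus_mat(301, 151, 151, 50, 120, 0.9)), 2)
  seg <- segment_and_centroid(ann)
  r_n <- detect_anoxic_boundary(ann, seg$centroid)
  expect_equal(mean(r_n), 50, tolerance = 1 / 50)
  expect_lt(sd(r_n), 1)

  # fully stained disc: stain present at the centroid, r_n = 0
  disc <- section_image(list(hypoxia = disc_mat(301, 151, 151, 120, 0.9)), 2)
  segd <- segment_and_centroid(disc)
  rays <- measure_section(disc, interface = FALSE)
  expect_true(all(rays$r_n_px == 0))

  # rotating the image by 90 degrees leaves the mean r_n unchanged within 1%
  ann_ch <- annulus_mat(301, 141, 161, 50, 120, 0.9) # off-centre on purpose
  img <- section_image(list(hypoxia = ann_ch), 2)
  img90 <- section_image(list(hypoxia = rot90(ann_ch)), 2)
  m1 <- measure_section(img, interface = FALSE)
  m2 <- measure_section(img90, interface = FALSE)
  expect_equal(mean(m2$r_n_px), mean(m1$r_n_px), tolerance = 0.01)
  expect_equal(mean(m2$r_o_px), mean(m1$r_o_px), tolerance = 0.01)
})

test_that("stain interface: two-annulus transition, artefact exclusion, swap", {
  n <- 301; cx <- 151
  hyp <- annulus_mat(n, cx, cx, 40, 80, 0.9)
  pro <- annulus_mat(n, cx, cx, 80, 120, 0.9)
  img <- section_image(list(hypoxia = hyp, proliferation = pro), 2)
  seg <- segment_and_centroid(img)
  r_o <- detect_outer_boundary(seg$mask, seg$centroid)
  r_n <- detect_anoxic_boundary(img, seg$centroid)
  int <- detect_stain_interface(img, seg$centroid, r_o, r_n)
  expect_equal(mean(int$r_interface, na.rm = TRUE), 80, tolerance = 2 / 80)

  # a detached hypoxia-stain blob beyond r_o forces detections outside the
  # spheroid that must be excluded on the rays it touches
  hyp2 <- hyp + disc_mat(n, cx + 135, cx, 5, 0.9)
  img2 <- section_image(list(hypoxia = pmin(hyp2, 1), proliferation = pro), 2)
  int2 <- detect_stain_interface(img2, seg$centroid, r_o, r_n)
  hit <- which(int2$excluded == "beyond_r_o")
  expect_gt(length(hit), 0)
  expect_true(all(is.na(int2$r_interface[hit])))
  # unaffected rays still measure the true interface
  expect_equal(mean(int2$r_interface, na.rm = TRUE), 80, tolerance = 2 / 80)

  # swapping the channel roles leaves no inside-out crossing to detect
  expect_error(
    detect_stain_interface(img, seg$centroid, r_o, r_n,
                           hypoxia = "proliferation", proliferation = "hypoxia"),
    class = "spheroido2_measurement")
})

test_that("threshold robustness: +/-20% threshold moves mean radii < 2%", {
  sp <- synthetic_spheroid_spec(r_o_um = 300, seed = 11, jitter_um = 0,
                                noise_sd = 0, n_artifacts = 0, ellipticity = 1)
  img <- render_section(sp)$image
  base <- segment_and_centroid(img)
  means <- sapply(c(0.8, 1, 1.2) * base$threshold, function(thr) {
    seg <- segment_and_centroid(img, threshold = thr)
    c(r_o = mean(detect_outer_boundary(seg$mask, seg$centroid)),
      r_n = mean(detect_anoxic_boundary(img, seg$centroid, threshold = thr)))
  })
  expect_lt(max(abs(means["r_o", c(1, 3)] / means["r_o", 2] - 1)), 0.02)
  expect_lt(max(abs(means["r_n", c(1, 3)] / means["r_n", 2] - 1)), 0.02)
})

test_that("ray summaries: arithmetic and degenerate cases", {
  rays <- structure(list(
    angles_deg = 0:359,
    r_o_px = c(100, 120, rep(NA, 358)),
    r_n_px = rep(40, 360),
    r_interface_px = rep(NA_real_, 360),
    excluded = rep(NA_character_, 360),
    centroid = c(x = 1, y = 1), threshold = 0.5, scale = 1),
    class = "ray_measurements")
  s <- summarize_rays(rays, scale = 1)
  expect_equal(s$mean_um[s$quantity == "r_o"], 110)
  expect_equal(s$sd_um[s$quantity == "r_o"], 10) # population s.d.
  expect_equal(s$n_rays[s$quantity == "r_o"], 2L)
  expect_equal(s$sd_um[s$quantity == "r_n"], 0)
  # mean r_c = mean r_o - mean r_n on the common valid rays
  expect_equal(s$mean_um[s$quantity == "r_c"], 70)
  # scale conversion
  s2 <- summarize_rays(rays, scale = 2.5)
  expect_equal(s2$mean_um[s2$quantity == "r_o"], 275)
  # no valid rays at all -> measurement error
  rays$r_o_px <- rep(NA_real_, 360)
  expect_error(summarize_rays(rays, scale = 1),
               class = "spheroido2_measurement")
})

test_that("otsu threshold separates a bimodal intensity distribution", {
  x <- c(rnorm(4000, 0.1, 0.03), rnorm(1000, 0.8, 0.05))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.7)
  expect_equal(otsu_threshold(rep(0.4, 100)), 0.4)
})
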