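test_that("physical_params validates fields and reports geometry", {
  p <- physical_params()
  expect_s3_class(p, "physical_params")
  # geometric prolate volume (pi/6) a_major a_minor^2 ~ 0.33 mL
  expect_equal(p$v_geom, (pi / 6) * 16e-3 * (6.3e-3)^2)
  expect_error(physical_params(c0 = -1), "c0")
  expect_error(physical_params(a_major = 3e-3, a_minor = 6.3e-3), "prolate")
  expect_warning(physical_params(depth_l = 1e-3), "burial")
  # V derived from the axes agrees with the geometric volume exactly
  pg <- physical_params(V = NULL)
  expect_equal(pg$V, pg$v_geom)
})

test_that("initial condition: the capsule starts at its uniform density", {
  pg <- physical_params(V = NULL, c0 = 100)
  center <- c(0, 0, pg$depth_l)
  # t = 0 exactly: c0 inside, 0 outside, c0/2 on the boundary
  expect_equal(capsule_concentration(pg, center, 0), 100)
  expect_equal(capsule_concentration(pg, c(0, 0, 0), 0), 0)
  expect_equal(capsule_concentration(
    pg, c(0, 0, pg$depth_l - pg$a_minor / 2), 0), 50)
  # t -> 0+: quadrature recovers the initial value at the center within 1%
  expect_equal(capsule_concentration(pg, center, 20), 100, tolerance = 0.01)
})

test_that("far-field capsule concentration matches an equivalent point source", {
  pg <- physical_params(V = NULL, c0 = 100)
  t <- 2e6                      # kernel width ~ 89 mm >> capsule
  probe <- c(150e-3, 0, pg$depth_l)
  cc <- capsule_concentration(pg, probe, t, "free_interface")
  cp <- point_source_free(pg$c0 * pg$V, c(0, 0, pg$depth_l), probe, pg$D, t)
  expect_equal(cc, cp, tolerance = 0.01)
})

test_that("free-interface field conserves the capsule's total moles", {
  p <- betaine_params()
  M <- p$c0 * p$V
  for (t in c(60, 600, 1800))
    expect_equal(field_mass(p, t, "free_interface"), M, tolerance = 5e-3)
  # absorbing interface: mass strictly decreasing, never above M
  md <- vapply(c(60, 600, 1800), function(t) field_mass(p, t, "dirichlet"),
               numeric(1))
  expect_true(all(diff(md) < 0))
  expect_true(all(md <= M * (1 + 5e-3)))
})

test_that("scenario ordering: absorbing boundary never exceeds the free field in sand", {
  p <- betaine_params()
  set.seed(21)
  P <- cbind(runif(40, -12e-3, 12e-3), runif(40, -8e-3, 8e-3),
             runif(40, 0, 12e-3))
  for (t in c(120, 900)) {
    vf <- capsule_concentration(p, P, t, "free_interface")
    vd <- capsule_concentration(p, P, t, "dirichlet")
    expect_true(all(vd <= vf * (1 + 1e-3) + 1e-6 * max(vf)))
    expect_true(all(vd >= -1e-6 * max(vf)))
  }
  # identically zero on the interface
  P0 <- cbind(seq(-5e-3, 5e-3, length.out = 7), 0, 0)
  expect_true(all(abs(capsule_concentration(p, P0, 600, "dirichlet")) <=
                    1e-12 * max(capsule_concentration(p, P0, 600,
                                                      "free_interface"))))
})

test_that("surface-layer profile peaks above the capsule and starts sub-threshold", {
  p <- betaine_params()
  xg <- seq(-10e-3, 10e-3, length.out = 9)
  prof <- surface_layer_profile(p, xg, xg, c(30, 600), "free_interface")
  expect_s3_class(prof, "concentration_field")
  # early transient: burial depth >> diffusion length => everything below c*
  expect_true(all(prof$values[1, , , ] < p$c_star))
  # late: the horizontal maximum sits at the capsule center (0, 0)
  late <- prof$values[2, 1, , ]
  peak_idx <- which(late == max(late), arr.ind = TRUE)
  expect_equal(unname(peak_idx[1, ]), c(5, 5))
  # free interface dominates the absorbing scenario pointwise
  prof_d <- surface_layer_profile(p, xg, xg, c(30, 600), "dirichlet")
  expect_true(all(prof_d$values <= prof$values * (1 + 1e-3) +
                    1e-6 * max(prof$values)))
  expect_error(surface_layer_profile(p, numeric(0), xg, 600), "empty")
})

test_that("onset detection: threshold crossings ordered by capsule concentration", {
  p <- betaine_params()
  onsets <- vapply(c(1, 10, 100), function(c0) {
    p$c0 <- c0
    r <- detect_onset(p, "free_interface")
    expect_true(r$detected_within_t_max)
    expect_gte(r$peak_surface_conc, r$c_star)
    r$onset_time
  }, numeric(1))
  expect_true(all(diff(onsets) < 0))
  expect_true(all(onsets > 0 & onsets <= p$t_max))
  # unreachable threshold
  p$c0 <- 100
  p$c_star <- 1e6
  r <- detect_onset(p, "free_interface")
  expect_false(r$detected_within_t_max)
  expect_true(is.na(r$onset_time))
})

test_that("detectability sweep is monotone in concentration and depth", {
  p <- betaine_params()
  dm <- detectability_map(p, c0_list = c(1, 100),
                          depth_list = c(5e-3, 8e-3, 12e-3),
                          scenario = "free_interface")
  df <- as.data.frame(dm)
  expect_equal(nrow(df), 6L)
  # detected region is monotone: richer and shallower stays detected
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (df$detected[i] && df$c0[j] >= df$c0[i] &&
        df$depth_l[j] <= df$depth_l[i])
      expect_true(df$detected[j])
  }
  # onset non-decreasing with depth at fixed c0
  for (c0 in unique(df$c0)) {
    sub <- df[df$c0 == c0, ]
    on <- sub$onset_time[order(sub$depth_l)]
    on <- on[!is.na(on)]
    if (length(on) > 1) expect_true(all(diff(on) >= 0))
  }
  # a single-entry sweep reduces to detect_onset
  single <- detectability_map(p, 100, 5e-3, "free_interface")
  p1 <- p; p1$c0 <- 100; p1$depth_l <- 5e-3
  direct <- detect_onset(p1, "free_interface")
  expect_equal(single[[1]]$onset_time, direct$onset_time)
})

test_that("concentration_field validates its grid and round-trips as CSV", {
  p <- betaine_params()
  fld <- capsule_field(p, x = c(-2e-3, 0, 2e-3), y = c(0, 1e-3),
                       z = c(1e-3, 3e-3), times = c(600),
                       scenario = "free_interface")
  df <- as.data.frame(fld)
  expect_equal(nrow(df), 12L)
  expect_named(df, c("scenario", "t", "x", "y", "z", "c"))
  # values indexed consistently: direct evaluation agrees
  direct <- capsule_concentration(p, c(2e-3, 1e-3, 3e-3), 600)
  expect_equal(df$c[df$x == 2e-3 & df$y == 1e-3 & df$z == 3e-3], direct,
               tolerance = 1e-6)
  path <- tempfile(fileext = ".csv")
  write_field_csv(fld, path)
  expect_equal(read_field_csv(path)$c, df$c, tolerance = 1e-12)
  expect_error(concentration_field(list(x = 1, y = 1, z = 1, t = 1),
                                   array(-1, c(1, 1, 1, 1))), "negative")
})
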