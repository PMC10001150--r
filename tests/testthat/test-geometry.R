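test_that("limacon radius and profile points match closed forms", {
  circ <- limacon_params(10)
  expect_equal(limacon_radius(circ, c(0, 1, pi, 4.7)), rep(10, 4))
  p <- limacon_params(11, 1.5, 0.5)
  expect_equal(limacon_radius(p, 0), 13)
  expect_equal(limacon_radius(p, pi / 2), 11, tolerance = 1e-12)

  expect_equal(profile_point(limacon_params(10, mx = 2), 0)[1, ],
               c(x_mm = 12, y_mm = 0))
  expect_equal(profile_point(limacon_params(10), pi / 2)[1, ],
               c(x_mm = 0, y_mm = 10), tolerance = 1e-12)
  expect_equal(profile_point(limacon_params(11, 1.5, 0.5, mx = 1), pi)[1, ],
               c(x_mm = -8, y_mm = 0), tolerance = 1e-12)
})

test_that("polar conversion matches hand values, rejects the centre and round-trips", {
  expect_equal(polar_convert(cbind(5, 0), mx = 1)[1, ],
               c(r_mm = 4, phi_hat = 0))
  expect_equal(polar_convert(cbind(1, 3), mx = 1)[1, ],
               c(r_mm = 3, phi_hat = pi / 2))
  expect_equal(polar_convert(cbind(-2, 0), mx = 0)[1, ],
               c(r_mm = 2, phi_hat = pi))
  expect_error(polar_convert(cbind(1, 0), mx = 1), "degenerate")

  # round trip: profile_point then polar_convert returns (R, phi)
  p <- limacon_params(9.7, 1.2, 0.4, mx = 0.8)
  phi <- seq(0.01, 2 * pi - 0.01, length.out = 113)
  pc <- polar_convert(profile_point(p, phi), mx = p$mx)
  expect_close(pc[, "r_mm"], limacon_radius(p, phi), 1e-12)
  expect_close(pc[, "phi_hat"], phi, 1e-10)
})

test_that("point-set validation rejects degenerate inputs", {
  expect_error(us_point_set(cbind(1:5, 1:5)), "at least 8")
  expect_error(us_point_set(cbind(1:10, 2 * (1:10))), "collinear")
  expect_error(limacon_params(5, 6, 0), "degenerate")
  expect_error(limacon_params(-1), "positive")
})

test_that("synthetic scans are deterministic, unbiased and leave the RNG alone", {
  p <- default_eye_params()
  a <- generate_synthetic_us_points(p, 64, 0.1, seed = 9)
  b <- generate_synthetic_us_points(p, 64, 0.1, seed = 9)
  expect_identical(a$points, b$points)

  noiseless <- generate_synthetic_us_points(p, 164, 0, seed = 1)
  pc <- polar_convert(noiseless, p$mx)
  expect_close(pc[, "r_mm"], limacon_radius(p, pc[, "phi_hat"]), 1e-10)

  big <- generate_synthetic_us_points(p, 1e4, 0.1, seed = 3)
  res <- polar_convert(big, p$mx)
  r_res <- res[, "r_mm"] - limacon_radius(p, res[, "phi_hat"])
  expect_lt(abs(stats::sd(r_res) / 0.1 - 1), 0.05)

  set.seed(123)
  x1 <- stats::runif(1)
  set.seed(123)
  invisible(generate_synthetic_us_points(p, 16, 0.1, seed = 77))
  expect_identical(stats::runif(1), x1)
})

test_that("fit recovers exact parameters from noiseless points", {
  truth <- limacon_params(11, 1.5, 0.5, mx = 1)
  pts <- generate_synthetic_us_points(truth, 64, 0, seed = 1)
  fit <- fit_limacon(pts)
  expect_true(fit$converged)
  expect_lt(fit$max_abs_residual, 1e-8)
  expect_close(unlist(fit$params[c("q1", "q2", "q3", "mx")]),
               c(11, 1.5, 0.5, 1), 1e-6)
})

test_that("fitted objective beats a brute-force parameter grid", {
  truth <- limacon_params(10, 1, 0.5, mx = 0.5)
  pts <- generate_synthetic_us_points(truth, 64, 0.1, seed = 7)
  fit <- fit_limacon(pts)
  obj <- function(q1, q2, q3, mx) {
    pc <- polar_convert(pts, mx)
    cp <- cos(pc[, "phi_hat"])
    sum((pc[, "r_mm"] - (q1 + q2 * cp + q3 * cp^3))^2)
  }
  fitted_obj <- sum(fit$residuals^2)
  # 20^4 grid spanning +-20% around the true parameters
  grid1 <- function(v) seq(0.8 * v, 1.2 * v, length.out = 20)
  best <- Inf
  for (mx in grid1(0.5)) {
    pc <- polar_convert(pts, mx)
    cp <- cos(pc[, "phi_hat"])
    X <- cbind(1, cp, cp^3)
    th <- as.matrix(expand.grid(grid1(10), grid1(1), grid1(0.5)))
    pred <- X %*% t(th)
    best <- min(best, min(colSums((pc[, "r_mm"] - pred)^2)))
  }
  expect_lte(fitted_obj, best)
})

test_that("fit is idempotent and keeps the profile positive", {
  truth <- limacon_params(10.5, 0.8, 0.6, mx = -0.4)
  fit1 <- fit_limacon(generate_synthetic_us_points(truth, 96, 0.15, seed = 5))
  regen <- generate_synthetic_us_points(fit1$params, 96, 0, seed = 1)
  fit2 <- fit_limacon(regen)
  expect_close(unlist(fit2$params[1:4]), unlist(fit1$params[1:4]), 1e-6)
  expect_gt(min(limacon_radius(fit2$params, seq(0, 2 * pi, length.out = 721))),
            0)
})

test_that("ultrasound CSV and geometry YAML round-trip", {
  pts <- generate_synthetic_us_points(default_eye_params(), 32, 0.05, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_us_points(pts, f)
  back <- read_us_points(f)
  expect_close(back$points, pts$points, 1e-9)

  shipped <- system.file("extdata", "synthetic_us_points.csv",
                         package = "eyevit")
  expect_equal(nrow(read_us_points(shipped)$points), 164)

  g <- withr::local_tempfile(fileext = ".yaml")
  write_geometry_yaml(default_eye_params(), g,
                      boundary_spec = default_boundary_spec())
  back2 <- read_geometry_yaml(g)
  expect_close(unlist(back2$params[1:4]), unlist(default_eye_params()[1:4]),
               1e-12)
  expect_equal(back2$boundary_spec$lens_half, 30)
})

test_that("domain partition covers the circle with sane defaults", {
  dom <- fx("dom")
  am <- arc_measures(dom)
  expect_gt(am[["retina"]], am[["lens"]])
  expect_gt(am[["lens"]], 0)
  expect_equal(sum(am), 2 * pi)
  # macula lies on the profile curve
  pc <- polar_convert(rbind(dom$macula_center_mm[1:2]), dom$params$mx)
  expect_lt(abs(pc[, "r_mm"] - limacon_radius(dom$params, pc[, "phi_hat"])),
            1e-9)
  expect_error(boundary_spec(120, 50), NA)
  expect_error(boundary_spec(120, 80))           # does not fit on the circle
  expect_error(build_domain(default_eye_params(), macula_offset_deg = 155),
               "retina")
})
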