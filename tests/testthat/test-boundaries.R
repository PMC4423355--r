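test_that("clamped spline has zero end slopes and interpolates its points", {
  f <- clamped_spline(c(10, 20, 30), c(200, 100, 0))
  expect_lt(abs(f(10, deriv = 1)), 1e-9)
  expect_lt(abs(f(30, deriv = 1)), 1e-9)
  expect_equal(f(c(10, 20, 30)), c(200, 100, 0), tolerance = 1e-12)
})

test_that("clamped spline contract holds across a seeded sweep", {
  set.seed(21)
  for (i in 1:100) {
    x <- sort(runif(3, 0, 500))
    while (min(diff(x)) < 1) x <- sort(runif(3, 0, 500))
    y <- runif(3, 0, 255)
    f <- clamped_spline(x, y)
    expect_lt(abs(f(x[1], deriv = 1)), 1e-9)
    expect_lt(abs(f(x[3], deriv = 1)), 1e-9)
    expect_equal(f(x), y, tolerance = 1e-9)
  }
})

test_that("emitted fits are monotone between plateaus without overshoot", {
  set.seed(22)
  for (i in 1:50) {
    el <- seq(0, 100, by = 0.25)
    p <- runif(1, 25, 75); w <- runif(1, 3, 10)
    lo <- runif(1, 0, 60); hi <- lo + runif(1, 60, 190)
    rising <- runif(1) < 0.5
    s <- plogis(el, location = p, scale = w / (2 * log(19)))
    if (!rising) s <- 1 - s
    prof <- data.frame(x = seq_along(el),
                       intensity = pmin(pmax(lo + (hi - lo) * s +
                                               rnorm(length(el), 0, 2), 0), 255),
                       pct_el = el)
    wins <- detect_boundary_windows(prof, min_amplitude = 30)
    expect_gte(length(wins), 1L)
    fit <- fit_clamped_boundary(prof, wins[[1]])
    cp <- fit$control_points
    vals <- fit$fun(seq(cp$x[1], cp$x[3], length.out = 200))
    expect_lte(max(vals), max(cp$y[1], cp$y[3]) + 1)
    expect_gte(min(vals), min(cp$y[1], cp$y[3]) - 1)
    expect_true(all(diff(vals) * sign(cp$y[3] - cp$y[1]) >= -1))
  }
})

test_that("a single domain yields one rising and one falling window", {
  el <- seq(0, 100, by = 0.25)
  b <- single_domain_boundaries(35, 60, 6)
  s <- blastoquant:::stain_strength(
    domain_spec("gt", b), el)
  prof <- data.frame(x = seq_along(el), R = 0, G = 0, B = 0,
                     intensity = 200 * s, pct_el = el)
  wins <- detect_boundary_windows(prof, min_amplitude = 30)
  expect_length(wins, 2L)
  expect_identical(vapply(wins, `[[`, "", "direction"),
                   c("rising", "falling"))
})

test_that("flat or sub-threshold profiles give no windows", {
  flat <- data.frame(x = 1:200, intensity = 0)
  expect_length(detect_boundary_windows(flat), 0L)
  small <- data.frame(x = 1:200,
                      intensity = 10 * sin(seq(0, 6 * pi, length.out = 200)))
  expect_length(detect_boundary_windows(small, min_amplitude = 30), 0L)
})

test_that("noise-free synthetic boundary is recovered at 45 +- 0.5 %EL, width 6 +- 1", {
  ge <- full_embryo(boundaries = single_domain_boundaries(45, 75, 6))
  q <- quantify_to_fits(ge)
  expect_length(q$fits, 2L)
  pw <- position_and_width(q$fits[[1]], q$mask)
  expect_lt(abs(pw[["position_pct_el"]] - 45), 0.5)
  expect_lt(abs(pw[["width_pct_el"]] - 6), 1)
})

test_that("noisy profiles (sigma 8) keep mean absolute position error <= 1 %EL", {
  set.seed(31)
  errs <- replicate(50, {
    el <- seq(0, 100, by = 0.2)
    s <- blastoquant:::stain_strength(
      domain_spec("gt", single_domain_boundaries(45, 70, 6)), el)
    prof <- data.frame(x = seq_along(el), R = 0, G = 0, B = 0,
                       intensity = pmin(pmax(45 + 150 * s +
                                               rnorm(length(el), 0, 8), 0), 255),
                       pct_el = el)
    wins <- detect_boundary_windows(prof, min_amplitude = 30)
    fits <- lapply(wins, function(w) fit_clamped_boundary(prof, w))
    pos <- vapply(fits, function(f)
      el[which.min(abs(seq_along(el) - f$control_points$x[2]))], numeric(1))
    min(abs(pos - 45))
  })
  expect_lte(mean(errs), 1)
})

test_that("ambiguous (non-monotone) windows are rejected", {
  x <- 1:100
  prof <- data.frame(x = x, intensity = 100 * sin(x / 8)^2)
  expect_error(
    fit_clamped_boundary(prof, list(x_lo = 1, x_hi = 100,
                                    direction = "rising")),
    "ambiguous boundary")
})

test_that("manual control-point overrides are used verbatim", {
  prof <- data.frame(x = 1:50, intensity = 0)
  ov <- data.frame(x = c(5, 20, 40), y = c(10, 100, 190))
  fit <- fit_clamped_boundary(prof, list(x_lo = 5, x_hi = 40,
                                         direction = "rising"),
                              overrides = ov)
  expect_equal(fit$control_points$x, ov$x)
  expect_equal(fit$control_points$y, ov$y)
  expect_true(fit$converged)
})

test_that("position is the mid point %EL and width the outer span", {
  mask <- exact_height_mask(120)
  x_min <- mask$bbox[["c1"]]; x_max <- mask$bbox[["c2"]]
  ov <- data.frame(x = c(x_min, (x_min + x_max) / 2, x_max), y = c(0, 50, 100))
  fit <- fit_clamped_boundary(data.frame(x = 1, intensity = 0),
                              list(x_lo = x_min, x_hi = x_max,
                                   direction = "rising"), overrides = ov)
  pw <- position_and_width(fit, mask)
  expect_equal(pw[["position_pct_el"]], 50)
  expect_equal(pw[["width_pct_el"]], 100)
  # symmetric shrink about the midpoint leaves the position unchanged
  ov2 <- data.frame(x = c(ov$x[2] - 30, ov$x[2], ov$x[2] + 30),
                    y = c(0, 50, 100))
  fit2 <- fit_clamped_boundary(data.frame(x = 1, intensity = 0),
                               list(x_lo = ov2$x[1], x_hi = ov2$x[3],
                                    direction = "rising"), overrides = ov2)
  expect_equal(position_and_width(fit2, mask)[["position_pct_el"]], 50)
})

test_that("gt fits are assigned IDs 2, 5, 6, 7 in A-P order", {
  mkfit <- function(x2) {
    fit_clamped_boundary(data.frame(x = 1, intensity = 0),
                         list(x_lo = x2 - 10, x_hi = x2 + 10,
                              direction = "rising"),
                         overrides = data.frame(x = c(x2 - 10, x2, x2 + 10),
                                                y = c(0, 50, 100)))
  }
  fits <- lapply(c(300, 120, 450, 210), mkfit) # deliberately unordered
  out <- assign_boundary_ids(fits, "gt")
  expect_identical(vapply(out, `[[`, 1L, "boundary_id"), c(2L, 5L, 6L, 7L))
  expect_identical(vapply(out, `[[`, "", "facing"),
                   c("posterior", "anterior", "posterior", "anterior"))
  expect_true(all(vapply(out, `[[`, TRUE, "assigned")))

  expect_identical(assign_boundary_ids(list(), "gt"), list())
  expect_warning(out3 <- assign_boundary_ids(fits[1:3], "gt"), "flagged")
  expect_identical(vapply(out3, `[[`, 1L, "boundary_id"), c(2L, 5L, 6L))
  expect_error(assign_boundary_ids(fits, "nonexistent_gene"), "catalogue knows")
})
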