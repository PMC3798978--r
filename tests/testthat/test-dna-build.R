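test_that("step transforms reproduce their parameters on re-extraction", {
  set.seed(11)
  for (k in 1:25) {
    p <- step_params(shift = runif(1, -1.5, 1.5), slide = runif(1, -1.5, 1.5),
                     rise = runif(1, 2.8, 4), tilt = runif(1, -12, 12),
                     roll = runif(1, -25, 25), twist = runif(1, 20, 45))
    m <- build_duplex("NN", p)
    p2 <- analyze_duplex(m)
    expect_lt(max(abs(as.matrix(p2) - as.matrix(p))), 1e-9)
  }
  # pure-rise step is a pure translation along local z
  tr <- step_transform(step_params(twist = 0, rise = 3.4))
  expect_equal(tr$translation, c(0, 0, 3.4), tolerance = 1e-12)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  # generic B-DNA step: rotation about local z plus the rise
  tr2 <- step_transform(step_params(twist = 34.2, rise = 3.4))
  expect_equal(tr2$translation, c(0, 0, 3.4), tolerance = 1e-12)
  expect_equal(acos((sum(diag(tr2$rotation)) - 1) / 2) * 180 / pi, 34.2,
               tolerance = 1e-9)
})

test_that("build/analyze round trip is the identity on random step tables", {
  set.seed(21)
  for (k in 1:100) {
    n <- sample(3:9, 1)
    P <- step_params(shift = runif(n, -1, 1), slide = runif(n, -1, 1),
                     rise = runif(n, 3, 3.8), tilt = runif(n, -10, 10),
                     roll = runif(n, -20, 20), twist = runif(n, 22, 42))
    m <- build_duplex(strrep("A", n + 1), P)
    expect_lt(max(abs(as.matrix(analyze_duplex(m)) - as.matrix(P))), 1e-6)
  }
})

test_that("straight helices obey the closed-form end-to-end distance", {
  m <- build_duplex(strrep("G", 11), step_params()[rep(1, 10), ])
  ax <- axis_curve(m)
  expect_equal(nrow(ax), 11)
  expect_equal(sqrt(sum((ax[11, ] - ax[1, ])^2)), 34.0, tolerance = 1e-9)
  # cumulative helical rotation 10 x 34.2 degrees
  steps <- analyze_duplex(m)
  expect_equal(sum(steps$twist), 342, tolerance = 1e-6)
  expect_lt(max(abs(steps$roll)), 1e-9)
  expect_lt(max(abs(steps$tilt)), 1e-9)
  # collinear axis
  d <- sweep(ax, 2, ax[1, ])
  expect_lt(max(abs(d[, 1:2])), 1e-9)
})

test_that("building is equivariant under rotation of the starting frame", {
  set.seed(5)
  P <- step_params(roll = runif(6, -15, 15), tilt = runif(6, -8, 8),
                   twist = runif(6, 25, 40), rise = 3.4)
  m1 <- build_duplex(strrep("T", 7), P)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- build_duplex(strrep("T", 7), P, origin = c(3, -2, 1), orientation = R)
  d1 <- dist(axis_curve(m1)); d2 <- dist(axis_curve(m2))
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("invalid inputs are rejected", {
  expect_error(build_duplex("ACGTA", step_params()[rep(1, 3), ]), "steps")
  expect_error(build_duplex("ACXGT", step_params()[rep(1, 4), ]), "nucleotide")
  expect_error(step_params(rise = -1), "rise")
  expect_error(step_params(twist = 200), "twist")
  expect_error(analyze_duplex(build_duplex("A", step_params()[0, ])), "at least 2")
})

test_that("the composed enhancer is 65 bp with site centers 47 bp apart", {
  spec <- fixture_spec()
  steps <- compose_enhancer_params(make_fis_site_params(spec), step_params())
  expect_equal(nrow(steps), 64)
  lay <- enhancer_layout()
  expect_equal(lay$site2_center - lay$site1_center, 47)
  m <- build_duplex(strrep("N", 65), steps)
  expect_equal(length(m$frames), 65)
  # straight blocks give a globally straight model
  st2 <- compose_enhancer_params(step_params()[rep(1, 20), ], step_params())
  ax <- axis_curve(build_duplex(strrep("N", 65), st2))
  expect_lt(max(abs(sweep(ax, 2, ax[1, ])[, 1:2])), 1e-6)
})

test_that("the bent enhancer is a non-planar S: bend planes rotated by the intervening twist", {
  spec <- fixture_spec()
  m <- build_duplex(strrep("N", 65),
                    compose_enhancer_params(make_fis_site_params(spec), step_params()))
  ax <- axis_curve(m)
  lay <- enhancer_layout()
  bend_normal <- function(ctr) {
    t_in <- ax[ctr - 6, ] - ax[ctr - 8, ]
    t_out <- ax[ctr + 8, ] - ax[ctr + 6, ]
    v <- c(t_in[2] * t_out[3] - t_in[3] * t_out[2],
           t_in[3] * t_out[1] - t_in[1] * t_out[3],
           t_in[1] * t_out[2] - t_in[2] * t_out[1])
    v / sqrt(sum(v^2))
  }
  n1 <- bend_normal(lay$site1_center); n2 <- bend_normal(lay$site2_center)
  dihedral <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  # the intervening twist rotates the second bend plane far out of the first
  expect_gt(dihedral, 60)
  # and the full axis is strongly non-planar (S, not C)
  ctr <- colMeans(ax)
  expect_gt(svd(sweep(ax, 2, ctr))$d[3], 10)
})

test_that("step tables survive a text round trip", {
  p <- step_params(shift = c(0.3, -0.2), slide = c(0.1, 0), rise = c(3.3, 3.5),
                   tilt = c(2, -3), roll = c(8, -5), twist = c(31, 36))
  f <- tempfile(fileext = ".txt")
  write_step_params(p, f)
  p2 <- read_step_params(f)
  expect_equal(as.matrix(p2), as.matrix(p), tolerance = 1e-6,
               ignore_attr = TRUE)
})
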