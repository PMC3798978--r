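test_that("superposition recovers a known rigid motion", {
  set.seed(7)
  p <- matrix(rnorm(36, 0, 10), 12, 3)
  expect_equal(superpose(p, p)$rmsd, 0, tolerance = 1e-9)
  expect_equal(superpose(p, p)$transform$rotation, diag(3), tolerance = 1e-9)
  for (k in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, -pi, pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    d <- rnorm(3, 0, 5)
    q <- t(R %*% t(p) + d)
    fit <- superpose(p, q)
    expect_lt(fit$rmsd, 1e-6)
    expect_lt(max(abs(fit$transform$rotation - R)), 1e-6)
    expect_lt(max(abs(fit$transform$translation - d)), 1e-6)
  }
})

test_that("superposition stays proper on mirror images and is motion-invariant", {
  set.seed(8)
  p <- matrix(rnorm(30, 0, 5), 10, 3)   # chiral in general
  q <- p; q[, 1] <- -q[, 1]
  fit <- superpose(p, q)
  expect_gt(det(fit$transform$rotation), 0)
  expect_gt(fit$rmsd, 0.1)
  # common rigid motion of both sets leaves the rmsd unchanged
  th <- 1.2; R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  mv <- function(x) t(R %*% t(x) + c(4, 5, 6))
  expect_equal(superpose(mv(p), mv(q))$rmsd, fit$rmsd, tolerance = 1e-9)
  expect_error(superpose(p, p[1:9, ]), "equal length")
  expect_error(superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)), "degenerate")
})

test_that("reference-pose docking seats the activator on its site", {
  comp <- make_toy_components(fixture_spec(), "cleaved")
  lay <- comp$layout
  half <- (lay$core_bp - 1) %/% 2
  site1 <- c(lay$site1_center - half, lay$site1_center + half)
  f1 <- dock_on_site(comp$fis, comp$enhancer, site1, comp$pose)
  prox <- rbind(comp$enhancer$backbone$top, comp$enhancer$backbone$bottom)
  for (l in c("A:98", "B:98")) {
    d <- min(sqrt(rowSums(sweep(prox, 2, landmark_xyz(f1, l))^2)))
    expect_lt(d, 6)
  }
  # both dimers docked: no clash
  site2 <- c(lay$site2_center - half, lay$site2_center + half)
  f2 <- dock_on_site(comp$fis, comp$enhancer, site2, comp$pose)
  d2 <- as.matrix(dist(rbind(f1$xyz, f2$xyz)))
  n <- nrow(f1$xyz)
  expect_gt(min(d2[1:n, (n + 1):(2 * n)]), 0.5)
  expect_error(dock_on_site(comp$fis, comp$enhancer, c(60, 80), comp$pose),
               "out of range")
})

test_that("constraint refinement is deterministic and never worsens the score", {
  a <- assembly_state("cleaved")
  # hand-perturb one subunit by a known 5 A offset
  bad <- a
  bad$hin$hix1L <- apply_transform(bad$hin$hix1L,
                                   rigid_transform(diag(3), c(5, 0, 0)))
  cs <- default_crosslink_set()
  s0 <- invertasome:::crosslink_score(bad, cs)
  expect_gt(s0, 0)
  r1 <- refine_by_constraints(bad, cs, max_iter = 150, seed = 42)
  r2 <- refine_by_constraints(bad, cs, max_iter = 150, seed = 42)
  expect_lt(r1$score, s0)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$assembly$hin$hix1L$xyz, r2$assembly$hin$hix1L$xyz)
  # already-satisfied assemblies are returned unchanged at score 0
  r0 <- refine_by_constraints(a, cs, max_iter = 10, seed = 1)
  expect_identical(r0$score, 0)
  expect_identical(r0$assembly$hin$hix1L$xyz, a$hin$hix1L$xyz)
})
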