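test_that("Fis arms contact only the enhancer-proximal subunit pair", {
  for (st in c("cleaved", "pre_cleaved", "dimer_docked")) {
    a <- assembly_state(st)
    lm <- assembly_landmarks(a)
    d <- function(x, y) sqrt(sum((lm[[x]] - lm[[y]])^2))
    cutoff <- a$contact_cutoff
    expect_lt(d("Fis1:B:21", "Hin:hix1L:155"), cutoff)
    expect_lt(d("Fis2:A:21", "Hin:hix2R:155"), cutoff)
    expect_gt(d("Fis1:B:21", "Hin:hix1R:155"), cutoff)
    expect_gt(d("Fis2:A:21", "Hin:hix2L:155"), cutoff)
  }
})

test_that("helix-B approaches the enhancer monotonically through the states", {
  hb_dist <- function(a) {
    lm <- assembly_landmarks(a)
    prox <- rbind(a$enhancer$backbone$top, a$enhancer$backbone$bottom)
    min(vapply(paste0("Hin:hix1L:", c(47, 48, 51)), function(l) {
      min(sqrt(rowSums(sweep(prox, 2, lm[[l]])^2)))
    }, numeric(1)))
  }
  d_clv <- hb_dist(assembly_state("cleaved"))
  d_pre <- hb_dist(assembly_state("pre_cleaved"))
  d_dim <- hb_dist(assembly_state("dimer_docked"))
  expect_lte(d_clv, d_pre)
  expect_lte(d_pre, d_dim)
  # contact only in the cleaved state
  expect_lt(d_clv, 6)
  expect_gt(d_pre, 6)
  expect_gt(d_dim, 6)
})

test_that("the packaged crosslink set is satisfied on the cleaved fixture", {
  a <- assembly_state("cleaved")
  rep <- crosslink_report(a)
  expect_true(all(rep$satisfied))
  pos <- rep[rep$observed == "crosslinked", ]
  neg <- rep[rep$observed == "not_crosslinked", ]
  expect_true(all(pos$distance <= pos$spacer + 3))
  expect_true(all(neg$distance > neg$spacer + 3))
})

test_that("crosslink compatibility follows the distance rule", {
  a <- assembly_state("cleaved")
  near <- crosslink_constraints("Fis1:B:21", "Hin:hix1L:155", 4.4, "crosslinked")
  res <- crosslink_compatibility(a, near)
  expect_true(res$satisfied)
  far <- crosslink_constraints("Fis1:B:21", "Hin:hix2L:155", 1.5, "crosslinked")
  expect_false(crosslink_compatibility(a, far)$satisfied)
  expect_error(crosslink_compatibility(a,
    crosslink_constraints("Fis1:B:21", "Hin:hix1L:999", 8, "crosslinked")),
    "missing")
})

test_that("tethered-nuclease footprints fall where the contacts place them", {
  a <- assembly_state("cleaved")
  lay <- a$layout
  half <- (lay$core_bp - 1) %/% 2
  core1 <- c(lay$site1_center - half, lay$site1_center + half)
  core2 <- c(lay$site2_center - half, lay$site2_center + half)
  for (teth in c("Hin:hix1L:54", "Hin:hix2R:54")) {
    fp <- predict_febabe_footprint(a, teth)
    expect_gt(nrow(fp), 0)
    expect_true(all(fp$bp > core1[2] & fp$bp < core2[1]))
    expect_true(all(diff(fp$distance) >= 0))
  }
  fp98 <- predict_febabe_footprint(a, "Fis1:A:98")
  expect_true(all(fp98$bp <= core1[2] + 1))
  fp98b <- predict_febabe_footprint(a, "Fis2:B:98")
  expect_true(all(fp98b$bp >= core2[1] - 1))
})

test_that("footprints are isometry invariant and monotone in reach", {
  a <- assembly_state("cleaved")
  fp <- predict_febabe_footprint(a, "Hin:hix1L:54")
  m <- mirror_assembly(a)
  fpm <- predict_febabe_footprint(m, "Hin:hix1L:54")
  expect_equal(fpm$distance, fp$distance, tolerance = 1e-9)
  wider <- predict_febabe_footprint(a, "Hin:hix1L:54",
                                    febabe_reach(12, 14))
  expect_true(all(paste(fp$bp, fp$strand) %in% paste(wider$bp, wider$strand)))
  # out-of-reach tether finds nothing
  none <- predict_febabe_footprint(a, "Hin:hix1R:54", febabe_reach(2, 1))
  expect_equal(nrow(none), 0)
})

test_that("the basic patch contacts the enhancer only from the static pair", {
  a <- assembly_state("cleaved")
  bp1 <- basic_patch_contacts(a, "hix1L")
  expect_setequal(bp1$residue, c(47, 48, 51))
  expect_true(all(diff(bp1$distance) >= 0))
  expect_equal(nrow(basic_patch_contacts(a, "hix1R")), 0)
  expect_equal(nrow(basic_patch_contacts(a, "hix1L", cutoff = 0)), 0)
  wide <- basic_patch_contacts(a, "hix1L", cutoff = 12)
  expect_true(all(bp1$residue %in% wide$residue))
  expect_error(basic_patch_contacts(a, "nope"), "unknown subunit")
})

test_that("identical assemblies give identical constraint reports", {
  a <- assembly_state("cleaved")
  comp <- make_toy_components(fixture_spec(), "cleaved")
  b <- assemble_invertasome(assembly_config(comp))
  expect_identical(crosslink_report(a), crosslink_report(b))
})
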