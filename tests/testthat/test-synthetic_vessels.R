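test_that("generation is deterministic given the spec", {
  spec <- synthetic_vessel_spec(n_sections = 2L, seed = 11)
  a <- generate_vessel(spec)
  b <- generate_vessel(spec)
  for (i in 1:2) {
    expect_identical(a$stack$sections[[i]]$labels, b$stack$sections[[i]]$labels)
  }
  expect_identical(a$truth, b$truth)
})

test_that("zero pericyte arc produces no pericyte or peg pixels", {
  v <- generate_vessel(synthetic_vessel_spec(pericyte_arc_fraction = 0,
                                             peg_count_per_section = 3L,
                                             n_sections = 1L, seed = 5))
  lab <- v$stack$sections[[1L]]$labels
  expect_equal(sum(lab == CODES[["pericyte"]]), 0L)
  expect_equal(sum(lab == CODES[["peg"]]), 0L)
  expect_equal(v$truth$peg_count_per_section, 0L)
})

test_that("programmed pericyte arc matches an angular sweep over the rasterized section", {
  v <- generate_vessel(synthetic_vessel_spec(pericyte_arc_fraction = 0.5,
                                             contact_arc_fraction = 0,
                                             peg_count_per_section = 0L,
                                             jitter_amp = 0,
                                             n_sections = 1L, seed = 21))
  lab <- v$stack$sections[[1L]]$labels
  n <- nrow(lab)
  ctr <- (n + 1) / 2
  # independent oracle: sample rays at many angles, ask whether pericyte is
  # present along each
  ang <- seq(0, 2 * pi, length.out = 721L)[-721L]
  hit <- vapply(ang, function(a) {
    t <- seq(2, n / 2 - 1, by = 0.5)
    ri <- round(ctr + t * sin(a))
    ci <- round(ctr + t * cos(a))
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
    any(lab[cbind(ri[ok], ci[ok])] == CODES[["pericyte"]])
  }, logical(1L))
  expect_equal(mean(hit), 0.5, tolerance = 0.02)
  # zero contact: no pericyte pixel 8-adjacent to endothelium
  peri <- lab == CODES[["pericyte"]]
  ec <- lab == CODES[["endothelial"]]
  touching <- peri & pericytemorph:::dilate_mask(ec, matrix(1, 3, 3))
  expect_equal(sum(touching), 0L)
})

test_that("peg components per section match the spec exactly", {
  for (k in c(1L, 3L)) {
    v <- generate_vessel(synthetic_vessel_spec(peg_count_per_section = k,
                                               n_sections = 2L, seed = 30 + k))
    for (s in v$stack$sections) {
      labs <- pericytemorph:::label_components(s$labels == CODES[["peg"]], 8L)
      expect_equal(max(labs), k)
    }
    expect_equal(nrow(v$truth$pegs), 2L * k)
    expect_true(all(v$truth$pegs$true_depth_nm == 400))
    expect_true(all(v$truth$pegs$true_area_nm2 == 400 * 300))
  }
})

test_that("impossible geometries fail loudly", {
  expect_error(
    generate_vessel(synthetic_vessel_spec(diameter_um = 4, seed = 1,
                                          ec_thickness_nm = 1500,
                                          pericyte_thickness_nm = 500)),
    "cannot fit")
  expect_error(
    generate_vessel(synthetic_vessel_spec(grid_px = 100L, seed = 1)),
    "cannot fit")
  expect_warning(synthetic_vessel_spec(diameter_um = 20), "capillary")
})

test_that("cohorts reproduce group offsets in the ground truth", {
  base <- synthetic_vessel_spec(n_sections = 1L, pixel_size_nm = 40)
  coh <- generate_cohort(n_per_group = c(A = 6L, B = 6L), base = base,
                         effects = list(B = c(peg_depth_nm = 200)),
                         seed = 99)
  expect_length(coh, 12L)
  depth_mean <- function(g) {
    mean(unlist(lapply(coh, function(v) {
      if (v$stack$group == g) v$truth$pegs$true_depth_nm else NULL
    })))
  }
  expect_equal(depth_mean("B") - depth_mean("A"), 200, tolerance = 80)
  # same seed regenerates bit-identical stacks
  coh2 <- generate_cohort(n_per_group = c(A = 6L, B = 6L), base = base,
                          effects = list(B = c(peg_depth_nm = 200)),
                          seed = 99)
  expect_identical(coh[[1L]]$stack$sections[[1L]]$labels,
                   coh2[[1L]]$stack$sections[[1L]]$labels)
  expect_identical(coh[[12L]]$stack$sections[[1L]]$labels,
                   coh2[[12L]]$stack$sections[[1L]]$labels)
})

test_that("fluorescence generator renders programmed tube and coverage", {
  branches <- list(list(centerline = rbind(c(64, 10), c(64, 246)),
                        width_um = 10, sma_coverage_fraction = 0.4))
  im <- generate_if_image(256L, 128L, pixel_size_um = 1, branches = branches,
                          seed = 4)
  tr <- im$truth[[1L]]
  expect_equal(sum(tr$sma_mask) / sum(tr$tube_mask), 0.4, tolerance = 0.02)
  # full coverage lights the whole tube
  br2 <- list(list(centerline = rbind(c(64, 10), c(64, 246)),
                   width_um = 10, sma_coverage_fraction = 1))
  im2 <- generate_if_image(256L, 128L, 1, br2, seed = 4)
  expect_true(all(im2$image[im2$truth[[1L]]$tube_mask] > 0.5))
  # Y junction: three ground-truth branches
  y <- list(
    list(centerline = rbind(c(100, 10), c(64, 100)), width_um = 8,
         sma_coverage_fraction = 0.5),
    list(centerline = rbind(c(28, 10), c(64, 100)), width_um = 8,
         sma_coverage_fraction = 0.5),
    list(centerline = rbind(c(64, 100), c(64, 246)), width_um = 8,
         sma_coverage_fraction = 0.5))
  im3 <- generate_if_image(256L, 128L, 1, y, seed = 4)
  expect_length(im3$truth, 3L)
  # zero branches: pure noise
  im4 <- generate_if_image(64L, 64L, 1, list(), seed = 4)
  expect_lt(max(im4$image), 0.2)
  expect_length(im4$truth, 0L)
})
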