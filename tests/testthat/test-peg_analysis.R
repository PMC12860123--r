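test_that("distance transform equals the brute-force oracle on random grids", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(16:48, 1L)
    m <- matrix(stats::runif(n * n) < stats::runif(1, 0.3, 0.8), n, n)
    expect_equal(pericytemorph:::euclidean_dt(m), brute_force_edt(m),
                 tolerance = 1e-12)
  }
})

test_that("peg component counting respects connectivity and minimum size", {
  v <- generate_vessel(synthetic_vessel_spec(peg_count_per_section = 3L,
                                             n_sections = 1L, seed = 41))
  labs <- peg_components(v$stack$sections[[1L]])
  expect_equal(max(labs), 3L)
  # no pegs: empty record list
  v0 <- generate_vessel(synthetic_vessel_spec(peg_count_per_section = 0L,
                                              n_sections = 1L, seed = 42))
  expect_equal(nrow(peg_max_depths(v0$stack$sections[[1L]])), 0L)
  # two 2x2 blocks touching at one corner: one component under 8-connectivity
  lab <- blank_grid(20L)
  lab[, ] <- CODES[["endothelial"]]
  lab[5:6, 5:6] <- CODES[["peg"]]
  lab[7:8, 7:8] <- CODES[["peg"]]
  expect_equal(max(peg_components(make_section(lab))), 1L)
  cfg4 <- pipeline_config(connectivity = 4L)
  expect_equal(max(peg_components(make_section(lab), cfg4)), 2L)
  # sub-minimum components are dropped
  lab2 <- blank_grid(20L)
  lab2[, ] <- CODES[["endothelial"]]
  lab2[5:6, 5L] <- CODES[["peg"]] # 2 px < min_component_px = 4
  expect_equal(max(peg_components(make_section(lab2))), 0L)
})

test_that("depth of a flat endothelial slab equals its thickness at the luminal face", {
  # 1000 nm EC slab (50 px at 20 nm) over lumen; abluminal face at row 10
  lab <- blank_grid(100L)
  lab[10:59, ] <- CODES[["endothelial"]]
  lab[60:100, ] <- CODES[["lumen"]]
  sec <- make_section(lab, pixel_size_nm = 20)
  dm <- depth_map(sec)
  expect_equal(dm[59L, 50L], 1000, tolerance = 1.5 * 20 / 1000 / (1000 / 1000))
  expect_equal(dm[9L, 50L], 0)   # just outside the mask
  expect_equal(dm[10L, 50L], 20) # first row inside
})

test_that("closing radius below one pixel warns and clamps", {
  lab <- blank_grid(32L)
  lab[10:20, 10:20] <- CODES[["endothelial"]]
  sec <- make_section(lab, pixel_size_nm = 400)
  expect_warning(depth_map(sec), "clamped")
})

test_that("a 100 nm cleft is sealed by the 134 nm closing; a 300 nm gap is not", {
  base <- function(cleft_px) {
    # EC wall rows 20..59 (800 nm); socket slot carved rows 20..45;
    # peg inside the slot separated from the walls by `cleft_px` of BM
    lab <- blank_grid(120L)
    lab[20:59, ] <- CODES[["endothelial"]]
    lab[60:120, ] <- CODES[["lumen"]]
    slot_rows <- 20:45
    slot_cols <- (50 - cleft_px - 7):(50 + cleft_px + 7)
    lab[slot_rows, slot_cols] <- CODES[["basement_membrane"]]
    lab[20:(45 - cleft_px), (50 - 7):(50 + 7)] <- CODES[["peg"]]
    lab[1:19, ] <- CODES[["pericyte"]]
    make_section(lab, pixel_size_nm = 20)
  }
  # 100 nm cleft = 5 px: closing seals it, so depth counts from the
  # abluminal surface and the peg tip reads its full protrusion depth
  sealed <- base(5L)
  d_sealed <- max(depth_map(sealed)[sealed$labels == CODES[["peg"]]])
  tip_depth_nm <- (45 - 5 - 20 + 1) * 20
  expect_gt(d_sealed, tip_depth_nm - 60)
  # 300 nm cleft = 15 px: not sealed; the peg floats in BM and its depth
  # reflects only its own half-width, far below the protrusion depth
  open <- base(15L)
  d_open <- max(depth_map(open)[open$labels == CODES[["peg"]]])
  expect_lt(d_open, 220)
})

test_that("programmed peg depth and area are recovered", {
  px <- 20
  diag_nm <- sqrt(2) * px
  for (depth in c(200, 500, 800)) {
    v <- generate_vessel(synthetic_vessel_spec(peg_count_per_section = 2L,
                                               peg_depth_nm = depth,
                                               ec_thickness_nm = 900,
                                               n_sections = 1L,
                                               seed = depth))
    recs <- peg_max_depths(v$stack$sections[[1L]])
    expect_equal(nrow(recs), 2L)
    # tolerance: one pixel diagonal plus closing fillet bound
    expect_true(all(abs(recs$max_depth_nm - depth) <= diag_nm + 134))
    expect_equal(recs$area_nm2, rep(300 * depth, 2L),
                 tolerance = 0.05)
    expect_false(any(recs$orphan))
  }
})

test_that("deepening a peg raises measured depth proportionally", {
  depths <- c(300, 400, 500) # 5-px steps at 20 nm/px
  meas <- vapply(depths, function(d) {
    v <- generate_vessel(synthetic_vessel_spec(peg_count_per_section = 1L,
                                               peg_depth_nm = d,
                                               ec_thickness_nm = 700,
                                               jitter_amp = 0,
                                               n_sections = 1L, seed = 7))
    peg_max_depths(v$stack$sections[[1L]])$max_depth_nm
  }, numeric(1L))
  diag_nm <- sqrt(2) * 20
  expect_true(all(abs(diff(meas) - 100) <= diag_nm))
})

test_that("component areas conserve the total peg pixel count", {
  v <- generate_vessel(synthetic_vessel_spec(peg_count_per_section = 3L,
                                             n_sections = 1L, seed = 91))
  sec <- v$stack$sections[[1L]]
  recs <- peg_max_depths(sec)
  expect_equal(sum(recs$area_nm2),
               sum(sec$labels == CODES[["peg"]]) * sec$pixel_size_nm^2)
})

test_that("pegs with no adjacent pericyte are flagged, not dropped", {
  lab <- blank_grid(40L)
  lab[, ] <- CODES[["endothelial"]]
  lab[30:40, ] <- CODES[["lumen"]]
  lab[10:15, 10:15] <- CODES[["peg"]] # floats inside the endothelium
  recs <- peg_max_depths(make_section(lab))
  expect_equal(nrow(recs), 1L)
  expect_true(recs$orphan)
})
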