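test_that("contact mask is empty when BM separates the cells, exact when they abut", {
  # pericyte and endothelium separated by 2 px of BM everywhere
  lab <- blank_grid(64L)
  lab[10:19, 5:60] <- CODES[["pericyte"]]
  lab[20:21, 5:60] <- CODES[["basement_membrane"]]
  lab[22:31, 5:60] <- CODES[["endothelial"]]
  expect_equal(sum(contact_mask(make_section(lab))), 0L)
  # direct abutment over 50 px: exactly the touching pericyte row
  lab2 <- blank_grid(64L)
  lab2[10:19, 5:54] <- CODES[["pericyte"]]
  lab2[20:29, 5:54] <- CODES[["endothelial"]]
  cm <- contact_mask(make_section(lab2))
  expect_equal(sum(cm), 50L)
  expect_true(all(which(cm, arr.ind = TRUE)[, 1L] == 19L))
})

test_that("peg pixels join the contact mask only when merged with pericyte", {
  lab <- blank_grid(64L)
  lab[10:19, 5:54] <- CODES[["peg"]]
  lab[20:29, 5:54] <- CODES[["endothelial"]]
  expect_gt(sum(contact_mask(make_section(lab), pipeline_config())), 0L)
  cfg_off <- pipeline_config(merge_peg_into_pericyte = FALSE)
  expect_equal(sum(contact_mask(make_section(lab), cfg_off)), 0L)
})

test_that("interface skeleton of an annulus is a single closed 1-px loop", {
  n <- 101L
  ctr <- 51
  xs <- matrix(seq_len(n), n, n)
  rr <- sqrt((xs - ctr)^2 + (t(xs) - ctr)^2)
  lab <- blank_grid(n)
  lab[rr >= 30 & rr <= 33] <- CODES[["basement_membrane"]]
  sec <- make_section(lab)
  sk <- skeletonize_interface(sec)
  nb <- pericytemorph:::neighbor_count(sk)
  expect_true(all(nb[sk] == 2L))
  expect_equal(max(pericytemorph:::label_components(sk, 8L)), 1L)
})

test_that("a contact bridge keeps the interface skeleton connected across a BM gap", {
  n <- 101L
  ctr <- 51
  xs <- matrix(seq_len(n), n, n)
  rr <- sqrt((xs - ctr)^2 + (t(xs) - ctr)^2)
  th <- atan2(t(xs) - ctr, xs - ctr)
  lab <- blank_grid(n)
  lab[rr <= 25] <- CODES[["lumen"]]
  lab[rr > 25 & rr <= 29] <- CODES[["endothelial"]]
  lab[rr > 29 & rr <= 33] <- CODES[["basement_membrane"]]
  gap <- abs(th) < 0.35
  lab[gap & rr > 29 & rr <= 33] <- CODES[["pericyte"]] # pericyte fills the gap
  sec <- make_section(lab)
  sk <- skeletonize_interface(sec)
  expect_equal(max(pericytemorph:::label_components(sk, 8L)), 1L)
})

test_that("straight-bar skeleton length matches its centerline", {
  lab <- blank_grid(120L)
  lab[58:62, 11:110] <- CODES[["basement_membrane"]]
  sk <- skeletonize_interface(make_section(lab))
  expect_equal(sum(sk), 96L, tolerance = 0.05)
})

test_that("uncovered vessels are all Class 3 with undefined contact", {
  v <- generate_vessel(synthetic_vessel_spec(pericyte_arc_fraction = 0,
                                             n_sections = 1L, seed = 8))
  p <- contact_profile(v$stack$sections[[1L]])
  expect_equal(p$L1_um, 0)
  expect_equal(p$L2_um, 0)
  expect_gt(p$L3_um, 0)
  expect_equal(p$coverage_pct, 0)
  expect_true(is.na(p$contact_pct))
})

test_that("full-contact coverage classifies the covered arc as Class 1", {
  v <- generate_vessel(synthetic_vessel_spec(pericyte_arc_fraction = 0.5,
                                             contact_arc_fraction = 1,
                                             peg_count_per_section = 0L,
                                             n_sections = 1L, seed = 13))
  p <- contact_profile(v$stack$sections[[1L]])
  expect_equal(p$contact_pct, 100, tolerance = 0.03)
  expect_equal(p$coverage_pct, 50, tolerance = 3 / 50)
})

test_that("no direct contact yields zero Class-1 length", {
  for (seed in 1:3) {
    v <- generate_vessel(synthetic_vessel_spec(contact_arc_fraction = 0,
                                               peg_count_per_section = 0L,
                                               n_sections = 1L, seed = seed))
    p <- contact_profile(v$stack$sections[[1L]])
    expect_equal(p$L1_um, 0)
  }
})

test_that("class lengths partition the retained skeleton exactly", {
  v <- generate_vessel(synthetic_vessel_spec(n_sections = 1L, seed = 31))
  sec <- v$stack$sections[[1L]]
  cfg <- pipeline_config()
  con <- contact_mask(sec, cfg)
  sk <- skeletonize_interface(sec, cfg)
  cls <- classify_skeleton(sec, sk, con, cfg)
  retained <- cls > 0L
  lens <- pericytemorph:::skeleton_halfedge_lengths(retained)
  total_um <- sum(lens) * sec$pixel_size_nm / 1000
  p <- contact_profile(sec, cfg)
  expect_equal(p$L1_um + p$L2_um + p$L3_um, total_um, tolerance = 1e-12)
  # every skeleton pixel got exactly one label
  expect_true(all(cls[sk] %in% c(-1L, 1L, 2L, 3L)))
  expect_true(all(cls[!sk] == 0L))
})

test_that("coverage and contact are invariant to pixel size and rotation", {
  p20 <- contact_profile(generate_vessel(
    synthetic_vessel_spec(n_sections = 1L, peg_count_per_section = 0L,
                          pixel_size_nm = 20, seed = 55))$stack$sections[[1L]])
  p40 <- contact_profile(generate_vessel(
    synthetic_vessel_spec(n_sections = 1L, peg_count_per_section = 0L,
                          pixel_size_nm = 40, seed = 55))$stack$sections[[1L]])
  expect_equal(p20$coverage_pct, p40$coverage_pct, tolerance = 2 / 50)
  expect_equal(p20$contact_pct, p40$contact_pct, tolerance = 2 / 10)
  sec <- generate_vessel(synthetic_vessel_spec(
    n_sections = 1L, peg_count_per_section = 0L, seed = 56))$stack$sections[[1L]]
  rot <- make_section(t(sec$labels[nrow(sec$labels):1, ]),
                      pixel_size_nm = sec$pixel_size_nm)
  pa <- contact_profile(sec)
  pb <- contact_profile(rot)
  expect_equal(pa$coverage_pct, pb$coverage_pct, tolerance = 2 / 50)
  expect_equal(pa$contact_pct, pb$contact_pct, tolerance = 2 / 10)
})

test_that("pixel-count length metric gives the same percentages", {
  sec <- generate_vessel(synthetic_vessel_spec(
    n_sections = 1L, peg_count_per_section = 0L, seed = 70))$stack$sections[[1L]]
  a <- contact_profile(sec, pipeline_config())
  b <- contact_profile(sec, pipeline_config(skeleton_length_metric = "pixel_count"))
  expect_equal(a$coverage_pct, b$coverage_pct, tolerance = 1.5 / 50)
  expect_equal(a$contact_pct, b$contact_pct, tolerance = 1.5 / 10)
})

test_that("vessel-level pooling is length-weighted, not a mean of ratios", {
  v <- generate_vessel(synthetic_vessel_spec(n_sections = 3L,
                                             peg_count_per_section = 0L,
                                             seed = 77))
  vc <- vessel_contact(v$stack)
  df <- vc$sections
  expect_equal(vc$contact_pct,
               100 * sum(df$L1_um) / sum(df$L1_um + df$L2_um))
  expect_equal(vc$coverage_pct,
               100 * sum(df$L1_um + df$L2_um) /
                 sum(df$L1_um + df$L2_um + df$L3_um))
})
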