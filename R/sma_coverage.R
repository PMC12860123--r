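# Mural-cell (alpha-SMA) coverage on fluorescence vessel networks. The vessel
# is detectable at low intensity; alpha-SMA-positive mural processes are
# bright. A top-hat filter removes slowly varying background, a fixed low
# threshold yields the vessel mask, Otsu's method (restricted to the vessel)
# yields the alpha-SMA mask, and the vessel skeleton is decomposed into
# branches whose diameters come from the distance transform.

#' Parameters of the fluorescence analysis
#'
#' @param tophat_radius_um Radius of the top-hat disk (um); must exceed the
#'   radius of the widest vessel of interest. Default 15.
#' @param low_threshold Fixed low intensity threshold applied to the
#'   top-hat-filtered image for the vessel mask. Default 0.05 (images are
#'   assumed scaled to roughly [0, 1]).
#' @param min_object_um2 Minimum object area retained in the vessel mask (um^2).
#' @param min_branch_um Skeleton segments shorter than this are not reported
#'   as separate branches (their pixels are absorbed by the nearest remaining
#'   branch). Default 2.
#' @param diameter_stat `"mean"` (default) or `"median"` distance-transform
#'   value along the branch skeleton.
#' @param min_bimodality Minimum eta-squared (between-class share of variance
#'   at the Otsu optimum) for the vessel-restricted intensity histogram to be
#'   treated as bimodal; a unimodal Gaussian scores about 0.64. Default 0.75.
#' @param saturated_floor When the histogram is unimodal, the vessel is
#'   called uniformly SMA-positive if its median top-hat intensity exceeds
#'   this value (full mask), otherwise uniformly negative (empty mask with a
#'   warning). Default 0.3.
#' @return Object of class `sma_params`.
#' @export
sma_params <- function(tophat_radius_um = 15,
                       low_threshold = 0.05,
                       min_object_um2 = 4,
                       min_branch_um = 2,
                       diameter_stat = c("mean", "median"),
                       min_bimodality = 0.75,
                       saturated_floor = 0.3) {
  stopifnot(tophat_radius_um > 0, low_threshold >= 0, min_object_um2 >= 0,
            min_branch_um >= 0, min_bimodality > 0, min_bimodality < 1,
            saturated_floor >= 0)
  structure(list(tophat_radius_um = tophat_radius_um,
                 low_threshold = low_threshold,
                 min_object_um2 = min_object_um2,
                 min_branch_um = min_branch_um,
                 diameter_stat = match.arg(diameter_stat),
                 min_bimodality = min_bimodality,
                 saturated_floor = saturated_floor),
            class = "sma_params")
}

# white top-hat: image minus its opening with a disk of the given radius
tophat_filter <- function(image, pixel_size_um, radius_um) {
  r_px <- max(1L, round(radius_um / pixel_size_um))
  image - open_image(image, disk_kernel(r_px))
}

#' Vessel mask from a single-channel fluorescence image
#'
#' Top-hat background subtraction, fixed low-intensity threshold, small-object
#' removal.
#'
#' @param image Numeric matrix, non-negative intensities.
#' @param pixel_size_um Pixel calibration, um per pixel edge.
#' @param params An [sma_params()].
#' @return Logical matrix (empty for an all-zero image; not an error).
#' @export
vessel_mask <- function(image, pixel_size_um, params = sma_params()) {
  stopifnot(is.matrix(image), all(image >= 0), pixel_size_um > 0)
  th <- tophat_filter(image, pixel_size_um, params$tophat_radius_um)
  mask <- th > params$low_threshold
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity = 8L)
  min_px <- params$min_object_um2 / pixel_size_um^2
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_px)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

# Otsu threshold of a value vector (256-bin histogram). Returns the threshold
# plus eta^2, the between-class share of the total variance at the optimum:
# ~0.64 for a unimodal Gaussian, near 1 for well-separated modes; used as a
# bimodality measure. NA threshold when the histogram has no spread.
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) <= .Machine$double.eps) {
    return(list(threshold = NA_real_, eta2 = 0))
  }
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  if (max(sb) <= 0) return(list(threshold = NA_real_, eta2 = 0))
  k <- which.max(sb)
  tot_var <- sum(p * (mids - mu_t)^2)
  list(threshold = (br[k] + br[k + 1L]) / 2,
       eta2 = if (tot_var > 0) sb[k] / tot_var else 0)
}

#' alpha-SMA mask
#'
#' Otsu's threshold computed on the top-hat-filtered intensities restricted to
#' the vessel mask (background pixels would dominate the histogram and drag
#' the threshold down). Otsu assumes a bimodal histogram; when the
#' vessel-restricted histogram is unimodal (eta-squared below
#' `params$min_bimodality`) the vessel is uniformly positive or uniformly
#' negative: above `params$saturated_floor` the whole vessel is returned,
#' otherwise an empty mask with a warning.
#'
#' @param image Numeric matrix.
#' @param pixel_size_um Pixel calibration, um.
#' @param vessel Logical matrix from [vessel_mask()].
#' @param params An [sma_params()].
#' @return Logical matrix, subset of `vessel`.
#' @export
sma_mask <- function(image, pixel_size_um, vessel, params = sma_params()) {
  stopifnot(is.matrix(image), identical(dim(image), dim(vessel)))
  out <- matrix(FALSE, nrow(image), ncol(image))
  if (!any(vessel)) return(out)
  th <- tophat_filter(image, pixel_size_um, params$tophat_radius_um)
  ot <- otsu_threshold(th[vessel])
  if (is.na(ot$threshold) || ot$eta2 < params$min_bimodality) {
    if (!is.na(ot$threshold) &&
        stats::median(th[vessel]) > params$saturated_floor) {
      out[vessel] <- TRUE # uniformly SMA-positive vessel
      return(out)
    }
    warning("degenerate (unimodal) intensity histogram inside the vessel ",
            "mask; returning an empty alpha-SMA mask")
    return(out)
  }
  out[vessel] <- th[vessel] > ot$threshold
  out
}

#' Decompose a vessel mask into branches
#'
#' Skeletonizes the mask, removes branch points (skeleton pixels with more
#' than two skeleton neighbours, 8-connectivity) to split the skeleton into
#' segments, drops segments shorter than `params$min_branch_um`, and assigns
#' every vessel-mask pixel to the branch with the nearest skeleton pixel (an
#' exact partition of the mask). Branch mean diameter is twice the
#' mean (or median) Euclidean distance-transform value of the vessel mask
#' along the branch skeleton.
#'
#' @param vessel Logical matrix.
#' @param pixel_size_um Pixel calibration, um.
#' @param params An [sma_params()].
#' @return List with `branches` (data frame: branch_id, mean_diameter_um,
#'   length_um, branch_area_um2, n_skeleton_px) and `assignment` (integer
#'   matrix mapping every vessel pixel to a branch id, 0 elsewhere).
#' @export
branch_decompose <- function(vessel, pixel_size_um, params = sma_params()) {
  stopifnot(is.matrix(vessel), pixel_size_um > 0)
  if (!any(vessel)) stop("vessel mask is empty")
  skel <- thin_mask(vessel)
  dt <- euclidean_dt(vessel)
  nb <- neighbor_count(skel)
  seg_mask <- skel & nb <= 2L
  if (!any(seg_mask)) seg_mask <- skel # single pixel / tiny blob
  seg_lab <- label_components(seg_mask, connectivity = 8L)
  n_seg <- max(seg_lab)
  lens_px <- skeleton_halfedge_lengths(seg_mask)
  seg_len_um <- vapply(seq_len(n_seg), function(k) {
    sum(lens_px[seg_lab == k]) * pixel_size_um
  }, numeric(1L))
  keep <- which(seg_len_um >= params$min_branch_um)
  if (length(keep) == 0L) keep <- which.max(seg_len_um) # degenerate: one branch
  # nearest-branch assignment of every vessel pixel (exact, chunked)
  nr <- nrow(vessel)
  sk_idx <- which(seg_lab %in% keep)
  sk_r <- ((sk_idx - 1L) %% nr) + 1L
  sk_c <- ((sk_idx - 1L) %/% nr) + 1L
  sk_b <- match(seg_lab[sk_idx], keep)
  v_idx <- which(vessel)
  v_r <- ((v_idx - 1L) %% nr) + 1L
  v_c <- ((v_idx - 1L) %/% nr) + 1L
  assign_vec <- integer(length(v_idx))
  chunk <- max(1L, floor(4e6 / length(sk_idx)))
  for (s in seq(1L, length(v_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(v_idx))
    d2 <- outer(v_r[s:e], sk_r, "-")^2 + outer(v_c[s:e], sk_c, "-")^2
    assign_vec[s:e] <- sk_b[max.col(-d2, ties.method = "first")]
  }
  assignment <- matrix(0L, nr, ncol(vessel))
  assignment[v_idx] <- assign_vec
  stat <- if (params$diameter_stat == "mean") mean else stats::median
  branches <- do.call(rbind, lapply(seq_along(keep), function(b) {
    ski <- sk_idx[sk_b == b]
    data.frame(branch_id = b,
               mean_diameter_um = 2 * stat(dt[ski]) * pixel_size_um,
               length_um = sum(lens_px[ski]) * pixel_size_um,
               branch_area_um2 = sum(assign_vec == b) * pixel_size_um^2,
               n_skeleton_px = length(ski))
  }))
  list(branches = branches, assignment = assignment)
}

#' Per-branch alpha-SMA coverage
#'
#' @param image Numeric matrix (single alpha-SMA channel).
#' @param pixel_size_um Pixel calibration, um.
#' @param params An [sma_params()].
#' @return Data frame of branch records: branch_id, mean_diameter_um,
#'   length_um, branch_area_um2, sma_coverage_pct (100 * alpha-SMA mask area
#'   on branch / branch area).
#' @export
sma_branch_analysis <- function(image, pixel_size_um, params = sma_params()) {
  vm <- vessel_mask(image, pixel_size_um, params)
  if (!any(vm)) {
    return(data.frame(branch_id = integer(), mean_diameter_um = numeric(),
                      length_um = numeric(), branch_area_um2 = numeric(),
                      sma_coverage_pct = numeric()))
  }
  sm <- sma_mask(image, pixel_size_um, vm, params)
  bd <- branch_decompose(vm, pixel_size_um, params)
  cov <- vapply(bd$branches$branch_id, function(b) {
    on_branch <- bd$assignment == b
    100 * sum(sm & on_branch) / sum(on_branch)
  }, numeric(1L))
  cbind(bd$branches[, c("branch_id", "mean_diameter_um", "length_um",
                        "branch_area_um2")],
        sma_coverage_pct = cov)
}

#' Coverage summarized by diameter bin
#'
#' @param branches Data frame with `mean_diameter_um` and `sma_coverage_pct`
#'   (e.g. from [sma_branch_analysis()], possibly pooled over images).
#' @param bins Numeric vector of diameter bin edges (um), increasing.
#' @return Data frame with one row per bin: bin label, lower/upper edge,
#'   n_branches, mean and SD of coverage (NA for empty bins, which are still
#'   reported with count 0).
#' @export
coverage_by_diameter <- function(branches, bins = c(0, 10, 25, 50)) {
  stopifnot(nrow(branches) >= 1L, length(bins) >= 2L, !is.unsorted(bins))
  cutf <- cut(branches$mean_diameter_um, breaks = bins, include.lowest = TRUE)
  lev <- levels(cutf)
  do.call(rbind, lapply(seq_along(lev), function(i) {
    v <- branches$sma_coverage_pct[!is.na(cutf) & cutf == lev[i]]
    data.frame(bin = lev[i],
               lower_um = bins[i], upper_um = bins[i + 1L],
               n_branches = length(v),
               mean_coverage_pct = if (length(v)) mean(v) else NA_real_,
               sd_coverage_pct = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
}

#' Generate a synthetic fluorescence vessel-network image
#'
#' Renders vessel tubes (polyline centerlines with given widths) at low
#' intensity over a noisy background, with alpha-SMA-positive signal at high
#' intensity over a programmed fraction of each tube (measured along the
#' centerline from its start). Ground truth records the noiseless per-branch
#' masks and programmed values.
#'
#' @param width_px,height_px Image size.
#' @param pixel_size_um Pixel calibration.
#' @param branches List of branch descriptors, each a list with `centerline`
#'   (n x 2 matrix of (row, col) vertices), `width_um`, and
#'   `sma_coverage_fraction` in `[0, 1]`.
#' @param background Mean background level. Default 0.02.
#' @param noise_sd Gaussian noise SD. Default 0.01.
#' @param vessel_intensity,sma_intensity Rendered intensities. Defaults 0.15
#'   and 0.8.
#' @param seed RNG seed.
#' @return List with `image` (numeric matrix, clipped to `[0, 1]`) and
#'   `truth`: per-branch list of `tube_mask`, `sma_mask`, `width_um`,
#'   `sma_coverage_fraction`.
#' @export
generate_if_image <- function(width_px, height_px, pixel_size_um, branches,
                              background = 0.02, noise_sd = 0.01,
                              vessel_intensity = 0.15, sma_intensity = 0.8,
                              seed = 1L) {
  stopifnot(width_px >= 16L, height_px >= 16L, pixel_size_um > 0)
  nr <- height_px
  nc <- width_px
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  truth <- vector("list", length(branches))
  img <- matrix(0, nr, nc)
  sma_all <- matrix(FALSE, nr, nc)
  tube_all <- matrix(FALSE, nr, nc)
  for (b in seq_along(branches)) {
    br <- branches[[b]]
    half_px <- br$width_um / pixel_size_um / 2
    if (2 * half_px < 2) stop("branch width must be at least 2 px")
    cl <- br$centerline
    dmin <- matrix(Inf, nr, nc)
    arc <- matrix(NA_real_, nr, nc) # arclength of nearest centerline point
    s0 <- 0
    for (s in seq_len(nrow(cl) - 1L)) {
      a <- cl[s, ]
      bb <- cl[s + 1L, ]
      ab <- bb - a
      len2 <- sum(ab^2)
      t <- ((rr - a[1L]) * ab[1L] + (cc - a[2L]) * ab[2L]) / max(len2, 1e-12)
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((rr - (a[1L] + t * ab[1L]))^2 + (cc - (a[2L] + t * ab[2L]))^2)
      upd <- d < dmin
      dmin[upd] <- d[upd]
      arc[upd] <- s0 + t[upd] * sqrt(len2)
      s0 <- s0 + sqrt(len2)
    }
    # band of w/pixel_size pixels centred on the line (pixel-centre sampling)
    tube <- dmin <= (br$width_um / pixel_size_um - 1) / 2
    sma <- tube & arc <= br$sma_coverage_fraction * s0
    truth[[b]] <- list(tube_mask = tube, sma_mask = sma,
                       width_um = br$width_um,
                       sma_coverage_fraction = br$sma_coverage_fraction)
    tube_all <- tube_all | tube
    sma_all <- sma_all | sma
  }
  img[tube_all] <- vessel_intensity
  img[sma_all] <- sma_intensity
  with_seed(as.integer(seed), function() {
    noisy <- img + background + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    list(image = pmin(pmax(noisy, 0), 1), truth = truth)
  })
}
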