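# Synthetic six-class capillary cross-sections with analytic ground truth.
#
# A section is built in polar coordinates about the grid centre: a lumen disk,
# an endothelial annulus, and a basement membrane (BM) that ensheathes the
# wall the way it does in capillaries: a thin BM ring on uncovered arcs, and,
# where a pericyte crescent covers the circumference, a BM film between
# endothelium and pericyte plus a BM wrap over the pericyte's abluminal face.
# Over a programmed sub-fraction of the covered arc the film is omitted so
# pericyte and endothelium are directly adjacent (direct contact).
# Finger-like pegs protrude from the pericyte into the endothelial cell to a
# programmed depth. The outer vessel boundary therefore steps outward over
# covered arcs (pericyte + wrap thickness), and carries a low-frequency
# radial jitter. All ground-truth values are computed from this generating
# geometry before rasterization.

#' Specification of one synthetic vessel
#'
#' Defaults describe a mid-range retinal capillary: 8 um diameter, 500 nm
#' endothelium, 150 nm basement membrane, half-circumference pericyte
#' coverage. Boundary jitter is a low-frequency radial perturbation (a few
#' harmonics, bounded amplitude) applied to the outer BM boundary, so sections
#' stay star-shaped about the centroid (required by the radial-probe skeleton
#' classification).
#'
#' @param diameter_um Outer vessel diameter, um. Values outside the capillary
#'   range 4-12 trigger a warning.
#' @param ec_thickness_nm Endothelial wall thickness, nm.
#' @param bm_thickness_nm Basement-membrane thickness, nm (film between
#'   pericyte and endothelium, and outer wrap).
#' @param pericyte_thickness_nm Radial thickness of the pericyte crescent, nm.
#' @param pericyte_arc_fraction Fraction of the circumference covered by
#'   pericyte, in `[0, 1]`.
#' @param contact_arc_fraction Fraction of the covered arc in direct contact
#'   (BM film locally absent), in `[0, 1]`.
#' @param peg_count_per_section Number of pegs per section (0 when
#'   `pericyte_arc_fraction` is 0).
#' @param peg_depth_nm,peg_width_nm Peg protrusion depth below the abluminal
#'   endothelial surface and tangential width, nm.
#' @param socket_bm_film_px Optional BM film thickness (pixels) lining the
#'   socket walls, separating peg from endothelium (exercises the
#'   peg-without-direct-contact case). Default 0.
#' @param n_sections Number of z-sections.
#' @param pixel_size_nm Pixel calibration, nm per pixel edge.
#' @param z_spacing_nm Section spacing, nm.
#' @param grid_px Grid side length; `NULL` (default) auto-sizes to the vessel
#'   extent plus margin.
#' @param jitter_amp Total relative amplitude bound of the radial boundary
#'   perturbation (default 0.02).
#' @param jitter_harmonics Harmonic orders of the perturbation.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return Object of class `synthetic_vessel_spec`.
#' @export
synthetic_vessel_spec <- function(diameter_um = 8,
                                  ec_thickness_nm = 500,
                                  bm_thickness_nm = 150,
                                  pericyte_thickness_nm = 400,
                                  pericyte_arc_fraction = 0.5,
                                  contact_arc_fraction = 0.1,
                                  peg_count_per_section = 2L,
                                  peg_depth_nm = 400,
                                  peg_width_nm = 300,
                                  socket_bm_film_px = 0L,
                                  n_sections = 5L,
                                  pixel_size_nm = 20,
                                  z_spacing_nm = 80,
                                  grid_px = NULL,
                                  jitter_amp = 0.02,
                                  jitter_harmonics = 2:4,
                                  seed = 1L) {
  stopifnot(diameter_um > 0, ec_thickness_nm > 0, bm_thickness_nm > 0,
            pericyte_thickness_nm > 0,
            pericyte_arc_fraction >= 0, pericyte_arc_fraction <= 1,
            contact_arc_fraction >= 0, contact_arc_fraction <= 1,
            peg_count_per_section >= 0L, peg_depth_nm > 0, peg_width_nm > 0,
            n_sections >= 1L, pixel_size_nm > 0, z_spacing_nm > 0,
            jitter_amp >= 0, socket_bm_film_px >= 0L)
  if (diameter_um < 4 || diameter_um > 12) {
    warning("diameter ", diameter_um,
            " um is outside the capillary range (~4-12 um)")
  }
  spec <- list(diameter_um = diameter_um,
               ec_thickness_nm = ec_thickness_nm,
               bm_thickness_nm = bm_thickness_nm,
               pericyte_thickness_nm = pericyte_thickness_nm,
               pericyte_arc_fraction = pericyte_arc_fraction,
               contact_arc_fraction = contact_arc_fraction,
               peg_count_per_section = as.integer(peg_count_per_section),
               peg_depth_nm = peg_depth_nm,
               peg_width_nm = peg_width_nm,
               socket_bm_film_px = as.integer(socket_bm_film_px),
               n_sections = as.integer(n_sections),
               pixel_size_nm = pixel_size_nm,
               z_spacing_nm = z_spacing_nm,
               grid_px = grid_px,
               jitter_amp = jitter_amp,
               jitter_harmonics = as.integer(jitter_harmonics),
               seed = as.integer(seed))
  structure(spec, class = "synthetic_vessel_spec")
}

# nominal layer radii (nm), from the outer BM boundary inward
.layer_radii <- function(spec) {
  r_out <- spec$diameter_um * 1000 / 2
  r_p_out <- r_out - spec$bm_thickness_nm
  r_p_in <- r_p_out - spec$pericyte_thickness_nm
  r_ec_out <- r_p_in - spec$bm_thickness_nm
  r_lumen <- r_ec_out - spec$ec_thickness_nm
  list(r_out = r_out, r_p_out = r_p_out, r_p_in = r_p_in,
       r_ec_out = r_ec_out, r_lumen = r_lumen)
}

# smallest absolute angular distance
.ang_dist <- function(theta, theta0) {
  d <- (theta - theta0) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Generate a synthetic segmented vessel stack with ground truth
#'
#' @param spec A [synthetic_vessel_spec()].
#' @param vessel_id,group Metadata attached to the returned stack.
#' @return List with elements `stack` (a [vessel_stack()]) and `truth`, a list
#'   holding analytic values computed from the generating geometry before
#'   rasterization: `true_diameter_um`, `true_pericyte_volume_pct`,
#'   `true_bm_volume_pct`, `true_coverage_pct`, `true_contact_pct`, a `pegs`
#'   data frame (per-peg depth/area), and `peg_count_per_section`.
#' @export
generate_vessel <- function(spec, vessel_id = "synthetic", group = "synthetic") {
  stopifnot(inherits(spec, "synthetic_vessel_spec"))
  rr <- .layer_radii(spec)
  px <- spec$pixel_size_nm
  if (rr$r_lumen < 10 * px) {
    stop("geometry cannot fit: lumen radius ", round(rr$r_lumen),
         " nm is too small for the wall layers")
  }
  if (spec$peg_depth_nm > rr$r_ec_out - 5 * px) {
    stop("geometry cannot fit: peg depth exceeds the vessel interior")
  }
  jit_max <- min(spec$jitter_amp, 0.8 * spec$bm_thickness_nm / rr$r_out)
  n <- spec$grid_px
  if (is.null(n)) {
    n <- 2L * ceiling(rr$r_out * (1 + jit_max) / px) + 24L
  }
  n <- max(as.integer(n), 32L)
  if (2 * rr$r_out * (1 + jit_max) / px + 8 > n) {
    stop("geometry cannot fit: vessel extent exceeds grid of ", n, " px")
  }
  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  x_nm <- (xs - ctr) * px
  y_nm <- t(x_nm)
  rho <- sqrt(x_nm^2 + y_nm^2)
  theta <- atan2(y_nm, x_nm)
  codes <- class_codes()

  n_pegs <- if (spec$pericyte_arc_fraction > 0) spec$peg_count_per_section else 0L
  film_nm <- spec$socket_bm_film_px * px

  out <- with_seed(spec$seed, function() {
    sections <- vector("list", spec$n_sections)
    peg_rows <- list()
    circ_nm <- numeric(spec$n_sections)
    wrap_area <- numeric(spec$n_sections)
    for (si in seq_len(spec$n_sections)) {
      theta0 <- stats::runif(1, -pi, pi)
      nh <- length(spec$jitter_harmonics)
      amp <- if (nh > 0 && jit_max > 0) {
        stats::runif(nh, 0, jit_max / max(1, nh))
      } else {
        numeric(nh)
      }
      phase <- stats::runif(nh, 0, 2 * pi)
      jfun <- function(th) {
        j <- rep(1, length(th))
        for (k in seq_len(nh)) {
          j <- j + amp[k] * cos(spec$jitter_harmonics[k] * th + phase[k])
        }
        j
      }
      jpfun <- function(th) {
        jp <- rep(0, length(th))
        for (k in seq_len(nh)) {
          jp <- jp - amp[k] * spec$jitter_harmonics[k] *
            sin(spec$jitter_harmonics[k] * th + phase[k])
        }
        jp
      }
      half_cov <- pi * spec$pericyte_arc_fraction
      half_con <- pi * spec$pericyte_arc_fraction * spec$contact_arc_fraction
      r_ring <- rr$r_ec_out + spec$bm_thickness_nm # outer radius, uncovered

      # analytic outer-boundary circumference and BM areas (fine quadrature):
      # the boundary follows r_out over covered arcs and the thin BM ring
      # elsewhere, with radial steps at the arc ends
      tg <- seq(0, 2 * pi, length.out = 8192L + 1L)[-1L]
      dth <- 2 * pi / length(tg)
      jv <- jfun(tg)
      jp <- jpfun(tg)
      cov_t <- .ang_dist(tg, theta0) <= half_cov & spec$pericyte_arc_fraction > 0
      ds <- sqrt(jv^2 + jp^2) * dth
      steps <- if (spec$pericyte_arc_fraction > 0 &&
                   spec$pericyte_arc_fraction < 1) {
        (rr$r_out - r_ring) *
          sum(jfun(theta0 + c(-half_cov, half_cov)))
      } else 0
      circ_nm[si] <- rr$r_out * sum(ds[cov_t]) + r_ring * sum(ds[!cov_t]) +
        steps
      wrap_area[si] <- sum((rr$r_out * jv[cov_t])^2 - rr$r_p_out^2) / 2 * dth +
        sum((r_ring * jv[!cov_t])^2 - rr$r_ec_out^2) / 2 * dth

      ad <- .ang_dist(theta, theta0)
      covered <- ad <= half_cov & spec$pericyte_arc_fraction > 0
      contact <- ad <= half_con & half_con > 0

      lab <- matrix(codes[["background"]], n, n)
      r_bound <- ifelse(covered, rr$r_out, r_ring) * jfun(theta)
      lab[rho <= r_bound] <- codes[["basement_membrane"]]
      p_inner <- ifelse(contact, rr$r_ec_out, rr$r_ec_out + spec$bm_thickness_nm)
      sel <- covered & rho <= rr$r_p_out & rho > p_inner
      lab[sel] <- codes[["pericyte"]]
      lab[rho <= rr$r_ec_out] <- codes[["endothelial"]]
      lab[rho <= rr$r_lumen] <- codes[["lumen"]]

      # pegs: radial fingers carved from the abluminal surface inward
      if (n_pegs > 0L) {
        span <- 0.7 * 2 * half_cov
        th_pegs <- theta0 + if (n_pegs == 1L) 0 else {
          seq(-span / 2, span / 2, length.out = n_pegs)
        }
        min_sep_nm <- spec$peg_width_nm + 2 * film_nm + 6 * px
        if (n_pegs > 1L) {
          sep <- (span / (n_pegs - 1L)) * rr$r_ec_out
          if (sep < min_sep_nm) {
            stop("geometry cannot fit: ", n_pegs,
                 " pegs of width ", spec$peg_width_nm,
                 " nm do not fit in the covered arc")
          }
        }
        for (pk in seq_len(n_pegs)) {
          arcdist <- rho * .ang_dist(theta, th_pegs[pk])
          radial <- rho <= rr$r_ec_out & rho > rr$r_ec_out - spec$peg_depth_nm
          if (film_nm > 0) {
            film_side <- radial & arcdist > spec$peg_width_nm / 2 &
              arcdist <= spec$peg_width_nm / 2 + film_nm
            film_bot <- rho <= rr$r_ec_out - spec$peg_depth_nm &
              rho > rr$r_ec_out - spec$peg_depth_nm - film_nm &
              arcdist <= spec$peg_width_nm / 2 + film_nm
            lab[(film_side | film_bot) &
                  lab != codes[["background"]]] <- codes[["basement_membrane"]]
          }
          lab[radial & arcdist <= spec$peg_width_nm / 2] <- codes[["peg"]]
          # the peg is pericyte material: bridge the BM film above the mouth
          # so the peg root is continuous with the pericyte body
          bridge <- rho > rr$r_ec_out &
            rho <= rr$r_ec_out + spec$bm_thickness_nm &
            arcdist <= spec$peg_width_nm / 2 &
            lab == codes[["basement_membrane"]]
          lab[bridge] <- codes[["pericyte"]]
          peg_rows[[length(peg_rows) + 1L]] <- data.frame(
            section_index = si - 1L, peg = pk,
            true_depth_nm = spec$peg_depth_nm,
            true_area_nm2 = spec$peg_width_nm * spec$peg_depth_nm,
            theta = th_pegs[pk])
        }
      }
      sections[[si]] <- segmented_section(lab, pixel_size_nm = px,
                                          section_index = si - 1L)
    }
    list(sections = sections, peg_rows = peg_rows,
         circ_nm = circ_nm, wrap_area = wrap_area)
  })

  # analytic areas (nm^2) of the nominal (pre-raster) geometry, per section
  frac <- spec$pericyte_arc_fraction
  cfrac <- spec$contact_arc_fraction
  a_peri <- pi * frac * (1 - cfrac) * (rr$r_p_out^2 - rr$r_p_in^2) +
    pi * frac * cfrac * (rr$r_p_out^2 - rr$r_ec_out^2)
  # pericyte bridges through the film above peg mouths outside contact arcs
  n_bridges <- if (n_pegs > 0L) {
    span <- 0.7 * 2 * pi * frac
    offs <- if (n_pegs == 1L) 0 else seq(-span / 2, span / 2,
                                         length.out = n_pegs)
    sum(abs(offs) > pi * frac * cfrac)
  } else 0L
  bridge_area <- n_bridges * spec$peg_width_nm * spec$bm_thickness_nm
  a_peri <- a_peri + bridge_area
  peg_area <- n_pegs * spec$peg_width_nm * spec$peg_depth_nm
  film_area <- if (n_pegs > 0L && film_nm > 0) {
    n_pegs * (2 * film_nm * spec$peg_depth_nm +
                (spec$peg_width_nm + 2 * film_nm) * film_nm)
  } else 0
  a_ec_full <- pi * (rr$r_ec_out^2 - rr$r_lumen^2)
  carve_ec <- n_pegs * spec$peg_width_nm * min(spec$peg_depth_nm,
                                               spec$ec_thickness_nm)
  a_ec <- a_ec_full - carve_ec - film_area
  a_bm_fixed <- pi * frac * (1 - cfrac) *
    ((rr$r_ec_out + spec$bm_thickness_nm)^2 - rr$r_ec_out^2) + film_area -
    bridge_area
  a_bm <- mean(out$wrap_area) + a_bm_fixed
  tissue <- a_ec + a_bm + a_peri + peg_area
  pegs_df <- if (length(out$peg_rows)) {
    do.call(rbind, out$peg_rows)
  } else {
    data.frame(section_index = integer(), peg = integer(),
               true_depth_nm = numeric(), true_area_nm2 = numeric(),
               theta = numeric())
  }
  truth <- list(
    true_diameter_um = mean(out$circ_nm) / pi / 1000,
    true_pericyte_volume_pct = 100 * (a_peri + peg_area) / tissue,
    true_bm_volume_pct = 100 * a_bm / tissue,
    true_coverage_pct = 100 * frac,
    true_contact_pct = if (frac > 0) 100 * cfrac else NA_real_,
    pegs = pegs_df,
    peg_count_per_section = n_pegs
  )
  list(stack = vessel_stack(out$sections, z_spacing_nm = spec$z_spacing_nm,
                            vessel_id = vessel_id, group = group),
       truth = truth)
}

#' Generate a multi-group synthetic cohort
#'
#' Draws per-vessel specifications around `base` with per-group additive
#' parameter offsets and mild between-vessel variability, mirroring a study
#' design with four genotype/condition groups. Default group sizes are the
#' study cohort: 19 WT, 16 Notch3 KO, 18 diabetic, 23 conditional KO vessels.
#'
#' @param n_per_group Named integer vector, group label -> vessel count.
#' @param base A [synthetic_vessel_spec()] shared by all groups.
#' @param effects Named list: group -> named numeric vector of additive offsets
#'   on spec parameters (e.g. `list(N3KO = c(peg_depth_nm = 200))`).
#' @param seed Integer master seed; vessel seeds are derived reproducibly.
#' @param vessel_sd Named numeric vector of between-vessel standard deviations
#'   applied to `diameter_um`, `pericyte_arc_fraction`, `contact_arc_fraction`,
#'   `peg_depth_nm`, `peg_width_nm` (set entries to 0 to pin a parameter).
#' @return List of elements `list(stack=, truth=)` as from [generate_vessel()];
#'   vessel ids encode group and index.
#' @export
generate_cohort <- function(n_per_group = c(WT = 19L, N3KO = 16L,
                                            Diabetic = 18L, CondKO = 23L),
                            base = synthetic_vessel_spec(),
                            effects = list(),
                            seed = 1L,
                            vessel_sd = c(diameter_um = 1.0,
                                          pericyte_arc_fraction = 0.05,
                                          contact_arc_fraction = 0.03,
                                          peg_depth_nm = 60,
                                          peg_width_nm = 40)) {
  stopifnot(all(n_per_group >= 1L), !is.null(names(n_per_group)))
  total <- sum(n_per_group)
  with_seed(as.integer(seed), function() {
    vessel_seeds <- sample.int(.Machine$integer.max - 1L, total)
    draws <- list()
    k <- 0L
    for (g in names(n_per_group)) {
      off <- effects[[g]]
      for (i in seq_len(n_per_group[[g]])) {
        k <- k + 1L
        par <- list(diameter_um = base$diameter_um,
                    pericyte_arc_fraction = base$pericyte_arc_fraction,
                    contact_arc_fraction = base$contact_arc_fraction,
                    peg_depth_nm = base$peg_depth_nm,
                    peg_width_nm = base$peg_width_nm)
        for (nm in names(off)) {
          if (!nm %in% names(par)) stop("unknown effect parameter: ", nm)
          par[[nm]] <- par[[nm]] + off[[nm]]
        }
        for (nm in names(par)) {
          sd <- vessel_sd[nm]
          if (!is.na(sd) && sd > 0) par[[nm]] <- stats::rnorm(1, par[[nm]], sd)
        }
        par$diameter_um <- min(max(par$diameter_um, 4), 12)
        par$pericyte_arc_fraction <-
          min(max(par$pericyte_arc_fraction, 0.05), 0.95)
        par$contact_arc_fraction <-
          min(max(par$contact_arc_fraction, 0.01), 0.9)
        par$peg_depth_nm <- max(par$peg_depth_nm, 100)
        par$peg_width_nm <- max(par$peg_width_nm, 100)
        spec_i <- base
        spec_i[names(par)] <- par
        spec_i$seed <- vessel_seeds[k]
        class(spec_i) <- "synthetic_vessel_spec"
        draws[[k]] <- list(spec = spec_i, group = g,
                           vessel_id = sprintf("%s_%02d", g, i))
      }
    }
    lapply(draws, function(d) {
      v <- suppressWarnings(generate_vessel(d$spec, vessel_id = d$vessel_id,
                                            group = d$group))
      v$spec <- d$spec
      v
    })
  })
}
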