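# Pericyte coverage and direct pericyte-endothelial contact, measured on a
# skeletonized representation of the basement membrane plus the contact
# lines. Every retained skeleton pixel is assigned to one of three classes:
#   Class 1 - direct cell-cell contact (pericyte touching endothelium),
#   Class 2 - pericyte coverage separated from the endothelium by basement
#             membrane,
#   Class 3 - vessel circumference without pericyte coverage.
# Coverage % = (L1+L2)/(L1+L2+L3); contact % = L1/(L1+L2).

CLASS_CONTACT <- 1L
CLASS_COVERED <- 2L
CLASS_UNCOVERED <- 3L
CLASS_DISCARD <- -1L

#' Pericyte-endothelial contact mask
#'
#' Pericyte-class pixels (including pegs when
#' `config$merge_peg_into_pericyte`) lying within
#' `config$contact_dilation_px` dilation steps (3x3 square element) of the
#' endothelial mask, i.e. the pixels where the two cells touch.
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @return Logical matrix.
#' @export
contact_mask <- function(section, config = pipeline_config()) {
  masks <- class_masks(section, config)
  peri <- if (config$merge_peg_into_pericyte) masks$pericyte_total else masks$pericyte
  ec_dil <- dilate_mask(masks$endothelial, box_kernel(),
                        iterations = config$contact_dilation_px)
  peri & ec_dil
}

#' Skeleton of the basement membrane and contact lines
#'
#' One-pixel-wide, topology-preserving skeleton of the union of the basement
#' membrane mask and the contact mask. Where a direct contact interrupts the
#' BM ring, the contact mask bridges the gap, so the interface skeleton stays
#' connected.
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @return Logical matrix (the skeleton).
#' @export
skeletonize_interface <- function(section, config = pipeline_config()) {
  masks <- class_masks(section, config)
  m <- masks$basement_membrane | contact_mask(section, config)
  if (!any(m)) stop("basement membrane and contact masks are both empty")
  thin_mask(m)
}

#' Classify skeleton pixels into contact / covered / uncovered
#'
#' Class 1 is assigned to skeleton pixels within the contact mask dilated by
#' `config$contact_dilation_px` (the medial axis can sit one pixel off the
#' contact line; contact, the most specific observation, takes precedence).
#' Every remaining pixel is classified by a radial probe from the vessel
#' centroid through the pixel: the first non-BM class met probing outward
#' decides (pericyte/peg = Class 2, background = Class 3), and pixels whose
#' inward probe meets pericyte before endothelium (the skeleton of the outer
#' BM layer wrapping the pericyte soma) are discarded to avoid
#' double-counting covered arcs. Valid for star-shaped sections.
#'
#' @param section A [segmented_section()].
#' @param skeleton Logical matrix from [skeletonize_interface()].
#' @param contact Logical matrix from [contact_mask()].
#' @param config A [pipeline_config()].
#' @return Integer matrix: 0 off-skeleton, 1/2/3 the classes, -1 discarded.
#' @export
classify_skeleton <- function(section, skeleton, contact,
                              config = pipeline_config()) {
  stopifnot(inherits(section, "segmented_section"))
  lab <- section$labels
  codes <- class_codes()
  vessel <- lab != codes[["background"]]
  if (!any(vessel)) stop("degenerate section: no vessel region")
  idx_v <- which(vessel)
  nr <- nrow(lab)
  cr <- mean(((idx_v - 1L) %% nr) + 1L)
  cc <- mean(((idx_v - 1L) %/% nr) + 1L)
  if (lab[round(cr), round(cc)] == codes[["background"]]) {
    stop("degenerate section: vessel centroid falls on background")
  }

  out <- matrix(0L, nr, ncol(lab))
  contact_dil <- dilate_mask(contact, box_kernel(),
                             iterations = config$contact_dilation_px)
  out[skeleton & contact_dil] <- CLASS_CONTACT

  rest <- which(skeleton & out == 0L)
  if (length(rest) == 0L) return(out)
  pr <- ((rest - 1L) %% nr) + 1L
  pc <- ((rest - 1L) %/% nr) + 1L
  dr <- pr - cr
  dc <- pc - cc
  nrm <- pmax(sqrt(dr^2 + dc^2), 1e-9)
  ur <- dr / nrm
  uc <- dc / nrm
  peri_codes <- codes[c("pericyte", "peg")]

  probe <- function(sign_dir, stop_codes, pass_through, t_max) {
    cls <- rep(NA_integer_, length(rest))
    und <- seq_along(rest)
    t <- 1
    while (length(und) && t <= max(t_max[und])) {
      ri <- round(pr[und] + sign_dir * t * ur[und])
      ci <- round(pc[und] + sign_dir * t * uc[und])
      inb <- ri >= 1L & ri <= nr & ci >= 1L & ci <= ncol(lab)
      val <- rep(codes[["background"]], length(und))
      val[inb] <- lab[cbind(ri[inb], ci[inb])]
      hit_stop <- val %in% stop_codes
      hit_keep <- !hit_stop & !(val %in% pass_through)
      over <- t > t_max[und]
      cls[und[hit_stop & !over]] <- 1L    # stop-set hit
      cls[und[(hit_keep | over) & !hit_stop]] <- 0L # keep / other
      und <- und[!(hit_stop | hit_keep | over)]
      t <- t + 0.5
    }
    cls[is.na(cls)] <- 0L
    cls
  }

  # outward: first non-BM class (skip BM; EC/lumen can only occur right at a
  # contact or peg outline, keep probing past them)
  max_out <- rep(max(nr, ncol(lab)) * 1.5, length(rest))
  out_hit <- probe(+1,
                   stop_codes = peri_codes,
                   pass_through = codes[c("basement_membrane", "endothelial",
                                          "lumen")],
                   t_max = max_out)
  cls_out <- ifelse(out_hit == 1L, CLASS_COVERED, CLASS_UNCOVERED)

  # inward: discard if pericyte/peg appears before endothelium or lumen
  in_hit <- probe(-1,
                  stop_codes = peri_codes,
                  pass_through = codes[c("basement_membrane", "background")],
                  t_max = nrm)
  cls_final <- ifelse(in_hit == 1L, CLASS_DISCARD, cls_out)
  out[rest] <- cls_final
  out
}

#' Contact profile of one section
#'
#' Runs the mask / skeleton / classification chain and measures the three
#' class lengths. With the default `"chain"` metric each retained skeleton
#' pixel contributes half the (1, sqrt 2) length of each incident skeleton
#' edge (corner-corrected), so the class lengths are exactly additive and sum
#' to the total retained skeleton length; `"pixel_count"` sums pixels instead.
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @return Object of class `contact_profile`: list with `L1_um`, `L2_um`,
#'   `L3_um`, `coverage_pct`, `contact_pct` (NA when nothing is covered), and
#'   `section_index`.
#' @export
contact_profile <- function(section, config = pipeline_config()) {
  con <- contact_mask(section, config)
  skel <- skeletonize_interface(section, config)
  cls <- classify_skeleton(section, skel, con, config)
  retained <- cls > 0L
  px_um <- section$pixel_size_nm / 1000
  if (config$skeleton_length_metric == "chain") {
    lens <- skeleton_halfedge_lengths(retained,
                                      correction = config$perimeter_correction)
    L <- vapply(1:3, function(k) sum(lens[cls == k]) * px_um, numeric(1L))
  } else {
    L <- vapply(1:3, function(k) sum(cls == k) * px_um, numeric(1L))
  }
  tot <- sum(L)
  covered <- L[1L] + L[2L]
  structure(list(
    L1_um = L[1L], L2_um = L[2L], L3_um = L[3L],
    coverage_pct = if (tot > 0) 100 * covered / tot else NA_real_,
    contact_pct = if (covered > 0) 100 * L[1L] / covered else NA_real_,
    section_index = section$section_index
  ), class = "contact_profile")
}

#' Coverage and contact for a whole vessel
#'
#' Sections are pooled by length (ratios of summed lengths), not by averaging
#' per-section ratios, so sections with tiny covered arcs cannot destabilize
#' the contact percentage.
#'
#' @param stack A [vessel_stack()].
#' @param config A [pipeline_config()].
#' @return List with pooled `coverage_pct` and `contact_pct`, and `sections`,
#'   a data frame of per-section profiles.
#' @export
vessel_contact <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "vessel_stack"))
  secs <- included_sections(stack)
  if (length(secs) == 0L) stop("all sections are excluded")
  profs <- lapply(secs, contact_profile, config = config)
  df <- data.frame(
    section_index = vapply(profs, `[[`, integer(1L), "section_index"),
    L1_um = vapply(profs, `[[`, numeric(1L), "L1_um"),
    L2_um = vapply(profs, `[[`, numeric(1L), "L2_um"),
    L3_um = vapply(profs, `[[`, numeric(1L), "L3_um"),
    coverage_pct = vapply(profs, `[[`, numeric(1L), "coverage_pct"),
    contact_pct = vapply(profs, `[[`, numeric(1L), "contact_pct"))
  tot <- sum(df$L1_um + df$L2_um + df$L3_um)
  cov <- sum(df$L1_um + df$L2_um)
  list(coverage_pct = if (tot > 0) 100 * cov / tot else NA_real_,
       contact_pct = if (cov > 0) 100 * sum(df$L1_um) / cov else NA_real_,
       sections = df)
}
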