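# Per-section and per-vessel basic morphometry: diameter from the outer
# perimeter of the vessel (the basement membrane is the outermost tissue
# layer, so the outer boundary of the filled non-background union is the
# outer BM perimeter, robust to local BM gaps at contact sites), and volume
# fractions of the non-lumen tissue.

#' Outer circumference of a section
#'
#' Length of the outer boundary of the filled vessel region (union of all
#' non-background classes, holes filled), measured as an 8-connected contour
#' chain (unit axis steps, sqrt(2) diagonal steps) with the isotropic
#' chain-length correction applied by default
#' (`config$perimeter_correction`).
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @return Circumference in micrometres.
#' @export
section_circumference <- function(section, config = pipeline_config()) {
  stopifnot(inherits(section, "segmented_section"))
  vessel <- section$labels != class_codes()[["background"]]
  if (!any(vessel)) stop("section has no vessel region")
  vessel <- fill_holes(vessel)
  per_px <- contour_perimeter_px(vessel, correction = config$perimeter_correction)
  per_px * section$pixel_size_nm / 1000
}

#' Vessel diameter from circumference
#'
#' Per-section diameter is `D = C / pi`; the vessel value is the unweighted
#' mean over non-excluded sections.
#'
#' @param stack A [vessel_stack()].
#' @param config A [pipeline_config()].
#' @return List with `diameter_um`, `circumference_um`, per-section
#'   `section_diameter_um`, and `n_sections_used`.
#' @export
vessel_diameter <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "vessel_stack"))
  secs <- included_sections(stack)
  if (length(secs) == 0L) stop("all sections are excluded")
  circ <- vapply(secs, section_circumference, numeric(1L), config = config)
  d <- circ / pi
  list(diameter_um = mean(d),
       circumference_um = mean(circ),
       section_diameter_um = d,
       n_sections_used = length(secs))
}

#' Volume fractions of the vessel wall
#'
#' Percentages of pericyte, basement membrane, and endothelium relative to the
#' total vessel volume excluding the lumen. Voxels are summed over all
#' non-excluded sections first, then divided (so sections with more tissue
#' weigh more, matching a voxel-count definition). Peg voxels count with the
#' pericyte when `config$merge_peg_into_pericyte` is set, otherwise with the
#' endothelial remainder; in either case the three percentages sum to 100.
#'
#' @param stack A [vessel_stack()].
#' @param config A [pipeline_config()].
#' @return List with `pericyte_pct`, `bm_pct`, `endothelial_pct`.
#' @export
volume_percentages <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "vessel_stack"))
  secs <- included_sections(stack)
  if (length(secs) == 0L) stop("all sections are excluded")
  codes <- class_codes()
  n_peri <- 0; n_bm <- 0; n_ec <- 0; n_peg <- 0
  for (s in secs) {
    n_peri <- n_peri + sum(s$labels == codes[["pericyte"]])
    n_bm <- n_bm + sum(s$labels == codes[["basement_membrane"]])
    n_ec <- n_ec + sum(s$labels == codes[["endothelial"]])
    n_peg <- n_peg + sum(s$labels == codes[["peg"]])
  }
  denom <- n_peri + n_bm + n_ec + n_peg
  if (denom == 0) stop("vessel has no non-lumen tissue voxels")
  if (config$merge_peg_into_pericyte) {
    n_peri <- n_peri + n_peg
  } else {
    n_ec <- n_ec + n_peg
  }
  list(pericyte_pct = 100 * n_peri / denom,
       bm_pct = 100 * n_bm / denom,
       endothelial_pct = 100 * n_ec / denom)
}

#' Full basic morphometry of one vessel
#'
#' @param stack A [vessel_stack()].
#' @param config A [pipeline_config()].
#' @return One-row data frame: vessel_id, group, diameter_um,
#'   circumference_um, pericyte_volume_pct, bm_volume_pct,
#'   endothelial_volume_pct, n_sections_used.
#' @export
vessel_morphometry <- function(stack, config = pipeline_config()) {
  d <- vessel_diameter(stack, config)
  v <- volume_percentages(stack, config)
  data.frame(vessel_id = stack$vessel_id,
             group = stack$group,
             diameter_um = d$diameter_um,
             circumference_um = d$circumference_um,
             pericyte_volume_pct = v$pericyte_pct,
             bm_volume_pct = v$bm_pct,
             endothelial_volume_pct = v$endothelial_pct,
             n_sections_used = d$n_sections_used)
}
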