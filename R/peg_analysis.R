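# Peg-and-socket morphometry. The protrusion depth of a pericyte peg below
# the abluminal endothelial surface is read off an exact Euclidean distance
# transform of the endothelium + pegs + lumen mask, after a morphological
# closing (disk element with a physical radius) seals sub-element clefts
# between peg and socket wall so that distances count from the outer surface.

#' Label the peg components of a section
#'
#' Connected components (connectivity per config, default 8) of the peg class
#' with at least `config$min_component_px` pixels. The number of components
#' per section is the peg-frequency statistic.
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @return Integer matrix of component labels (0 = not a counted peg).
#' @export
peg_components <- function(section, config = pipeline_config()) {
  stopifnot(inherits(section, "segmented_section"))
  pegmask <- section$labels == class_codes()[["peg"]]
  lab <- label_components(pegmask, connectivity = config$connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < config$min_component_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    keep <- sort(unique(lab[lab > 0L]))
    lab[] <- match(lab, keep, nomatch = 0L)
  }
  lab
}

#' Depth map from the abluminal endothelial surface
#'
#' Builds the mask M = endothelium + pegs + lumen, closes it with a disk of
#' radius `round(closing_radius_nm / pixel_size_nm)` pixels, and returns the
#' exact Euclidean distance (nm) of every pixel of the closed mask to the
#' nearest pixel outside it. Distances are 0 outside the mask and increase
#' moving from the abluminal surface toward the lumen.
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @return Numeric matrix of distances in nm.
#' @export
depth_map <- function(section, config = pipeline_config()) {
  masks <- class_masks(section, config)
  if (!any(masks$endothelial)) stop("endothelial mask is empty")
  m <- masks$endothelial | masks$peg | masks$lumen
  r_px <- round(config$closing_radius_nm / section$pixel_size_nm)
  if (r_px < 1) {
    warning("closing radius ", config$closing_radius_nm,
            " nm is below one pixel at ", section$pixel_size_nm,
            " nm/px; clamped to 1 px")
    r_px <- 1
  }
  closed <- close_mask(m, disk_kernel(r_px))
  euclidean_dt(closed) * section$pixel_size_nm
}

#' Per-peg maximum depth and area
#'
#' For each counted peg component, the maximum depth-map value over its pixels
#' and its cross-sectional area (`pixel count * pixel_size_nm^2`). Pegs with
#' no pericyte pixel within one dilation step are retained but flagged
#' (`orphan = TRUE`), since a peg should protrude from a pericyte.
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @param vessel_id Optional id copied into the output.
#' @return Data frame with one row per peg: component_id, area_nm2,
#'   max_depth_nm, centroid_row, centroid_col, orphan, section_index.
#' @export
peg_max_depths <- function(section, config = pipeline_config(),
                           vessel_id = NA_character_) {
  labs <- peg_components(section, config)
  n <- max(labs)
  empty <- data.frame(vessel_id = character(), section_index = integer(),
                      component_id = integer(), area_nm2 = numeric(),
                      max_depth_nm = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), orphan = logical())
  if (n == 0L) return(empty)
  dm <- depth_map(section, config)
  peri_dil <- dilate_mask(section$labels == class_codes()[["pericyte"]],
                          box_kernel())
  px <- section$pixel_size_nm
  nr <- nrow(labs)
  rows <- lapply(seq_len(n), function(k) {
    idx <- which(labs == k)
    data.frame(vessel_id = vessel_id,
               section_index = section$section_index,
               component_id = k,
               area_nm2 = length(idx) * px^2,
               max_depth_nm = max(dm[idx]),
               centroid_row = mean(((idx - 1L) %% nr) + 1L),
               centroid_col = mean(((idx - 1L) %/% nr) + 1L),
               orphan = !any(peri_dil[idx]))
  })
  do.call(rbind, rows)
}

#' Peg records for a whole vessel
#'
#' @param stack A [vessel_stack()].
#' @param config A [pipeline_config()].
#' @return Data frame of per-peg records over all non-excluded sections
#'   (zero rows when the vessel has no pegs).
#' @export
vessel_pegs <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "vessel_stack"))
  secs <- included_sections(stack)
  do.call(rbind, lapply(secs, peg_max_depths, config = config,
                        vessel_id = stack$vessel_id))
}
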