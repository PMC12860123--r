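#' Semantic class codes of the six-class capillary segmentation
#'
#' The pipeline operates on integer label maps with six classes: background,
#' basement membrane, endothelial cell, pericyte, pericyte peg (the portion of
#' a pericyte protruding into an endothelial invagination), and lumen.
#' Erythrocytes inside the lumen are labeled lumen; the lumen is excluded from
#' every volume denominator regardless of content.
#'
#' @return Named integer vector mapping class name to canonical code.
#' @export
#' @examples
#' class_codes()
class_codes <- function() {
  c(background = 0L, basement_membrane = 1L, endothelial = 2L,
    pericyte = 3L, peg = 4L, lumen = 5L)
}

#' Pipeline configuration
#'
#' Collects every tunable physical and algorithmic parameter. Physical sizes
#' are stated in nanometres and converted to pixels per image via that image's
#' `pixel_size_nm`; nothing is hard-coded in pixel units.
#'
#' @param class_map Named character vector (or list) mapping on-disk integer
#'   label values (names) to class names (values among `names(class_codes())`).
#'   The mapping is explicit, never positional. Default: identity over codes
#'   0..5.
#' @param closing_radius_nm Radius (nm) of the disk structuring element used to
#'   close the endothelial+peg+lumen mask before the depth transform, sealing
#'   sub-element clefts between peg and socket. Default 134.
#' @param contact_dilation_px Dilation steps (3x3 square element) applied to
#'   the endothelial mask when defining pericyte-endothelial contact. Default 1.
#' @param merge_peg_into_pericyte Count peg pixels with the pericyte
#'   (`pericyte_total` mask) in volume and contact measurements. Default TRUE.
#' @param min_component_px Minimum pixel count for a peg component to be
#'   counted. Default 4.
#' @param connectivity Pixel connectivity for components and skeletons,
#'   4 or 8. Default 8.
#' @param perimeter_correction `"kulpa"` (default) applies the isotropic
#'   chain-length bias correction to perimeters and skeleton lengths; `"none"`
#'   uses the raw (1, sqrt 2) chain.
#' @param skeleton_length_metric `"chain"` (default) measures class lengths as
#'   corner-corrected chain length; `"pixel_count"` sums skeleton pixels (the
#'   historical convention) for fidelity checks. Ratios are insensitive to the
#'   choice.
#' @return Object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(class_map = NULL,
                            closing_radius_nm = 134,
                            contact_dilation_px = 1L,
                            merge_peg_into_pericyte = TRUE,
                            min_component_px = 4L,
                            connectivity = 8L,
                            perimeter_correction = c("kulpa", "none"),
                            skeleton_length_metric = c("chain", "pixel_count")) {
  codes <- class_codes()
  if (is.null(class_map)) {
    class_map <- stats::setNames(names(codes), as.character(codes))
  }
  class_map <- unlist(class_map)
  if (!all(class_map %in% names(codes))) {
    stop("class_map values must be class names: ",
         paste(setdiff(class_map, names(codes)), collapse = ", "))
  }
  if (anyDuplicated(names(class_map)) || anyDuplicated(class_map)) {
    stop("class_map must be one-to-one")
  }
  stopifnot(closing_radius_nm > 0, contact_dilation_px >= 1L,
            min_component_px >= 0L, connectivity %in% c(4L, 8L))
  structure(list(
    class_map = class_map,
    closing_radius_nm = closing_radius_nm,
    contact_dilation_px = as.integer(contact_dilation_px),
    merge_peg_into_pericyte = isTRUE(merge_peg_into_pericyte),
    min_component_px = as.integer(min_component_px),
    connectivity = as.integer(connectivity),
    perimeter_correction = match.arg(perimeter_correction),
    skeleton_length_metric = match.arg(skeleton_length_metric)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments; `class_map` is a mapping from on-disk integer to class name.
#' @return A `pipeline_config`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, y)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$class_map <- as.list(y$class_map)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' One segmented z-section
#'
#' @param labels Integer matrix (rows x cols, at least 16 x 16) of canonical
#'   class codes (see [class_codes()]).
#' @param pixel_size_nm Physical edge length of one pixel, nm (> 0). There is
#'   no default: the calibration must always be supplied.
#' @param section_index Non-negative integer position in the stack.
#' @param excluded Flag a section (for example for imaging artifacts) so that
#'   aggregation skips it while the data are retained.
#' @return Object of class `segmented_section`.
#' @export
segmented_section <- function(labels, pixel_size_nm, section_index = 0L,
                              excluded = FALSE) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (nrow(labels) < 16L || ncol(labels) < 16L) {
    stop("label grid must be at least 16 x 16")
  }
  stopifnot(is.numeric(pixel_size_nm), pixel_size_nm > 0,
            section_index >= 0L)
  bad <- setdiff(unique(as.vector(labels)), unname(class_codes()))
  if (length(bad)) {
    stop("unknown label value(s) ", paste(bad, collapse = ", "),
         " in section ", section_index)
  }
  structure(list(
    labels = labels,
    pixel_size_nm = as.numeric(pixel_size_nm),
    section_index = as.integer(section_index),
    excluded = isTRUE(excluded)
  ), class = "segmented_section")
}

#' An ordered stack of segmented sections for one vessel
#'
#' @param sections List of [segmented_section()] objects sharing grid shape
#'   and pixel size, with strictly increasing `section_index`; at least one
#'   must not be excluded.
#' @param z_spacing_nm Section spacing, nm (default 80, the nominal serial
#'   ultrathin section thickness).
#' @param vessel_id Identifier string.
#' @param group Experimental group label (e.g. "WT", "N3KO").
#' @return Object of class `vessel_stack`.
#' @export
vessel_stack <- function(sections, z_spacing_nm = 80, vessel_id = "vessel",
                         group = "unknown") {
  stopifnot(length(sections) >= 1L, z_spacing_nm > 0)
  if (!all(vapply(sections, inherits, logical(1L), "segmented_section"))) {
    stop("sections must be segmented_section objects")
  }
  dims <- vapply(sections, function(s) dim(s$labels), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("all sections must share the same grid shape")
  }
  px <- vapply(sections, function(s) s$pixel_size_nm, numeric(1L))
  if (any(px != px[1L])) stop("all sections must share pixel_size_nm")
  idx <- vapply(sections, function(s) s$section_index, integer(1L))
  if (any(diff(idx) <= 0L)) stop("section_index must be strictly increasing")
  if (!any(!vapply(sections, function(s) s$excluded, logical(1L)))) {
    stop("stack needs at least one non-excluded section")
  }
  structure(list(
    sections = sections,
    z_spacing_nm = as.numeric(z_spacing_nm),
    vessel_id = as.character(vessel_id),
    group = as.character(group)
  ), class = "vessel_stack")
}

#' @export
print.vessel_stack <- function(x, ...) {
  n_excl <- sum(vapply(x$sections, function(s) s$excluded, logical(1L)))
  cat(sprintf(
    "<vessel_stack> %s (group %s): %d sections (%d excluded), %d x %d px @ %g nm/px, dz = %g nm\n",
    x$vessel_id, x$group, length(x$sections), n_excl,
    nrow(x$sections[[1L]]$labels), ncol(x$sections[[1L]]$labels),
    x$sections[[1L]]$pixel_size_nm, x$z_spacing_nm))
  invisible(x)
}

# sections that enter aggregation
included_sections <- function(stack) {
  Filter(function(s) !s$excluded, stack$sections)
}

#' Per-class boolean masks of a section
#'
#' The per-class masks are pairwise disjoint and jointly cover the grid. When
#' `config$merge_peg_into_pericyte` is set (the default), an additional
#' `pericyte_total` mask (pericyte plus peg) is appended; it overlaps its two
#' constituents but is not part of the partition.
#'
#' @param section A [segmented_section()].
#' @param config A [pipeline_config()].
#' @return Named list of logical matrices.
#' @export
class_masks <- function(section, config = pipeline_config()) {
  stopifnot(inherits(section, "segmented_section"))
  codes <- class_codes()
  masks <- lapply(codes, function(v) section$labels == v)
  names(masks) <- names(codes)
  if (config$merge_peg_into_pericyte) {
    masks$pericyte_total <- masks$pericyte | masks$peg
  }
  masks
}

#' Write a vessel stack to disk
#'
#' Writes a multi-page 8-bit TIFF of label values plus a JSON metadata sidecar
#' (`<path>.json`) carrying vessel id, group, calibration, exclusion list and
#' the integer-to-class mapping. `read_stack(write_stack(s))` reproduces `s`
#' bit-exactly.
#'
#' @param stack A [vessel_stack()].
#' @param path Destination TIFF filename (sidecar written next to it).
#' @param config A [pipeline_config()]; its `class_map` defines the on-disk
#'   integers.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, config = pipeline_config()) {
  stopifnot(inherits(stack, "vessel_stack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("destination directory does not exist: ", dir)
  codes <- class_codes()
  # canonical code -> on-disk integer
  disk_of_code <- stats::setNames(
    as.integer(names(config$class_map)),
    as.character(codes[config$class_map]))
  pages <- lapply(stack$sections, function(s) {
    disk <- matrix(disk_of_code[as.character(s$labels)],
                   nrow(s$labels), ncol(s$labels))
    disk / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(
    vessel_id = stack$vessel_id,
    group = stack$group,
    pixel_size_nm = stack$sections[[1L]]$pixel_size_nm,
    z_spacing_nm = stack$z_spacing_nm,
    section_index = vapply(stack$sections, function(s) s$section_index,
                           integer(1L)),
    excluded_sections = vapply(stack$sections, function(s) s$section_index,
                               integer(1L))[
      vapply(stack$sections, function(s) s$excluded, logical(1L))]
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a vessel stack from disk
#'
#' @param path Multi-page TIFF written by [write_stack()] (or compatible).
#' @param meta Optional metadata file path; defaults to `<path>.json`.
#'   Must supply `pixel_size_nm`; `z_spacing_nm`, `vessel_id`, `group`,
#'   `section_index` and `excluded_sections` are honoured when present.
#' @param config A [pipeline_config()]; on-disk values are remapped through
#'   its `class_map`, and any value absent from the map is a hard error naming
#'   the value and the section.
#' @return A [vessel_stack()]. Excluded sections are flagged but retained.
#' @export
read_stack <- function(path, meta = NULL, config = pipeline_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(meta)) meta <- paste0(path, ".json")
  if (!file.exists(meta)) stop("metadata file not found: ", meta)
  md <- jsonlite::read_json(meta, simplifyVector = TRUE)
  if (is.null(md$pixel_size_nm)) {
    stop("metadata must supply pixel_size_nm (no default calibration exists)")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  codes <- class_codes()
  code_of_disk <- stats::setNames(unname(codes[config$class_map]),
                                  names(config$class_map))
  sec_idx <- md$section_index
  if (is.null(sec_idx)) sec_idx <- seq_along(pages) - 1L
  excl <- as.integer(md$excluded_sections)
  sections <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    disk <- round(pages[[i]] * 255)
    vals <- unique(as.vector(disk))
    bad <- setdiff(as.character(vals), names(code_of_disk))
    if (length(bad)) {
      stop("unknown label value(s) ", paste(bad, collapse = ", "),
           " in section ", sec_idx[i], " of ", path)
    }
    lab <- matrix(code_of_disk[as.character(disk)], nrow(disk), ncol(disk))
    sections[[i]] <- segmented_section(
      lab, pixel_size_nm = md$pixel_size_nm,
      section_index = as.integer(sec_idx[i]),
      excluded = as.integer(sec_idx[i]) %in% excl)
  }
  vessel_stack(sections,
               z_spacing_nm = if (is.null(md$z_spacing_nm)) 80 else md$z_spacing_nm,
               vessel_id = if (is.null(md$vessel_id)) basename(path) else md$vessel_id,
               group = if (is.null(md$group)) "unknown" else md$group)
}
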