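# End-to-end orchestration: measure whole stacks, aggregate per-vessel
# tables, run the group statistics, and drive a fully synthetic cohort
# demonstration.

#' Measure everything for one vessel stack
#'
#' @param stack A [vessel_stack()].
#' @param config A [pipeline_config()].
#' @return List with `vessel` (one-row data frame: morphometry plus pooled
#'   coverage/contact and peg summaries), `sections` (per-section contact
#'   profiles), `pegs` (per-peg records).
#' @export
measure_vessel <- function(stack, config = pipeline_config()) {
  morpho <- vessel_morphometry(stack, config)
  con <- vessel_contact(stack, config)
  pegs <- vessel_pegs(stack, config)
  n_sec <- morpho$n_sections_used
  vessel <- cbind(morpho,
                  coverage_pct = con$coverage_pct,
                  contact_pct = con$contact_pct,
                  peg_count = nrow(pegs),
                  pegs_per_section = nrow(pegs) / n_sec,
                  peg_mean_depth_nm = if (nrow(pegs)) mean(pegs$max_depth_nm) else NA_real_,
                  peg_max_depth_nm = if (nrow(pegs)) max(pegs$max_depth_nm) else NA_real_,
                  peg_mean_area_nm2 = if (nrow(pegs)) mean(pegs$area_nm2) else NA_real_)
  sections <- cbind(vessel_id = stack$vessel_id, group = stack$group,
                    con$sections)
  if (nrow(pegs)) pegs <- cbind(pegs, group = stack$group)
  list(vessel = vessel, sections = sections, pegs = pegs)
}

#' Measure every stack in a directory
#'
#' Reads every `*.tif`/`*.tiff` stack (with its JSON sidecar) under
#' `input_dir`, measures it, and writes `vessels.csv`, `sections.csv`,
#' `pegs.csv` and `manifest.json` into `output_dir`. Unreadable stacks are
#' skipped with a logged error; zero successes is an error.
#'
#' @param input_dir Directory of stacks written by [write_stack()].
#' @param config A [pipeline_config()].
#' @param output_dir Destination directory (created if needed).
#' @return Invisibly, the list of output tables.
#' @export
run_measure <- function(input_dir, config = pipeline_config(),
                        output_dir = file.path(input_dir, "results")) {
  paths <- sort(list.files(input_dir, pattern = "\\.tiff?$",
                           full.names = TRUE))
  if (length(paths) == 0L) stop("no TIFF stacks found in ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  vessels <- list(); sections <- list(); pegs <- list(); inventory <- list()
  errors <- character()
  for (p in paths) {
    res <- tryCatch({
      stack <- read_stack(p, config = config)
      m <- measure_vessel(stack, config)
      inventory[[length(inventory) + 1L]] <- list(
        file = basename(p), vessel_id = stack$vessel_id, group = stack$group,
        n_sections = length(stack$sections),
        n_excluded = sum(vapply(stack$sections, function(s) s$excluded,
                                logical(1L))))
      m
    }, error = function(e) {
      message("skipping ", basename(p), ": ", conditionMessage(e))
      errors <<- c(errors, paste0(basename(p), ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      vessels[[length(vessels) + 1L]] <- res$vessel
      sections[[length(sections) + 1L]] <- res$sections
      if (nrow(res$pegs)) pegs[[length(pegs) + 1L]] <- res$pegs
    }
  }
  if (length(vessels) == 0L) stop("no stack could be measured")
  out <- list(vessels = do.call(rbind, vessels),
              sections = do.call(rbind, sections),
              pegs = if (length(pegs)) do.call(rbind, pegs) else
                data.frame())
  utils::write.csv(out$vessels, file.path(output_dir, "vessels.csv"),
                   row.names = FALSE)
  utils::write.csv(out$sections, file.path(output_dir, "sections.csv"),
                   row.names = FALSE)
  utils::write.csv(out$pegs, file.path(output_dir, "pegs.csv"),
                   row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("pericytemorph")),
                   config = {
                     cfg <- unclass(config)
                     cfg$class_map <- as.list(cfg$class_map)
                     cfg
                   },
                   inputs = inventory,
                   skipped = errors,
                   outputs = c("vessels.csv", "sections.csv", "pegs.csv"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Full synthetic-cohort demonstration
#'
#' Generates a four-group cohort (default sizes 19/16/18/23 vessels) with
#' programmed effects in one group (default: deeper, wider pegs and more
#' direct contact in "N3KO"), measures every vessel, and runs the group
#' statistics on each per-vessel metric. The demonstration shows that the
#' measurement chain recovers programmed group differences and stays quiet on
#' metrics with no programmed effect.
#'
#' @param seed Integer seed for the whole run.
#' @param output_dir Optional directory; when given, vessels.csv, pegs.csv and
#'   a stats summary CSV are written there.
#' @param n_per_group Named integer vector of group sizes.
#' @param base Base [synthetic_vessel_spec()]; the default uses 40 nm pixels
#'   and 3 sections per vessel to keep a full cohort fast.
#' @param effects Per-group spec offsets (see [generate_cohort()]).
#' @param config A [pipeline_config()].
#' @return List with `vessels` (per-vessel table), `pegs`, `stats` (list of
#'   [compare_groups()] results per metric), `truth` (per-vessel ground-truth
#'   table).
#' @export
run_full_demo <- function(seed = 1L, output_dir = NULL,
                          n_per_group = c(WT = 19L, N3KO = 16L,
                                          Diabetic = 18L, CondKO = 23L),
                          base = synthetic_vessel_spec(pixel_size_nm = 40,
                                                       n_sections = 3L),
                          effects = list(N3KO = c(peg_depth_nm = 250,
                                                  peg_width_nm = 100,
                                                  contact_arc_fraction = 0.08),
                                         Diabetic = c(peg_width_nm = 100)),
                          config = pipeline_config()) {
  cohort <- generate_cohort(n_per_group = n_per_group, base = base,
                            effects = effects, seed = seed)
  vessels <- list(); pegs <- list(); truths <- list()
  for (v in cohort) {
    m <- measure_vessel(v$stack, config)
    vessels[[length(vessels) + 1L]] <- m$vessel
    if (nrow(m$pegs)) pegs[[length(pegs) + 1L]] <- m$pegs
    truths[[length(truths) + 1L]] <- data.frame(
      vessel_id = v$stack$vessel_id, group = v$stack$group,
      true_diameter_um = v$truth$true_diameter_um,
      true_coverage_pct = v$truth$true_coverage_pct,
      true_contact_pct = v$truth$true_contact_pct,
      true_pericyte_volume_pct = v$truth$true_pericyte_volume_pct,
      true_bm_volume_pct = v$truth$true_bm_volume_pct)
  }
  vessels <- do.call(rbind, vessels)
  pegs <- if (length(pegs)) do.call(rbind, pegs) else data.frame()
  truth <- do.call(rbind, truths)
  metrics <- c("diameter_um", "pericyte_volume_pct", "bm_volume_pct",
               "coverage_pct", "contact_pct", "peg_mean_depth_nm",
               "peg_mean_area_nm2", "pegs_per_section")
  stats_out <- lapply(metrics, function(mname) {
    samples <- split(vessels[[mname]], vessels$group)
    tryCatch(compare_groups(samples, metric_name = mname),
             error = function(e) NULL)
  })
  names(stats_out) <- metrics
  stats_out <- Filter(Negate(is.null), stats_out)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(vessels, file.path(output_dir, "vessels.csv"),
                     row.names = FALSE)
    utils::write.csv(pegs, file.path(output_dir, "pegs.csv"),
                     row.names = FALSE)
    summ <- do.call(rbind, lapply(stats_out, function(s) {
      data.frame(metric = s$metric_name, H = s$omnibus_stat,
                 df = s$omnibus_df, p = s$omnibus_p,
                 significant = s$significant)
    }))
    utils::write.csv(summ, file.path(output_dir, "stats_summary.csv"),
                     row.names = FALSE)
  }
  list(vessels = vessels, pegs = pegs, stats = stats_out, truth = truth)
}
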