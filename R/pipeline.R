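#' Run the full social-structure analysis pipeline
#'
#' End-to-end composition of the package: read (or accept) a sighting
#' database, optionally filter identifications by photo quality, build the
#' half-weight association matrix over the chosen mark grades, construct the
#' sociogram, partition it into communities (connected components), assign
#' the remaining individuals via their permanently marked associates, and
#' produce the composition tables, pairwise chi-square tests, and — when
#' distances from shore are available or computable from a coastline — the
#' spatial segregation comparison. All artifacts are written to `out_dir`
#' together with a JSON manifest. Analytic outputs are deterministic: two
#' runs on the same input and configuration produce identical files (the
#' manifest's timestamp aside).
#'
#' @param sightings a [sighting_database()] or path to a sightings CSV.
#' @param out_dir output directory (created if needed).
#' @param coastline optional [coastline()] or path to a coastline file, used
#'   to fill missing encounter distances (never overwriting supplied ones).
#' @param grade_filter mark grades included in the network analysis
#'   (default permanently marked individuals only).
#' @param hwi_threshold sociogram edge threshold (edge iff HWI > threshold).
#' @param alpha,correction,n_comparisons settings for
#'   [pairwise_network_tests()].
#' @param grouping optional named list of two label sets for the pooled
#'   comparisons; default largest community vs all others.
#' @param worst_quality optional photo-quality cutoff (see
#'   [filter_quality()]).
#' @return An object of class `report_bundle`: list with the computed
#'   objects (`summary`, `assoc`, `sociogram`, `partition`, `severity`,
#'   `pairwise_mark`, `pairwise_tip`, `spatial`, `group_size_by_area`) and
#'   `manifest` (files written, config echo, versions).
#' @export
run_pipeline <- function(sightings, out_dir,
                         coastline = NULL,
                         grade_filter = "PERMANENT",
                         hwi_threshold = 0,
                         alpha = 0.05,
                         correction = "bonferroni",
                         n_comparisons = NULL,
                         grouping = NULL,
                         worst_quality = NULL) {
  db <- if (inherits(sightings, "sighting_db")) sightings
        else read_sightings(sightings)
  report <- validate_database(db)
  if (nrow(report))
    stop_domain("input database is invalid:\n  ",
                paste(report$message, collapse = "\n  "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(worst_quality)) db <- filter_quality(db, worst_quality)
  if (!is.null(coastline)) {
    if (is.character(coastline)) coastline <- read_coastline(coastline)
    db <- fill_distances(db, coastline)
  }

  files <- character()
  out <- function(name) file.path(out_dir, name)
  emit <- function(name) files <<- c(files, name)

  summary <- summarize_catalog(db)
  summary_json(summary, out("catalog_summary.json")); emit("catalog_summary.json")

  assoc <- association_matrix(db, grade_filter = grade_filter)
  write_association(assoc, out("association_long.csv"),
                    out("association_matrix.csv"))
  emit("association_long.csv"); emit("association_matrix.csv")

  g <- build_sociogram(assoc, threshold = hwi_threshold, db = db)
  partition <- assign_unmarked(db, detect_communities(g))
  write_sociogram(g, out("sociogram.graphml"), partition)
  emit("sociogram.graphml")
  write_edge_list(g, out("sociogram_edges.csv")); emit("sociogram_edges.csv")
  write_partition(partition, out("partition.csv")); emit("partition.csv")

  severity <- mark_severity_table(db, partition, grouping = grouping)
  write.csv(severity, out("mark_severity.csv"), row.names = FALSE)
  emit("mark_severity.csv")

  pairwise_mark <- pairwise_network_tests(
    db, partition, feature = "permanent_mark", alpha = alpha,
    correction = correction, n_comparisons = n_comparisons)
  write_pairwise_tests(pairwise_mark, out("pairwise_mark.csv"),
                       out("pairwise_mark.json"))
  emit("pairwise_mark.csv"); emit("pairwise_mark.json")

  pairwise_tip <- tryCatch(
    pairwise_network_tests(db, partition, feature = "tip_damage",
                           alpha = alpha, correction = correction,
                           n_comparisons = n_comparisons),
    error = function(e) NULL)
  if (!is.null(pairwise_tip)) {
    write_pairwise_tests(pairwise_tip, out("pairwise_tip.csv"),
                         out("pairwise_tip.json"))
    emit("pairwise_tip.csv"); emit("pairwise_tip.json")
  }

  spatial <- NULL
  skipped <- character()
  if (any(!is.na(db$encounters$distance_from_shore_km))) {
    spatial <- tryCatch(
      compare_group_distances(db, partition, grouping = grouping),
      error = function(e) NULL)
  }
  if (!is.null(spatial)) {
    payload <- list(summary = spatial$summary,
                    test = unclass(spatial$test),
                    n_excluded_missing_distance =
                      spatial$n_excluded_missing_distance,
                    n_excluded_unattributed = spatial$n_excluded_unattributed)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                na = "null", pretty = TRUE),
               out("distance_comparison.json"))
    emit("distance_comparison.json")
    write.csv(spatial$summary, out("distance_summary.csv"),
              row.names = FALSE)
    emit("distance_summary.csv")
  } else {
    skipped <- c(skipped, "spatial: no usable distances from shore")
    message("spatial stage skipped: no usable distances from shore")
  }

  gsize <- tryCatch(compare_area_group_sizes(db), error = function(e) NULL)
  if (!is.null(gsize)) {
    writeLines(jsonlite::toJSON(list(summary = gsize$summary,
                                     test = unclass(gsize$test)),
                                auto_unbox = TRUE, digits = NA, na = "null",
                                pretty = TRUE),
               out("group_size_by_area.json"))
    emit("group_size_by_area.json")
  }

  manifest <- list(
    files = files,
    skipped = skipped,
    config = list(grade_filter = grade_filter,
                  hwi_threshold = hwi_threshold, alpha = alpha,
                  correction = correction,
                  n_comparisons = n_comparisons,
                  worst_quality = worst_quality),
    package_version = as.character(packageVersion("photoidnet")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             out("manifest.json"))

  structure(list(db = db, summary = summary, assoc = assoc, sociogram = g,
                 partition = partition, severity = severity,
                 pairwise_mark = pairwise_mark, pairwise_tip = pairwise_tip,
                 spatial = spatial, group_size_by_area = gsize,
                 manifest = manifest, out_dir = out_dir),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> in", x$out_dir, "\n")
  cat("  communities:", length(attr(x$partition, "labels")), "\n")
  cat("  files:", paste(x$manifest$files, collapse = ", "), "\n")
  if (length(x$manifest$skipped))
    cat("  skipped:", paste(x$manifest$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Simulate a sighting database and write it to disk
#'
#' Convenience wrapper pairing [generate_sightings()] with the CSV writers:
#' writes `sightings.csv` and `truth.csv` into `out_dir` and prints summary
#' counts.
#'
#' @param out_dir output directory (created if needed).
#' @param config a `sim_config` (default [default_config()]).
#' @param seed integer seed.
#' @param quiet suppress the summary printout.
#' @return invisibly, the [generate_sightings()] result.
#' @export
simulate_to_dir <- function(out_dir, config = default_config(), seed,
                            quiet = FALSE) {
  sim <- generate_sightings(config, seed = seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_sightings(sim$db, file.path(out_dir, "sightings.csv"))
  write_truth(sim$truth, file.path(out_dir, "truth.csv"))
  if (!quiet) {
    cat("simulated", nrow(sim$db$individuals), "individuals,",
        nrow(sim$db$encounters), "encounters,",
        nrow(sim$db$sightings), "identifications ->", out_dir, "\n")
  }
  invisible(sim)
}
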