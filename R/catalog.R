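#' Mark severity grades
#'
#' The three dorsal-fin mark severity grades used in photo-identification
#' catalogues, ordered from most to least reliable for re-identification:
#' permanently marked fins carry deep cuts or large stable scars, temporarily
#' marked fins carry small cuts or tooth rakes that may heal within a year,
#' and superficially marked fins carry only shallow rakes and lesions.
#' @export
MARK_GRADES <- c("PERMANENT", "TEMPORARY", "SUPERFICIAL")

#' Construct a sighting database
#'
#' A sighting database is the core container of the package: a photo-ID
#' catalogue of individuals, a table of group encounters, and a long table of
#' identifications (one row per individual identified within an encounter).
#' The constructor coerces and canonically orders its inputs but performs only
#' light checking; use [validate_database()] for a full invariant report.
#'
#' @param individuals data.frame with columns `individual_id` (character,
#'   unique), `mark_grade` (one of [MARK_GRADES]) and `tip_damage` (logical:
#'   characteristic damage to the tip of the dorsal fin).
#' @param encounters data.frame with columns `encounter_id` (character,
#'   unique), `date` (`Date` or "YYYY-MM-DD" string), `area` (free-text label)
#'   and optionally `latitude`, `longitude` (decimal degrees WGS84),
#'   `distance_from_shore_km` and `group_size_estimate`.
#' @param sightings data.frame with columns `encounter_id`, `individual_id`
#'   and optionally `photo_quality` (integer, 1 = best).
#' @return An object of class `sighting_db` (a list with elements
#'   `individuals`, `encounters`, `sightings`), rows sorted by their keys.
#' @seealso [read_sightings()], [write_sightings()], [validate_database()]
#' @export
sighting_database <- function(individuals = NULL, encounters = NULL,
                              sightings = NULL) {
  individuals <- as.data.frame(individuals %||% data.frame(
    individual_id = character(), mark_grade = character(),
    tip_damage = logical()))
  encounters <- as.data.frame(encounters %||% data.frame(
    encounter_id = character(), date = as.Date(character()),
    area = character()))
  sightings <- as.data.frame(sightings %||% data.frame(
    encounter_id = character(), individual_id = character()))

  individuals$individual_id <- as.character(individuals$individual_id)
  individuals$mark_grade <- as.character(individuals$mark_grade)
  individuals$tip_damage <- as.logical(individuals$tip_damage)

  encounters$encounter_id <- as.character(encounters$encounter_id)
  encounters$date <- as.Date(encounters$date)
  encounters$area <- as.character(encounters$area)
  for (col in c("latitude", "longitude", "distance_from_shore_km")) {
    if (is.null(encounters[[col]]))
      encounters <- add_column(encounters, col, NA_real_)
    encounters[[col]] <- as.numeric(encounters[[col]])
  }
  if (is.null(encounters$group_size_estimate))
    encounters <- add_column(encounters, "group_size_estimate", NA_integer_)
  encounters$group_size_estimate <- as.integer(encounters$group_size_estimate)

  sightings$encounter_id <- as.character(sightings$encounter_id)
  sightings$individual_id <- as.character(sightings$individual_id)
  if (is.null(sightings$photo_quality))
    sightings <- add_column(sightings, "photo_quality", NA_integer_)
  sightings$photo_quality <- as.integer(sightings$photo_quality)

  individuals <- individuals[order(individuals$individual_id), , drop = FALSE]
  encounters <- encounters[order(encounters$encounter_id), , drop = FALSE]
  sightings <- sightings[order(sightings$encounter_id,
                               sightings$individual_id), , drop = FALSE]
  rownames(individuals) <- rownames(encounters) <- rownames(sightings) <- NULL

  structure(list(individuals = individuals, encounters = encounters,
                 sightings = sightings), class = "sighting_db")
}

#' @export
print.sighting_db <- function(x, ...) {
  cat("<sighting_db>", nrow(x$individuals), "individuals,",
      nrow(x$encounters), "encounters,",
      nrow(x$sightings), "identifications\n")
  invisible(x)
}

sightings_schema <- list(
  required = c("encounter_id", "date", "area", "individual_id",
               "mark_grade", "tip_damage"),
  optional = c("latitude", "longitude", "distance_from_shore_km",
               "group_size_estimate", "photo_quality"))

#' Read a sighting database from a long-format CSV
#'
#' The file holds one row per identification. Required columns:
#' `encounter_id`, `date` (YYYY-MM-DD), `area`, `individual_id`, `mark_grade`
#' (PERMANENT | TEMPORARY | SUPERFICIAL), `tip_damage` (0 | 1). Optional
#' columns: `latitude`, `longitude`, `distance_from_shore_km`,
#' `group_size_estimate`, `photo_quality` (integer, 1 = best). Rows sharing an
#' `encounter_id` are merged into one encounter; encounter metadata and
#' individual metadata must be identical across the rows they span —
#' conflicting values raise a consistency error rather than a silent merge,
#' because a photo-ID catalogue must be internally consistent. A duplicated
#' (encounter, individual) row is likewise an error, never silently
#' deduplicated.
#'
#' @param path path to a CSV file (UTF-8, comma separated, header required).
#' @return A validated [sighting_database()].
#' @export
read_sightings <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(sightings_schema$required, names(raw))
  if (length(missing_cols))
    stop_domain("schema error: missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(raw),
                     c(sightings_schema$required, sightings_schema$optional))
  if (length(unknown))
    stop_domain("schema error: unknown column(s): ",
                paste(unknown, collapse = ", "))
  if (nrow(raw) == 0) return(sighting_database())

  for (col in sightings_schema$optional)
    if (is.null(raw[[col]])) raw[[col]] <- NA_character_
  blank_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  for (col in names(raw)) raw[[col]] <- blank_to_na(raw[[col]])

  key <- paste(raw$encounter_id, raw$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- raw[duplicated(key), , drop = FALSE][1, ]
    stop_domain("consistency error: duplicate identification row for ",
                "encounter '", d$encounter_id, "', individual '",
                d$individual_id, "'")
  }

  bad_grade <- setdiff(unique(raw$mark_grade), MARK_GRADES)
  if (length(bad_grade))
    stop_domain("schema error: invalid mark_grade value(s): ",
                paste(bad_grade, collapse = ", "))

  # individual metadata must agree across rows
  ind_meta <- unique(raw[, c("individual_id", "mark_grade", "tip_damage")])
  if (anyDuplicated(ind_meta$individual_id)) {
    dup <- ind_meta$individual_id[duplicated(ind_meta$individual_id)][1]
    stop_domain("consistency error: conflicting metadata for individual '",
                dup, "'")
  }
  enc_cols <- c("encounter_id", "date", "area", "latitude", "longitude",
                "distance_from_shore_km", "group_size_estimate")
  enc_meta <- unique(raw[, enc_cols])
  if (anyDuplicated(enc_meta$encounter_id)) {
    dup <- enc_meta$encounter_id[duplicated(enc_meta$encounter_id)][1]
    stop_domain("consistency error: conflicting metadata for encounter '",
                dup, "'")
  }

  individuals <- data.frame(
    individual_id = ind_meta$individual_id,
    mark_grade = ind_meta$mark_grade,
    tip_damage = as.integer(ind_meta$tip_damage) > 0)
  encounters <- data.frame(
    encounter_id = enc_meta$encounter_id,
    date = as.Date(enc_meta$date),
    area = enc_meta$area,
    latitude = as.numeric(enc_meta$latitude),
    longitude = as.numeric(enc_meta$longitude),
    distance_from_shore_km = as.numeric(enc_meta$distance_from_shore_km),
    group_size_estimate = as.integer(enc_meta$group_size_estimate))
  sightings <- data.frame(
    encounter_id = raw$encounter_id,
    individual_id = raw$individual_id,
    photo_quality = as.integer(raw$photo_quality))

  db <- sighting_database(individuals, encounters, sightings)
  report <- validate_database(db)
  if (nrow(report))
    stop_domain("invalid sighting database: ",
                paste(report$message, collapse = "; "))
  db
}

#' Write a sighting database to a long-format CSV
#'
#' Inverse of [read_sightings()]: produces one row per identification with
#' encounter and individual metadata repeated on each row. Rows are written in
#' canonical (encounter, individual) order so repeated writes of the same
#' database are byte-identical.
#'
#' @param db a [sighting_database()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(db, path) {
  stopifnot(inherits(db, "sighting_db"))
  long <- merge(db$sightings, db$encounters, by = "encounter_id")
  long <- merge(long, db$individuals, by = "individual_id")
  long <- long[order(long$encounter_id, long$individual_id), , drop = FALSE]
  out <- data.frame(
    encounter_id = long$encounter_id,
    date = format(long$date, "%Y-%m-%d"),
    area = long$area,
    latitude = long$latitude,
    longitude = long$longitude,
    distance_from_shore_km = long$distance_from_shore_km,
    group_size_estimate = long$group_size_estimate,
    individual_id = long$individual_id,
    mark_grade = long$mark_grade,
    tip_damage = as.integer(long$tip_damage),
    photo_quality = long$photo_quality)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a sighting database
#'
#' Checks every structural invariant of the data model and reports violations
#' instead of throwing, so a whole file's problems can be listed at once:
#' unique individual and encounter ids, valid mark grades, non-missing tip
#' damage flags, every identification referencing a known individual and
#' encounter, no duplicate identifications, no empty encounters, non-negative
#' distances, and group size estimates at least as large as the number of
#' individuals identified.
#'
#' @param db a [sighting_database()].
#' @return data.frame with columns `entity`, `rule`, `message`; zero rows iff
#'   the database is valid.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "sighting_db"))
  v <- list()
  add <- function(entity, rule, message)
    v[[length(v) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                       message = message)

  dup <- unique(db$individuals$individual_id[
    duplicated(db$individuals$individual_id)])
  for (id in dup)
    add(id, "unique_individual_id",
        paste0("individual '", id, "' has multiple records"))
  bad <- db$individuals$individual_id[
    !db$individuals$mark_grade %in% MARK_GRADES]
  for (id in bad)
    add(id, "mark_grade", paste0("individual '", id,
                                 "' has an invalid mark_grade"))
  nab <- db$individuals$individual_id[is.na(db$individuals$tip_damage)]
  for (id in nab)
    add(id, "tip_damage", paste0("individual '", id,
                                 "' has missing tip_damage"))

  dup <- unique(db$encounters$encounter_id[
    duplicated(db$encounters$encounter_id)])
  for (id in dup)
    add(id, "unique_encounter_id",
        paste0("encounter '", id, "' has multiple records"))
  neg <- db$encounters$encounter_id[
    !is.na(db$encounters$distance_from_shore_km) &
      db$encounters$distance_from_shore_km < 0]
  for (id in neg)
    add(id, "distance_nonnegative",
        paste0("encounter '", id, "' has negative distance_from_shore_km"))

  unknown_ind <- setdiff(db$sightings$individual_id,
                         db$individuals$individual_id)
  for (id in unknown_ind)
    add(id, "known_individual",
        paste0("identification references unknown individual '", id, "'"))
  unknown_enc <- setdiff(db$sightings$encounter_id,
                         db$encounters$encounter_id)
  for (id in unknown_enc)
    add(id, "known_encounter",
        paste0("identification references unknown encounter '", id, "'"))

  key <- paste(db$sightings$encounter_id, db$sightings$individual_id,
               sep = "\r")
  dupkey <- db$sightings[duplicated(key), , drop = FALSE]
  for (i in seq_len(nrow(dupkey)))
    add(dupkey$individual_id[i], "no_duplicate_identification",
        paste0("individual '", dupkey$individual_id[i],
               "' identified more than once in encounter '",
               dupkey$encounter_id[i], "'"))

  empty <- setdiff(db$encounters$encounter_id, db$sightings$encounter_id)
  for (id in empty)
    add(id, "nonempty_encounter",
        paste0("encounter '", id, "' has no identifications"))

  n_ident <- table(db$sightings$encounter_id)
  gse <- db$encounters$group_size_estimate
  has_gse <- !is.na(gse)
  for (i in which(has_gse)) {
    eid <- db$encounters$encounter_id[i]
    n <- as.integer(n_ident[eid])
    if (!is.na(n) && gse[i] < n)
      add(eid, "group_size_estimate",
          paste0("encounter '", eid, "' group_size_estimate (", gse[i],
                 ") below number identified (", n, ")"))
  }

  if (!length(v))
    return(data.frame(entity = character(), rule = character(),
                      message = character()))
  do.call(rbind, v)
}

#' Drop identifications below a photo-quality threshold
#'
#' Photo quality is an opaque per-identification integer, 1 being the best
#' grade. This filter keeps identifications whose quality is at or better
#' than (numerically at most) `worst_quality`; identifications with no
#' recorded quality are kept. Encounters left with no identifications, and
#' individuals left with no sightings, are removed from the database.
#'
#' @param db a [sighting_database()].
#' @param worst_quality integer; identifications with
#'   `photo_quality > worst_quality` are dropped.
#' @return A filtered [sighting_database()].
#' @export
filter_quality <- function(db, worst_quality) {
  stopifnot(inherits(db, "sighting_db"), is.numeric(worst_quality))
  keep <- is.na(db$sightings$photo_quality) |
    db$sightings$photo_quality <= worst_quality
  s <- db$sightings[keep, , drop = FALSE]
  e <- db$encounters[db$encounters$encounter_id %in% s$encounter_id, ,
                     drop = FALSE]
  i <- db$individuals[db$individuals$individual_id %in% s$individual_id, ,
                      drop = FALSE]
  sighting_database(i, e, s)
}

#' Summarize a photo-ID catalogue
#'
#' Computes the descriptive statistics conventionally reported for photo-ID
#' studies: individual counts by mark severity (with integer-rounded
#' percentages, the raw fractions retained alongside), encounter and
#' identification totals, the sighting-frequency histogram, counts of
#' once-sighted / resighted (two or more encounters) / multi-year (encounters
#' in two or more calendar years) individuals, per-area individual counts with
#' cross-area overlap (individuals identified in two or more distinct area
#' labels, as a percentage of each area's catalogue), and the mean, SD and
#' range of the number of individuals identified per encounter.
#'
#' @param db a valid [sighting_database()].
#' @return An object of class `catalog_summary` (a list; serialize with
#'   [summary_json()]).
#' @export
summarize_catalog <- function(db) {
  stopifnot(inherits(db, "sighting_db"))
  n_ind <- nrow(db$individuals)
  grade_counts <- setNames(integer(length(MARK_GRADES)), MARK_GRADES)
  tab <- table(db$individuals$mark_grade)
  grade_counts[names(tab)] <- as.integer(tab)
  grade_fraction <- if (n_ind) grade_counts / n_ind else grade_counts * NA_real_
  grade_pct <- round(100 * grade_fraction)

  sightings_per_ind <- table(factor(db$sightings$individual_id,
                                    levels = db$individuals$individual_id))
  hist_tab <- table(as.integer(sightings_per_ind))
  sighting_histogram <- setNames(as.integer(hist_tab), names(hist_tab))

  n_once <- sum(sightings_per_ind == 1)
  n_resighted <- sum(sightings_per_ind >= 2)

  enc_year <- as.integer(format(db$encounters$date, "%Y"))
  year_of <- setNames(enc_year, db$encounters$encounter_id)
  years_per_ind <- tapply(year_of[db$sightings$encounter_id],
                          db$sightings$individual_id,
                          function(y) length(unique(y)))
  n_multi_year <- sum(years_per_ind >= 2)

  area_of <- setNames(db$encounters$area, db$encounters$encounter_id)
  areas_per_ind <- tapply(area_of[db$sightings$encounter_id],
                          db$sightings$individual_id,
                          function(a) unique(a))
  area_labels <- sort(unique(db$encounters$area))
  per_area <- setNames(integer(length(area_labels)), area_labels)
  overlap_per_area <- per_area
  for (a in area_labels) {
    in_a <- vapply(areas_per_ind, function(x) a %in% x, logical(1))
    per_area[a] <- sum(in_a)
    overlap_per_area[a] <- sum(in_a & lengths(areas_per_ind) >= 2)
  }
  overlap_fraction <- ifelse(per_area > 0, overlap_per_area / per_area,
                             NA_real_)
  n_cross_area <- sum(lengths(areas_per_ind) >= 2)

  group_sizes <- as.integer(table(factor(db$sightings$encounter_id,
                                         levels = db$encounters$encounter_id)))
  structure(list(
    n_individuals = n_ind,
    grade_counts = grade_counts,
    grade_fraction = grade_fraction,
    grade_pct = grade_pct,
    n_encounters = nrow(db$encounters),
    identifications_total = nrow(db$sightings),
    sighting_histogram = sighting_histogram,
    n_sighted_once = n_once,
    n_resighted = n_resighted,
    n_multi_year = n_multi_year,
    per_area_counts = per_area,
    cross_area_overlap = n_cross_area,
    area_overlap_counts = overlap_per_area,
    area_overlap_fraction = overlap_fraction,
    area_overlap_pct = round(100 * overlap_fraction),
    group_size_mean = if (length(group_sizes)) mean(group_sizes) else NA_real_,
    group_size_sd = if (length(group_sizes) > 1) sd(group_sizes) else NA_real_,
    group_size_range = if (length(group_sizes)) range(group_sizes)
                       else c(NA_integer_, NA_integer_)
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("<catalog_summary>\n")
  cat("  individuals:", x$n_individuals, sprintf(
    "(%s)", paste(sprintf("%s %d [%d%%]", names(x$grade_counts),
                          x$grade_counts, x$grade_pct), collapse = ", ")), "\n")
  cat("  encounters:", x$n_encounters,
      " identifications:", x$identifications_total, "\n")
  cat("  sighted once:", x$n_sighted_once, " resighted:", x$n_resighted,
      " multi-year:", x$n_multi_year, "\n")
  if (!is.na(x$group_size_mean))
    cat(sprintf("  group size: mean %.1f, SD %.1f, range %d-%d\n",
                x$group_size_mean, x$group_size_sd %||% NA,
                x$group_size_range[1], x$group_size_range[2]))
  invisible(x)
}

#' Serialize a catalogue summary (or other result list) to JSON
#'
#' @param x a `catalog_summary` or any list of scalar/vector fields.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
summary_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
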