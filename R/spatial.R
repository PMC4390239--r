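#' Mean Earth radius (IUGG), km
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

check_lonlat <- function(lon, lat) {
  if (any(is.na(lon)) || any(is.na(lat)) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stop_domain("coordinates out of range: lon in [-180, 180], ",
                "lat in [-90, 90]")
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius).
#'
#' @param a,b numeric length-2 vectors `c(lon, lat)` in decimal degrees
#'   (WGS84).
#' @return distance in km.
#' @export
haversine_km <- function(a, b) {
  check_lonlat(c(a[1], b[1]), c(a[2], b[2]))
  rad <- pi / 180
  dlat <- (b[2] - a[2]) * rad
  dlon <- (b[1] - a[1]) * rad
  h <- sin(dlat / 2)^2 +
    cos(a[2] * rad) * cos(b[2] * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Read a coastline polyline
#'
#' Accepts either GeoJSON (a `LineString` or `MultiLineString` geometry,
#' possibly wrapped in a Feature or FeatureCollection) or a two-column CSV of
#' `lon, lat` vertices forming a single part.
#'
#' @param path input file; format inferred from the `.json`/`.geojson`
#'   extension, otherwise CSV is assumed.
#' @return An object of class `coastline`: a list of two-column matrices
#'   (`lon`, `lat`), one per part.
#' @export
read_coastline <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    geom <- extract_geometry(obj)
    parts <- if (geom$type == "LineString") list(geom$coordinates)
             else geom$coordinates
    parts <- lapply(parts, function(p) {
      p <- as.matrix(p)
      colnames(p) <- c("lon", "lat")
      p
    })
  } else {
    m <- as.matrix(read.csv(path))
    if (ncol(m) < 2) stop_domain("coastline CSV needs lon and lat columns")
    parts <- list(matrix(as.numeric(m[, 1:2]), ncol = 2,
                         dimnames = list(NULL, c("lon", "lat"))))
  }
  coastline(parts)
}

extract_geometry <- function(obj) {
  if (!is.null(obj$type) && obj$type %in% c("LineString", "MultiLineString"))
    return(obj)
  if (!is.null(obj$geometry)) return(extract_geometry(obj$geometry))
  if (!is.null(obj$features)) {
    g <- obj$features$geometry
    if (!is.null(g$type))
      return(list(type = g$type[1],
                  coordinates = if (is.list(g$coordinates))
                    g$coordinates[[1]] else g$coordinates))
  }
  stop_domain("no LineString/MultiLineString geometry found")
}

#' Construct a coastline from vertex coordinates
#'
#' @param parts a two-column matrix of `(lon, lat)` vertices, or a list of
#'   such matrices (one per polyline part).
#' @return An object of class `coastline`.
#' @export
coastline <- function(parts) {
  if (is.matrix(parts) || is.data.frame(parts)) parts <- list(parts)
  if (!length(parts)) stop_domain("coastline must have at least one part")
  parts <- lapply(parts, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 2)
      stop_domain("each coastline part needs >= 2 (lon, lat) vertices")
    check_lonlat(p[, 1], p[, 2])
    colnames(p) <- c("lon", "lat")
    p
  })
  structure(parts, class = "coastline")
}

#' Distance from a point to the nearest coastline segment
#'
#' Minimum distance from `pt` to any segment of the polyline, computed in a
#' local equirectangular projection centred on the point (longitudes scaled
#' by `cos(lat)`), which is accurate for the coastal scales this supports and
#' exact at vertices.
#'
#' @param pt numeric `c(lon, lat)` in decimal degrees.
#' @param coast a [coastline()].
#' @return distance in km.
#' @export
distance_to_coast <- function(pt, coast) {
  if (!inherits(coast, "coastline")) coast <- coastline(coast)
  check_lonlat(pt[1], pt[2])
  deg_km <- pi * EARTH_RADIUS_KM / 180
  coslat <- cos(pt[2] * pi / 180)
  rad <- pi / 180
  best <- Inf
  for (part in coast) {
    x <- (part[, 1] - pt[1]) * coslat * deg_km
    y <- (part[, 2] - pt[2]) * deg_km
    n <- nrow(part)
    ax <- x[-n]; ay <- y[-n]
    bx <- x[-1]; by <- y[-1]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, -(ax * dx + ay * dy) / len2)))
    px <- ax + t * dx
    py <- ay + t * dy
    best <- min(best, sqrt(px^2 + py^2))
    # great-circle distance to the vertices themselves, so the result is
    # exact at vertices and never exceeds the distance to any vertex
    h <- sin((part[, 2] - pt[2]) * rad / 2)^2 +
      cos(pt[2] * rad) * cos(part[, 2] * rad) *
        sin((part[, 1] - pt[1]) * rad / 2)^2
    best <- min(best, 2 * EARTH_RADIUS_KM * asin(sqrt(pmin(1, h))))
  }
  best
}

#' Mann-Whitney U rank test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The statistic is the
#' number of pairs `(x_i, y_j)` with `x_i > y_j`, counting ties as 1/2. For
#' tie-free samples with `n1 * n2 <= 400` the p-value is exact, from the
#' full permutation distribution of U computed by dynamic programming (the
#' two-sided p is the probability, under random relabelling, of a U at least
#' as far from its mean `n1 n2 / 2` as observed). Larger or tied samples use
#' the normal approximation with tie correction and a continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param method `"auto"` (exact when feasible), `"exact"` (error if tied)
#'   or `"normal"`.
#' @return An object of class `rank_test_result`: list with `U` (for `x`),
#'   `n1`, `n2`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_domain("samples must be non-empty")
  if (anyNA(c(x, y))) stop_domain("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  use_exact <- switch(method,
    exact = TRUE,
    normal = FALSE,
    auto = !ties && n1 * n2 <= 400)
  if (method == "exact" && ties)
    stop_domain("exact method is not defined for tied samples")

  if (use_exact) {
    freq <- u_distribution(n1, n2)            # counts for U = 0..n1*n2
    dev <- abs(seq(0, n1 * n2) - n1 * n2 / 2)
    p <- sum(freq[dev >= abs(u - n1 * n2 / 2) - 1e-9]) / sum(freq)
    meth <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    t_tab <- table(c(x, y))
    tie_term <- sum(t_tab^3 - t_tab) / (nn * (nn - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma   # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    meth <- "normal-approximation"
  }
  structure(list(U = u, n1 = n1, n2 = n2, p = p, method = meth),
            class = "rank_test_result")
}

# Number of rank subsets of size n1 from n1+n2 with each rank-sum statistic
# value; classic recurrence over (sample size, statistic).
u_distribution <- function(n1, n2) {
  max_u <- n1 * n2
  # f[k+1, u+1] = number of ways to pick k of the n1+n2 ranks giving U = u
  f <- matrix(0, n1 + 1, max_u + 1)
  f[1, 1] <- 1
  for (i in seq_len(n1 + n2)) {
    for (k in rev(seq_len(min(i, n1)))) {
      # adding element i as an x contributes (i - k_prev_total) inversions;
      # standard formulation: U increments by number of y's before it
      new <- f[k, ]
      shift <- i - k  # y's already placed
      if (shift > 0)
        new <- c(rep(0, shift), new)[seq_len(max_u + 1)]
      f[k + 1, ] <- f[k + 1, ] + new
    }
  }
  f[n1 + 1, ]
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, n1 = %d, n2 = %d, p = %.4g (%s)\n",
              x$U, x$n1, x$n2, x$p, x$method))
  invisible(x)
}

#' Fill missing encounter distances from a coastline
#'
#' Computes [distance_to_coast()] for encounters that have coordinates but no
#' recorded `distance_from_shore_km`. Distances supplied in the input data
#' always take precedence; nothing is overwritten.
#'
#' @param db a [sighting_database()].
#' @param coast a [coastline()].
#' @return The database with distances filled in where computable.
#' @export
fill_distances <- function(db, coast) {
  stopifnot(inherits(db, "sighting_db"))
  e <- db$encounters
  todo <- which(is.na(e$distance_from_shore_km) &
                  !is.na(e$latitude) & !is.na(e$longitude))
  for (i in todo)
    e$distance_from_shore_km[i] <-
      distance_to_coast(c(e$longitude[i], e$latitude[i]), coast)
  db$encounters <- e
  db
}

#' Compare encounter distances from shore between community groupings
#'
#' The encounter (group sighting) is the sampling unit. Each encounter is
#' attributed to a grouping side by the majority community membership of its
#' identified individuals (`UNASSIGNED` individuals are ignored; exact ties
#' and encounters with no assigned members are excluded with a warning).
#' Encounters without a distance are excluded and counted. Returns
#' per-side distance summaries (n, mean, SD, quartiles, range) and a
#' two-sided Mann-Whitney test of the first side against the second.
#'
#' @param db a [sighting_database()] with `distance_from_shore_km` populated
#'   (see [fill_distances()]).
#' @param partition an extended `community_partition`.
#' @param grouping named list of two character vectors of labels; default:
#'   largest community versus all other communities.
#' @return list with `summary` (data.frame, one row per side), `test` (a
#'   `rank_test_result`), `n_excluded_missing_distance`,
#'   `n_excluded_unattributed`.
#' @export
compare_group_distances <- function(db, partition, grouping = NULL) {
  att <- attribute_encounters(db, partition, grouping)
  grouping <- att$grouping
  e <- db$encounters
  dist_of <- setNames(e$distance_from_shore_km, e$encounter_id)

  side_values <- lapply(names(grouping), function(g) {
    encs <- att$encounters$encounter_id[att$encounters$side == g]
    d <- dist_of[encs]
    d[!is.na(d)]
  })
  names(side_values) <- names(grouping)
  n_missing <- sum(vapply(names(grouping), function(g)
    sum(is.na(dist_of[att$encounters$encounter_id[
      att$encounters$side == g]])), integer(1)))
  if (any(lengths(side_values) == 0))
    stop_domain("a grouping side has no encounters with distances")

  summ <- do.call(rbind, lapply(names(side_values), function(g) {
    d <- side_values[[g]]
    q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n_encounters = length(d), mean = mean(d),
               sd = if (length(d) > 1) sd(d) else NA_real_,
               min = min(d), q1 = q[1], median = q[2], q3 = q[3],
               max = max(d))
  }))
  list(summary = summ,
       test = mann_whitney_u(side_values[[1]], side_values[[2]]),
       n_excluded_missing_distance = n_missing,
       n_excluded_unattributed = att$n_excluded)
}

# Attribute each encounter to a grouping side by majority membership.
attribute_encounters <- function(db, partition, grouping = NULL) {
  stopifnot(inherits(db, "sighting_db"),
            inherits(partition, "community_partition"))
  labels <- attr(partition, "labels")
  if (is.null(grouping)) {
    if (length(labels) < 2)
      stop_domain("default grouping needs at least 2 communities")
    grouping <- list(labels[1], labels[-1])
    names(grouping) <- c(labels[1],
                         if (length(labels) > 2)
                           paste0(labels[2], "-", labels[length(labels)])
                         else labels[2])
  }
  if (length(grouping) != 2)
    stop_domain("grouping must define exactly 2 sides")
  label_of <- setNames(partition$label, partition$individual_id)
  side_of_label <- function(lab)
    names(grouping)[vapply(grouping, function(g) lab %in% g, logical(1))]

  enc_ids <- db$encounters$encounter_id
  members <- split(db$sightings$individual_id, db$sightings$encounter_id)
  sides <- character(length(enc_ids))
  for (i in seq_along(enc_ids)) {
    labs <- label_of[members[[enc_ids[i]]]]
    labs <- labs[!is.na(labs) & labs != "UNASSIGNED"]
    votes <- c(0, 0)
    names(votes) <- names(grouping)
    for (lab in labs) {
      s <- side_of_label(lab)
      if (length(s) == 1) votes[s] <- votes[s] + 1
    }
    sides[i] <- if (sum(votes) == 0 || votes[1] == votes[2]) NA_character_
                else names(votes)[which.max(votes)]
  }
  n_excluded <- sum(is.na(sides))
  if (n_excluded)
    warning(n_excluded, " encounter(s) excluded: no majority grouping side",
            call. = FALSE)
  list(encounters = data.frame(encounter_id = enc_ids, side = sides),
       grouping = grouping, n_excluded = n_excluded)
}

#' Compare identified group sizes between two areas
#'
#' Mann-Whitney comparison of the number of individuals identified per
#' encounter between two area labels.
#'
#' @param db a [sighting_database()].
#' @param areas character vector of two area labels; default: the two most
#'   frequent areas.
#' @return list with `summary` (per-area n, mean, sd) and `test`.
#' @export
compare_area_group_sizes <- function(db, areas = NULL) {
  stopifnot(inherits(db, "sighting_db"))
  sizes <- table(factor(db$sightings$encounter_id,
                        levels = db$encounters$encounter_id))
  if (is.null(areas)) {
    tab <- sort(table(db$encounters$area), decreasing = TRUE)
    if (length(tab) < 2) stop_domain("need two areas to compare")
    areas <- names(tab)[1:2]
  }
  vals <- lapply(areas, function(a)
    as.integer(sizes[db$encounters$area == a]))
  if (any(lengths(vals) == 0)) stop_domain("an area has no encounters")
  summ <- do.call(rbind, lapply(seq_along(areas), function(i)
    data.frame(area = areas[i], n_encounters = length(vals[[i]]),
               mean = mean(vals[[i]]),
               sd = if (length(vals[[i]]) > 1) sd(vals[[i]]) else NA_real_)))
  list(summary = summ, test = mann_whitney_u(vals[[1]], vals[[2]]))
}
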