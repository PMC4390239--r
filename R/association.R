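#' Gambit-of-the-group dyad counts
#'
#' Counts, for every unordered pair of the chosen individuals, the number of
#' encounters in which both were identified (`x`), only the first (`y_a`) and
#' only the second (`y_b`). Individuals identified in the same group are
#' taken to be associated (the gambit of the group); the sampling unit is the
#' encounter, so each encounter contributes at most one count to any of the
#' three tallies of a dyad.
#'
#' @param db a [sighting_database()].
#' @param ids character vector of individual ids to analyse (at least 2, all
#'   present in the catalogue).
#' @return data.frame with one row per unordered pair: `id_a`, `id_b`, `x`,
#'   `y_a`, `y_b`. Pair order follows the order of `ids`.
#' @export
pairwise_counts <- function(db, ids) {
  stopifnot(inherits(db, "sighting_db"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, db$individuals$individual_id)
  if (length(unknown))
    stop_domain("unknown individual id(s): ", paste(unknown, collapse = ", "))
  if (length(ids) < 2)
    stop_domain("need at least 2 individuals for dyad counting")

  inc <- incidence_matrix(db, ids)
  x_mat <- tcrossprod(inc)            # joint encounter counts
  n_sight <- rowSums(inc)             # per-individual encounter counts

  pair_idx <- combn(length(ids), 2)
  a <- pair_idx[1, ]
  b <- pair_idx[2, ]
  x <- x_mat[cbind(a, b)]
  data.frame(id_a = ids[a], id_b = ids[b], x = as.integer(x),
             y_a = as.integer(n_sight[a] - x),
             y_b = as.integer(n_sight[b] - x))
}

# 0/1 individuals x encounters matrix over all encounters in db
incidence_matrix <- function(db, ids) {
  enc <- db$encounters$encounter_id
  inc <- matrix(0L, length(ids), length(enc), dimnames = list(ids, enc))
  s <- db$sightings[db$sightings$individual_id %in% ids, , drop = FALSE]
  inc[cbind(match(s$individual_id, ids), match(s$encounter_id, enc))] <- 1L
  inc
}

#' Half-weight association index
#'
#' `HWI = X / (X + 0.5 * (Ya + Yb))` where `X` is the number of groups in
#' which both individuals of a dyad were identified together and `Ya`, `Yb`
#' the numbers of groups in which only one of them was identified. The index
#' ranges from 0 (never associated) to 1 (always associated) and is widely
#' used in cetacean studies because it reduces the bias from incomplete
#' identification of group members. Vectorized over dyads.
#'
#' @param x,y_a,y_b non-negative dyad counts (recycled to common length).
#' @return numeric vector of HWI values in `[0, 1]`; the degenerate all-zero
#'   dyad returns 0 (see [association_matrix()] for the undefined-dyad flag).
#' @export
half_weight_index <- function(x, y_a, y_b) {
  if (any(c(x, y_a, y_b) < 0, na.rm = TRUE))
    stop_domain("dyad counts must be non-negative")
  denom <- x + 0.5 * (y_a + y_b)
  ifelse(denom == 0, 0, x / denom)
}

#' Half-weight association matrix
#'
#' Builds the symmetric HWI matrix over a subset of the catalogue, by default
#' the permanently marked individuals only (their marks are stable enough to
#' match between years and areas). All individuals of the chosen grades are
#' included regardless of sighting frequency. All encounters in the database
#' are the sampling units.
#'
#' @param db a [sighting_database()].
#' @param grade_filter character vector of mark grades to include, or `NULL`
#'   for all individuals. Default `"PERMANENT"`.
#' @param ids optional explicit id subset (overrides `grade_filter`).
#' @return An object of class `assoc_matrix`: list with `ids`, `n_sightings`
#'   (per-individual encounter counts), `x` (joint-count matrix), `hwi`
#'   (symmetric HWI matrix, diagonal `NA`), and `undefined` (logical matrix
#'   flagging dyads whose three counts are all zero, for which the HWI is
#'   undefined and reported as 0).
#' @export
association_matrix <- function(db, grade_filter = "PERMANENT", ids = NULL) {
  stopifnot(inherits(db, "sighting_db"))
  if (is.null(ids)) {
    ids <- db$individuals$individual_id
    if (!is.null(grade_filter))
      ids <- ids[db$individuals$mark_grade %in% grade_filter]
  } else {
    ids <- as.character(ids)
    unknown <- setdiff(ids, db$individuals$individual_id)
    if (length(unknown))
      stop_domain("unknown individual id(s): ",
                  paste(unknown, collapse = ", "))
  }
  if (length(ids) < 2)
    stop_domain("fewer than 2 individuals remain after filtering; ",
                "cannot build an association matrix")

  inc <- incidence_matrix(db, ids)
  x_mat <- tcrossprod(inc)
  n_sight <- rowSums(inc)
  denom <- outer(n_sight, n_sight, "+") / 2   # X + 0.5 (Ya + Yb)
  hwi <- ifelse(denom == 0, 0, x_mat / denom)
  undefined <- denom == 0
  diag(hwi) <- NA_real_
  diag(undefined) <- FALSE
  dimnames(hwi) <- dimnames(undefined) <- list(ids, ids)

  structure(list(ids = ids, n_sightings = setNames(as.integer(n_sight), ids),
                 x = x_mat, hwi = hwi, undefined = undefined),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  off <- x$hwi[upper.tri(x$hwi)]
  cat("<assoc_matrix>", length(x$ids), "individuals,",
      sum(off > 0), "associated dyads, mean HWI",
      sprintf("%.3f", mean(off)), "\n")
  invisible(x)
}

#' Long-format dyad table of an association matrix
#'
#' @param x an `assoc_matrix`.
#' @param ... unused.
#' @return data.frame with `id_a`, `id_b`, `x`, `y_a`, `y_b`, `hwi` per
#'   unordered pair.
#' @export
as.data.frame.assoc_matrix <- function(x, ...) {
  idx <- combn(length(x$ids), 2)
  a <- idx[1, ]
  b <- idx[2, ]
  xx <- x$x[cbind(a, b)]
  data.frame(id_a = x$ids[a], id_b = x$ids[b], x = as.integer(xx),
             y_a = as.integer(x$n_sightings[a] - xx),
             y_b = as.integer(x$n_sightings[b] - xx),
             hwi = x$hwi[cbind(a, b)])
}

#' Export an association matrix to CSV
#'
#' Writes the long-format dyad table (`id_a, id_b, x, y_a, y_b, hwi`) and/or
#' the square HWI matrix. HWI values are written at full precision; rounding
#' is a presentation concern left to reports.
#'
#' @param m an `assoc_matrix`.
#' @param long_path,square_path output paths (`NULL` to skip either form).
#' @return invisibly, the paths written.
#' @export
write_association <- function(m, long_path = NULL, square_path = NULL) {
  stopifnot(inherits(m, "assoc_matrix"))
  written <- character()
  if (!is.null(long_path)) {
    write.csv(as.data.frame(m), long_path, row.names = FALSE, quote = FALSE)
    written <- c(written, long_path)
  }
  if (!is.null(square_path)) {
    sq <- as.data.frame(m$hwi)
    sq <- cbind(individual_id = m$ids, sq)
    write.csv(sq, square_path, row.names = FALSE, quote = FALSE)
    written <- c(written, square_path)
  }
  invisible(written)
}
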