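#' Pearson chi-square test of independence
#'
#' Classic Pearson chi-square on an r x c contingency table of counts, with
#' no continuity correction by default: expected cells are
#' `row_total * column_total / N`, the statistic is
#' `sum((observed - expected)^2 / expected)` and the p-value is the upper
#' tail of the chi-square distribution on `(r-1)(c-1)` degrees of freedom.
#' The Yates continuity correction (subtract 0.5 from each absolute residual
#' of a 2 x 2 table) is available but off by default.
#'
#' @param observed matrix of non-negative integer counts, at least 2 x 2,
#'   with every row and column total positive.
#' @param correct logical; apply the Yates continuity correction (2 x 2
#'   tables only).
#' @return An object of class `contingency_result`: list with `observed`,
#'   `expected`, `chi2`, `df`, `p`.
#' @export
pearson_chi_square <- function(observed, correct = FALSE) {
  observed <- as.matrix(observed)
  if (any(is.na(observed)) || any(observed < 0))
    stop_domain("observed counts must be non-negative and non-missing")
  if (any(abs(observed - round(observed)) > 1e-8))
    stop_domain("observed counts must be integers")
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop_domain("table must be at least 2 x 2")
  rt <- rowSums(observed)
  ct <- colSums(observed)
  if (any(rt == 0) || any(ct == 0))
    stop_domain("degenerate table: zero row or column total")
  n <- sum(observed)
  expected <- outer(rt, ct) / n
  resid <- abs(observed - expected)
  if (correct) {
    if (!all(dim(observed) == c(2, 2)))
      stop_domain("continuity correction applies to 2 x 2 tables only")
    resid <- pmax(resid - 0.5, 0)
  }
  chi2 <- sum(resid^2 / expected)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  structure(list(observed = observed, expected = expected, chi2 = chi2,
                 df = df, p = chi_square_upper_tail(chi2, df)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: chi2 = %.4g, df = %d, N = %d, p = %.4g\n",
              x$chi2, x$df, sum(x$observed), x$p))
  invisible(x)
}

#' Upper tail of the chi-square distribution
#'
#' Survival function `P(X >= x)` for a chi-square variate on `df` degrees of
#' freedom, i.e. the regularized upper incomplete gamma function
#' `Q(df/2, x/2)`.
#'
#' @param x non-negative statistic value(s).
#' @param df positive integer degrees of freedom.
#' @return p-value(s) in `[0, 1]`.
#' @export
chi_square_upper_tail <- function(x, df) {
  if (any(x < 0)) stop_domain("statistic must be non-negative")
  if (any(df < 1) || any(df != round(df)))
    stop_domain("df must be a positive integer")
  pchisq(x, df, lower.tail = FALSE)
}

#' Pairwise chi-square comparisons between communities
#'
#' For every unordered pair of communities, tests whether a binary individual
#' feature — by default the proportion of permanently marked individuals,
#' alternatively the proportion with dorsal-fin tip damage — differs between
#' the two communities, using an uncorrected 2 x 2 Pearson chi-square.
#' Significance is judged against a Bonferroni-corrected level
#' `alpha / n_comparisons`, where `n_comparisons` defaults to the number of
#' pairs actually tested but can be overridden to mirror published analyses
#' that used a different denominator. A pair whose 2 x 2 table has a zero
#' margin is reported as untestable rather than dropped.
#'
#' @param db a [sighting_database()].
#' @param partition a `community_partition` (usually extended by
#'   [assign_unmarked()]); `UNASSIGNED` individuals are excluded.
#' @param feature `"permanent_mark"` (permanent vs other grades) or
#'   `"tip_damage"` (damaged vs undamaged).
#' @param alpha base significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @param n_comparisons optional override for the Bonferroni denominator.
#' @return An object of class `pairwise_test_table`: data.frame with one row
#'   per pair (`label_1`, `label_2`, `n`, `chi2`, `df`, `p`, `testable`,
#'   `significant`) plus attributes `alpha`, `corrected_alpha`,
#'   `n_comparisons`, `correction`, `feature`, `counts` (the per-community
#'   feature counts used).
#' @export
pairwise_network_tests <- function(db, partition,
                                   feature = c("permanent_mark",
                                               "tip_damage"),
                                   alpha = 0.05,
                                   correction = c("bonferroni", "none"),
                                   n_comparisons = NULL) {
  feature <- match.arg(feature)
  correction <- match.arg(correction)
  stopifnot(inherits(db, "sighting_db"),
            inherits(partition, "community_partition"))
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must be in (0, 1)")

  counts <- community_feature_counts(db, partition, feature)
  labels <- rownames(counts)
  if (length(labels) < 2)
    stop_domain("need at least 2 communities with members to compare")

  pairs <- combn(labels, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    l1 <- pairs[1, i]; l2 <- pairs[2, i]
    tab <- counts[c(l1, l2), , drop = FALSE]
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(data.frame(label_1 = l1, label_2 = l2, n = sum(tab),
                        chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                        testable = FALSE))
    r <- pearson_chi_square(tab)
    data.frame(label_1 = l1, label_2 = l2, n = sum(tab), chi2 = r$chi2,
               df = r$df, p = r$p, testable = TRUE)
  })
  out <- do.call(rbind, rows)

  n_tested <- sum(out$testable)
  n_comp <- n_comparisons %||% n_tested
  corrected_alpha <- if (correction == "bonferroni") alpha / n_comp else alpha
  out$significant <- out$testable & !is.na(out$p) & out$p < corrected_alpha

  structure(out, alpha = alpha, corrected_alpha = corrected_alpha,
            n_comparisons = n_comp, correction = correction,
            feature = feature, counts = counts,
            class = c("pairwise_test_table", "data.frame"))
}

# Per-community (feature-positive, feature-negative) counts; UNASSIGNED
# individuals are excluded, community order follows the partition labels.
community_feature_counts <- function(db, partition, feature) {
  assigned <- partition[partition$label != "UNASSIGNED", , drop = FALSE]
  idx <- match(assigned$individual_id, db$individuals$individual_id)
  if (anyNA(idx))
    stop_domain("partition references individuals absent from the database")
  positive <- if (feature == "permanent_mark")
    db$individuals$mark_grade[idx] == "PERMANENT"
  else
    db$individuals$tip_damage[idx]
  labels <- intersect(attr(partition, "labels") %||% sort(unique(assigned$label)),
                      unique(assigned$label))
  pos <- tapply(positive, factor(assigned$label, levels = labels), sum)
  tot <- tapply(positive, factor(assigned$label, levels = labels), length)
  counts <- cbind(positive = as.integer(pos),
                  negative = as.integer(tot - pos))
  rownames(counts) <- labels
  col_names <- if (feature == "permanent_mark")
    c("permanent", "other") else c("tip_damage", "no_tip_damage")
  colnames(counts) <- col_names
  counts
}

#' @export
print.pairwise_test_table <- function(x, ...) {
  cat(sprintf(
    "<pairwise_test_table> feature %s, %d pairs, corrected alpha %.4g (%s)\n",
    attr(x, "feature"), nrow(x), attr(x, "corrected_alpha"),
    attr(x, "correction")))
  print(as.data.frame(x))
  invisible(x)
}

#' Lower-triangular matrix layout of a pairwise test table
#'
#' Arranges the pairwise chi-square results as a lower-triangular character
#' matrix (rows and columns are community labels, each filled cell reading
#' `chi2 (p)`), the layout conventionally used to publish such comparisons.
#'
#' @param x a `pairwise_test_table`.
#' @return character matrix.
#' @export
pairwise_triangle <- function(x) {
  stopifnot(inherits(x, "pairwise_test_table"))
  labels <- unique(c(x$label_1, x$label_2))
  m <- matrix("", length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_len(nrow(x))) {
    r <- max(match(c(x$label_1[i], x$label_2[i]), labels))
    c_ <- min(match(c(x$label_1[i], x$label_2[i]), labels))
    m[r, c_] <- if (!x$testable[i]) "untestable" else
      sprintf("chi2 = %.3g (p = %.3f)%s", x$chi2[i], x$p[i],
              if (x$significant[i]) " *" else "")
  }
  m
}

#' Write a pairwise test table to CSV (lower-triangular layout) and JSON
#'
#' @param x a `pairwise_test_table`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_pairwise_tests <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "pairwise_test_table"))
  written <- character()
  if (!is.null(csv_path)) {
    tri <- pairwise_triangle(x)
    out <- cbind(network = rownames(tri), as.data.frame(tri))
    write.csv(out, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    payload <- list(feature = attr(x, "feature"), alpha = attr(x, "alpha"),
                    correction = attr(x, "correction"),
                    n_comparisons = attr(x, "n_comparisons"),
                    corrected_alpha = attr(x, "corrected_alpha"),
                    counts = as.data.frame(attr(x, "counts")),
                    pairs = as.data.frame(x))
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                na = "null", pretty = TRUE), json_path)
    written <- c(written, json_path)
  }
  invisible(written)
}

#' Mark-severity composition table by community grouping
#'
#' Summarizes catalogue composition for groups of communities (for instance
#' the largest community versus all others pooled): individual counts per
#' mark grade, and the percentage of individuals with dorsal tip damage,
#' sighted exactly once, and resighted. Percentages are over all individuals
#' of the group, all grades, rounded to the nearest integer (raw fractions
#' retained). An empty group reports zero counts and undefined (`NA`)
#' percentages. `UNASSIGNED` individuals appear only in groupings that
#' explicitly include the `"UNASSIGNED"` label.
#'
#' @param db a [sighting_database()].
#' @param partition an extended `community_partition`.
#' @param grouping named list of character vectors of labels; default: the
#'   first (largest) community versus all remaining community labels pooled.
#' @return data.frame with one row per group, class `mark_severity_table`.
#' @export
mark_severity_table <- function(db, partition, grouping = NULL) {
  stopifnot(inherits(db, "sighting_db"),
            inherits(partition, "community_partition"))
  labels <- attr(partition, "labels")
  if (is.null(grouping)) {
    if (length(labels) < 1) stop_domain("partition has no community labels")
    grouping <- list(labels[1],
                     if (length(labels) > 1) labels[-1] else character())
    names(grouping) <- c(labels[1],
                         if (length(labels) > 2)
                           paste0(labels[2], "-", labels[length(labels)])
                         else if (length(labels) == 2) labels[2]
                         else "other")
  }
  sightings_per_ind <- table(factor(db$sightings$individual_id,
                                    levels = db$individuals$individual_id))
  rows <- lapply(names(grouping), function(gname) {
    ids <- partition$individual_id[partition$label %in% grouping[[gname]]]
    idx <- match(ids, db$individuals$individual_id)
    n <- length(ids)
    grades <- db$individuals$mark_grade[idx]
    gc <- vapply(MARK_GRADES, function(g) sum(grades == g), integer(1))
    tip <- sum(db$individuals$tip_damage[idx])
    once <- sum(sightings_per_ind[ids] == 1)
    multi <- sum(sightings_per_ind[ids] >= 2)
    frac <- function(k) if (n > 0) k / n else NA_real_
    data.frame(group = gname, n = n,
               n_permanent = gc[["PERMANENT"]],
               n_temporary = gc[["TEMPORARY"]],
               n_superficial = gc[["SUPERFICIAL"]],
               pct_permanent = round(100 * frac(gc[["PERMANENT"]])),
               pct_tip_damage = round(100 * frac(tip)),
               pct_sighted_once = round(100 * frac(once)),
               pct_sighted_multi = round(100 * frac(multi)),
               frac_permanent = frac(gc[["PERMANENT"]]),
               frac_tip_damage = frac(tip),
               frac_sighted_once = frac(once),
               frac_sighted_multi = frac(multi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mark_severity_table", "data.frame"))
}
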