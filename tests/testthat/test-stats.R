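# Network composition counts (permanent vs non-permanent individuals) used
# throughout: A(72,120), B(33,9), C(8,3), D(30,1), E(9,1).
network_counts <- rbind(A = c(72, 120), B = c(33, 9), C = c(8, 3),
                        D = c(30, 1), E = c(9, 1))

test_that("Pearson chi-square matches published network comparisons", {
  r <- pearson_chi_square(network_counts[c("A", "B"), ])
  expect_equal(round(r$chi2, 1), 23.5)
  expect_equal(r$df, 1)

  r5 <- pearson_chi_square(network_counts)
  expect_equal(round(r5$chi2, 1), 60.6)
  expect_equal(r5$df, 4)
  expect_lt(r5$p, 0.001)
})

test_that("chi-square handles the degenerate and uniform cases", {
  r <- pearson_chi_square(matrix(10, 2, 2))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_error(pearson_chi_square(rbind(c(1, 0), c(2, 0))), "degenerate")
  expect_error(pearson_chi_square(rbind(c(1.5, 1), c(2, 1))), "integers")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "at least 2 x 2")
  expect_error(pearson_chi_square(rbind(c(-1, 2), c(2, 1))), "non-negative")
})

test_that("expected table preserves the grand total", {
  for (seed in 1:5) {
    set.seed(seed)
    tab <- matrix(rpois(12, 20), 3, 4)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    r <- pearson_chi_square(tab)
    expect_lt(abs(sum(r$expected) - sum(r$observed)), 1e-9)
    expect_gte(r$chi2, 0)
    expect_true(r$p >= 0 && r$p <= 1)
  }
})

test_that("2x2 statistic equals the closed form and chisq.test", {
  closed_form <- function(t) {
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
    unname(sum(t) * (a * d - b * c)^2 /
             ((a + b) * (c + d) * (a + c) * (b + d)))
  }
  pairs <- combn(rownames(network_counts), 2)
  for (i in seq_len(ncol(pairs))) {
    tab <- network_counts[pairs[, i], ]
    r <- pearson_chi_square(tab)
    expect_equal(r$chi2, closed_form(tab), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("statistic is invariant under row/column permutation", {
  set.seed(42)
  tab <- matrix(rpois(15, 10) + 1, 3, 5)
  base <- pearson_chi_square(tab)$chi2
  for (k in 1:5) {
    perm <- tab[sample(3), sample(5)]
    expect_equal(pearson_chi_square(perm)$chi2, base, tolerance = 1e-12)
  }
})

test_that("continuity correction is available but off by default", {
  tab <- network_counts[c("A", "B"), ]
  plain <- pearson_chi_square(tab)$chi2
  corrected <- pearson_chi_square(tab, correct = TRUE)$chi2
  expect_gt(plain, corrected)
  expect_equal(unname(suppressWarnings(
    chisq.test(tab, correct = TRUE)$statistic)), corrected,
    tolerance = 1e-12)
})

test_that("upper tail probability matches a numerical-integration oracle", {
  for (df in c(1, 2, 3, 5, 10)) {
    for (x in c(0.5, 1, 3.841, 5.41, 10, 20)) {
      expect_lt(abs(chi_square_upper_tail(x, df) -
                      integrate_chisq_tail(x, df)), 1e-10)
    }
  }
  expect_equal(chi_square_upper_tail(0, 3), 1)
  expect_lt(abs(chi_square_upper_tail(3.841, 1) - 0.05), 0.0005)
  # the df=1 tail of 5.41 is ~0.020 (sometimes misprinted as 0.201)
  expect_lt(abs(chi_square_upper_tail(5.41, 1) - 0.020), 0.0005)
  expect_error(chi_square_upper_tail(1, 0), "df")
  expect_error(chi_square_upper_tail(-1, 1), "non-negative")
})

# A fixture whose five communities have exactly the published permanent /
# non-permanent margins: community k = one encounter-group of permanents
# plus satellites each co-occurring with one permanent of that community.
margins_db <- function(counts) {
  encs <- list()
  grades <- character()
  tip <- logical()
  for (k in seq_len(nrow(counts))) {
    nm <- rownames(counts)[k]
    perms <- sprintf("%s_p%03d", nm, seq_len(counts[k, 1]))
    grades[perms] <- "PERMANENT"
    tip[perms] <- FALSE
    encs[[sprintf("%s_core", nm)]] <- perms
    if (counts[k, 2] > 0) {
      others <- sprintf("%s_t%03d", nm, seq_len(counts[k, 2]))
      grades[others] <- "TEMPORARY"
      tip[others] <- FALSE
      for (j in seq_along(others))
        encs[[sprintf("%s_sat%03d", nm, j)]] <-
          c(perms[(j - 1) %% length(perms) + 1], others[j])
    }
  }
  toy_db(encs, grades = grades, tip = tip)
}

test_that("pairwise network tests reproduce the published comparisons", {
  db <- margins_db(network_counts)
  m <- association_matrix(db)
  part <- assign_unmarked(db, detect_communities(build_sociogram(m, db = db)))
  counts_found <- table(part$label,
    db$individuals$mark_grade[match(part$individual_id,
                                    db$individuals$individual_id)])
  expect_equal(unname(counts_found[, "PERMANENT"]), c(72, 33, 30, 9, 8))

  tt <- pairwise_network_tests(db, part, feature = "permanent_mark")
  expect_equal(nrow(tt), 10)
  expect_equal(attr(tt, "n_comparisons"), 10)
  expect_equal(attr(tt, "corrected_alpha"), 0.005)

  # label sizes order as A(192), B(42), C(31), D(10), E(11 -> C has 8+3)
  # look rows up by their permanent counts rather than by label
  chi_of <- function(n_pair) tt$chi2[tt$n == n_pair]
  expect_equal(round(chi_of(72 + 120 + 33 + 9)[1], 1), 23.5)

  # override mirrors a published 0.05/9 correction
  tt9 <- pairwise_network_tests(db, part, n_comparisons = 9)
  expect_equal(attr(tt9, "corrected_alpha"), 0.05 / 9, tolerance = 1e-12)
})

test_that("identical communities give chi2 = 0; zero margins are untestable", {
  counts <- rbind(A = c(10, 5), B = c(10, 5))
  dbe <- margins_db(counts)
  m <- association_matrix(dbe)
  part <- assign_unmarked(dbe, detect_communities(build_sociogram(m, db = dbe)))
  tt <- pairwise_network_tests(dbe, part, feature = "permanent_mark")
  expect_equal(tt$chi2[1], 0)
  expect_false(tt$significant[1])

  # tip damage nowhere -> zero column margin in every pair
  tt_tip <- pairwise_network_tests(dbe, part, feature = "tip_damage")
  expect_false(any(tt_tip$testable))
  expect_true(all(is.na(tt_tip$chi2)))
})

test_that("mark severity table reports composition per grouping", {
  grades <- c(a1 = "PERMANENT", a2 = "TEMPORARY", a3 = "SUPERFICIAL",
              a4 = "PERMANENT", b1 = "PERMANENT", b2 = "TEMPORARY")
  db <- toy_db(list(E1 = c("a1", "a2", "a3"), E2 = c("a1", "a4"),
                    E3 = c("b1", "b2")), grades = grades)
  m <- association_matrix(db)
  part <- assign_unmarked(db, detect_communities(build_sociogram(m, db = db)))
  tab <- mark_severity_table(db, part)
  expect_equal(tab$group, c("A", "B"))
  expect_equal(tab$n, c(4, 2))
  # group B members all sighted exactly once
  expect_equal(tab$pct_sighted_once[tab$group == "B"], 100)
  expect_equal(tab$pct_sighted_multi[tab$group == "B"], 0)
  # empty group reports undefined percentages
  tab2 <- mark_severity_table(db, part,
                              grouping = list(A = "A", none = "Z"))
  expect_equal(tab2$n[2], 0)
  expect_true(is.na(tab2$pct_permanent[2]))
})
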