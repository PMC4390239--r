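test_that("haversine distance matches spherical arc lengths", {
  expect_equal(haversine_km(c(5, 50), c(5, 50)), 0)
  # one degree of arc along the equator: 2*pi*R / 360
  expect_equal(haversine_km(c(0, 0), c(1, 0)), 111.19, tolerance = 0.01)
  # symmetry on random pairs
  set.seed(1)
  for (i in 1:10) {
    a <- c(runif(1, -180, 180), runif(1, -89, 89))
    b <- c(runif(1, -180, 180), runif(1, -89, 89))
    expect_equal(haversine_km(a, b), haversine_km(b, a))
  }
  expect_error(haversine_km(c(200, 0), c(0, 0)), "out of range")
})

test_that("haversine agrees with an independent geodesy implementation", {
  skip_if_not_installed("geosphere")
  set.seed(2)
  for (i in 1:20) {
    a <- c(runif(1, -180, 180), runif(1, -89, 89))
    b <- c(runif(1, -180, 180), runif(1, -89, 89))
    ref <- geosphere::distHaversine(a, b, r = 6371008.8) / 1000
    expect_equal(haversine_km(a, b), ref, tolerance = 1e-9)
  }
})

test_that("distance to coast is exact at vertices and perpendiculars", {
  coast <- coastline(cbind(lon = c(0, 0), lat = c(-1, 1)))
  expect_equal(distance_to_coast(c(0, 1), coast), 0)
  # 0.1 degrees due east of a meridian segment at the equator
  expect_equal(distance_to_coast(c(0.1, 0), coast), 11.12,
               tolerance = 0.05)
  expect_error(distance_to_coast(c(0, 0), coastline(list())),
               "at least one part")
})

test_that("segment distance agrees with a dense-sampling oracle", {
  set.seed(5)
  for (i in 1:5) {
    verts <- cbind(lon = -9.5 + cumsum(runif(6, -0.05, 0.05)),
                   lat = 54 + cumsum(runif(6, -0.05, 0.05)))
    coast <- coastline(verts)
    pt <- c(-9.45 + runif(1, -0.02, 0.02), 54.02 + runif(1, -0.02, 0.02))
    got <- distance_to_coast(pt, coast)
    # oracle: haversine to 10,000 sample points along every segment
    best <- Inf
    for (s in seq_len(nrow(verts) - 1)) {
      t <- seq(0, 1, length.out = 10000)
      px <- verts[s, 1] + t * (verts[s + 1, 1] - verts[s, 1])
      py <- verts[s, 2] + t * (verts[s + 1, 2] - verts[s, 2])
      rad <- pi / 180
      h <- sin((py - pt[2]) * rad / 2)^2 +
        cos(pt[2] * rad) * cos(py * rad) * sin((px - pt[1]) * rad / 2)^2
      best <- min(best, 2 * 6371.0088 * asin(sqrt(h)))
    }
    expect_equal(got, best, tolerance = 0.005 * best + 1e-6)
    # never closer than the nearest vertex allows
    vert_d <- apply(verts, 1, function(v) haversine_km(pt, v))
    expect_lte(got, min(vert_d) + 1e-9)
  }
})

test_that("coastline readers accept GeoJSON and CSV", {
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = rbind(c(-10, 54), c(-9.8, 54.2))),
    properties = NULL), auto_unbox = TRUE, null = "null"), f)
  c1 <- read_coastline(f)
  expect_s3_class(c1, "coastline")
  expect_equal(nrow(c1[[1]]), 2)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(lon = c(-10, -9.8), lat = c(54, 54.2)), f2,
            row.names = FALSE)
  c2 <- read_coastline(f2)
  expect_equal(unname(c1[[1]]), unname(c2[[1]]))
})

test_that("Mann-Whitney U statistic counts exceeding pairs", {
  # complete separation: U = n1 * n2
  r <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$U, 9)
  expect_equal(r$method, "exact")
  # one tied pair counts half
  r <- mann_whitney_u(1, 1)
  expect_equal(r$U, 0.5)
  expect_equal(r$p, 1)
  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
  expect_error(mann_whitney_u(c(1, 1), c(1, 2), method = "exact"), "tied")
})

test_that("U1 + U2 = n1 n2 for all inputs, ties included", {
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(1:10, 1); n2 <- sample(1:10, 1)
    x <- sample(1:6, n1, replace = TRUE)   # heavy ties
    y <- sample(1:6, n2, replace = TRUE)
    u1 <- mann_whitney_u(x, y)$U
    u2 <- mann_whitney_u(y, x)$U
    expect_equal(u1 + u2, n1 * n2)
    expect_true(u1 >= 0 && u1 <= n1 * n2)
  }
})

test_that("exact p equals brute-force enumeration for tie-free samples", {
  set.seed(31)
  cases <- list()
  for (n1 in 2:5) for (n2 in 2:(10 - n1))
    cases[[length(cases) + 1]] <- c(n1, n2)
  for (cs in cases) {
    pooled <- sample(seq_len(40), cs[1] + cs[2])  # distinct -> tie-free
    x <- pooled[seq_len(cs[1])]
    y <- pooled[-seq_len(cs[1])]
    got <- mann_whitney_u(x, y, method = "exact")
    expect_equal(got$p, brute_force_mwu_p(x, y), tolerance = 1e-12)
    # wilcox.test exact two-sided p is the same quantity
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$U, unname(ref$statistic))
  }
})

test_that("normal approximation tracks the exact p for moderate n", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(9)
    y <- rnorm(8, mean = runif(1, -1, 1))
    pe <- mann_whitney_u(x, y, method = "exact")$p
    pn <- mann_whitney_u(x, y, method = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("encounter distances separate communities as configured", {
  sim <- generate_sightings(default_config(), seed = 5)
  m <- association_matrix(sim$db)
  part <- assign_unmarked(sim$db,
                          detect_communities(build_sociogram(m, db = sim$db)))
  cmp <- compare_group_distances(sim$db, part)
  s <- cmp$summary
  expect_equal(s$group[1], "A")
  expect_lt(s$mean[1], 1)          # inshore mean < 1 km
  expect_gt(s$mean[2], 4)          # offshore mean > 4 km
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                    s$median <= s$q3 & s$q3 <= s$max))
  # complete separation: U = 0 for the inshore side (all closer)
  expect_equal(cmp$test$U, 0)
  expect_lt(cmp$test$p, 0.05)
  expect_equal(cmp$n_excluded_missing_distance, 0)
})

test_that("identical distances on both sides give p = 1", {
  r <- mann_whitney_u(rep(c(1, 2, 3), 4), rep(c(1, 2, 3), 4))
  expect_equal(r$U, 72)  # n1 n2 / 2
  expect_equal(r$p, 1)
})

test_that("tied encounters are excluded with a warning", {
  grades <- c(p1 = "PERMANENT", p2 = "PERMANENT",
              p3 = "PERMANENT", p4 = "PERMANENT")
  db <- toy_db(list(E1 = c("p1", "p2"), E2 = c("p3", "p4"),
                    E3 = c("p1", "p3"), E4 = c("p2"), E5 = c("p4")),
               grades = grades,
               distances = c(1, 10, 5, 2, 11))
  # E3 mixes both communities equally -> excluded
  m <- association_matrix(db, ids = c("p1", "p2"))
  # build partition manually: {p1,p2} = A, {p3,p4} = B
  part <- structure(
    data.frame(individual_id = c("p1", "p2", "p3", "p4"),
               label = c("A", "A", "B", "B"), provenance = "PRIMARY"),
    labels = c("A", "B"), class = c("community_partition", "data.frame"))
  expect_warning(cmp <- compare_group_distances(db, part), "excluded")
  expect_equal(cmp$n_excluded_unattributed, 1)
  expect_equal(cmp$summary$n_encounters, c(2, 2))
})

test_that("group sizes compare between areas", {
  db <- toy_db(list(E1 = c("a", "b", "c"), E2 = c("a", "b"),
                    E3 = c("c"), E4 = c("a", "b", "c")),
               areas = c("MAYO", "MAYO", "CONNEMARA", "CONNEMARA"))
  r <- compare_area_group_sizes(db)
  expect_setequal(r$summary$area, c("MAYO", "CONNEMARA"))
  expect_equal(sum(r$summary$n_encounters), 4)
  expect_true(r$test$p >= 0 && r$test$p <= 1)
})
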