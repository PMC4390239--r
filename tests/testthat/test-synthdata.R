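test_that("default configuration encodes the study conditions", {
  cfg <- default_config()
  inshore <- cfg$communities[[1]]
  offshore <- cfg$communities[[2]]
  expect_equal(inshore$n_individuals, 192)
  expect_equal(inshore$n_encounters, 56)
  expect_equal(unname(inshore$grade_probs),
               c(72, 74, 46) / 192, tolerance = 1e-12)
  expect_equal(inshore$tip_damage_prob, 0.07)
  expect_equal(inshore$distance$mean, 0.61)
  expect_equal(inshore$distance$max, 3.0)
  expect_equal(sort(offshore$group_sizes), c(8, 9, 30, 33))
  expect_equal(offshore$membership, "transient")
  expect_equal(unname(offshore$grade_probs),
               c(80, 8, 6) / 94, tolerance = 1e-12)
  expect_equal(offshore$tip_damage_prob, 0.48)
  expect_equal(offshore$distance$min, 4.6)
  expect_equal(offshore$distance$max, 40.5)
  expect_equal(cfg$cross_community_prob, 0)
  expect_equal(sum(inshore$grade_probs), 1)
  expect_equal(sum(offshore$grade_probs), 1)
})

test_that("configuration validation rejects inconsistent specs", {
  expect_error(community_spec("X", 10, 2, group_sizes = c(8, 8),
                              membership = "transient"),
               "n_individuals >= sum")
  expect_error(community_spec("X", 10, 2,
                              group_sizes = list(dist = "lognormal",
                                                 mean = 3, sd = 1),
                              membership = "transient"),
               "explicit group_sizes")
  expect_error(community_spec("X", 10, 2, group_sizes = c(3, 3),
                              grade_probs = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(simulation_config(list(), 0), "non-empty")
  cfg <- default_config()
  expect_error(simulation_config(cfg$communities, 1.5), "\\[0, 1\\]")
})

test_that("generation is deterministic per seed", {
  cfg <- default_config()
  s1 <- generate_sightings(cfg, seed = 42)
  s2 <- generate_sightings(cfg, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sightings(s1$db, f1)
  write_sightings(s2$db, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_sightings(cfg, seed = 43)
  expect_false(identical(s1$db$sightings, s3$db$sightings))
})

test_that("generated databases validate and respect the membership models", {
  sim <- generate_sightings(default_config(), seed = 1)
  expect_equal(nrow(validate_database(sim$db)), 0)

  sightings_per_ind <- table(sim$db$sightings$individual_id)
  offshore_ids <- sim$truth$individuals$id[
    sim$truth$individuals$community == "OFFSHORE"]
  # transient model: every offshore individual has exactly one sighting
  expect_true(all(sightings_per_ind[offshore_ids] == 1))
  expect_equal(length(offshore_ids), 8 + 9 + 30 + 33)

  inshore_ids <- sim$truth$individuals$id[
    sim$truth$individuals$community == "INSHORE"]
  resight <- mean(sightings_per_ind[inshore_ids] >= 2)
  expect_gt(resight, 0.5)

  # no encounter mixes communities when cross probability is 0
  enc_com <- setNames(sim$truth$encounters$community,
                      sim$truth$encounters$id)
  ind_com <- setNames(sim$truth$individuals$community,
                      sim$truth$individuals$id)
  expect_true(all(ind_com[sim$db$sightings$individual_id] ==
                    enc_com[sim$db$sightings$encounter_id]))

  # distance clipping respected exactly
  d <- sim$db$encounters$distance_from_shore_km
  off_enc <- enc_com[sim$db$encounters$encounter_id] == "OFFSHORE"
  expect_true(all(d[off_enc] >= 4.6 & d[off_enc] <= 40.5))
  expect_true(all(d[!off_enc] >= 0.05 & d[!off_enc] <= 3.0))

  # truth covers every catalogued entity
  expect_setequal(sim$truth$individuals$id, sim$db$individuals$individual_id)
  expect_setequal(sim$truth$encounters$id, sim$db$encounters$encounter_id)
})

test_that("a configuration with zero encounters yields an empty database", {
  cfg <- simulation_config(list(
    community_spec("X", 5, 0,
                   group_sizes = list(dist = "lognormal", mean = 2, sd = 1))))
  sim <- generate_sightings(cfg, seed = 1)
  expect_equal(nrow(sim$db$individuals), 0)
  expect_equal(nrow(sim$db$encounters), 0)
})

test_that("generated grade proportions converge to spec probabilities", {
  # binomial sampling check on the permanent grade of the inshore pool
  cfg <- default_config()
  p_perm <- cfg$communities[[1]]$grade_probs[["PERMANENT"]]
  hits <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    sim <- generate_sightings(cfg, seed = 1000 + r)
    ins <- sim$truth$individuals$id[
      sim$truth$individuals$community == "INSHORE"]
    grades <- sim$db$individuals$mark_grade[
      match(ins, sim$db$individuals$individual_id)]
    k <- sum(grades == "PERMANENT")
    n <- length(grades)
    ci <- qbinom(c(0.005, 0.995), n, p_perm) / n
    if (k / n >= ci[1] && k / n <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("gregariousness weights skew sighting frequencies", {
  spec <- community_spec("W", 20, 40,
                         group_sizes = list(dist = "lognormal",
                                            mean = 4, sd = 2),
                         grade_probs = c(1, 0, 0),
                         gregariousness = c(rep(10, 5), rep(0.2, 15)))
  sim <- generate_sightings(simulation_config(list(spec)), seed = 2)
  counts <- table(factor(sim$db$sightings$individual_id,
                         levels = sprintf("W_I%03d", 1:20)))
  expect_gt(mean(counts[1:5]), mean(counts[6:20]))
})

test_that("incomplete capture still identifies someone in every group", {
  spec <- community_spec("C", 30, 25,
                         group_sizes = list(dist = "lognormal",
                                            mean = 5, sd = 3),
                         grade_probs = c(1, 0, 0), capture_prob = 0.3)
  sim <- generate_sightings(simulation_config(list(spec)), seed = 3)
  expect_equal(nrow(validate_database(sim$db)), 0)
  expect_true(all(table(sim$db$sightings$encounter_id) >= 1))
  # identified counts never exceed the group size estimate
  n_id <- table(factor(sim$db$sightings$encounter_id,
                       levels = sim$db$encounters$encounter_id))
  expect_true(all(as.integer(n_id) <=
                    sim$db$encounters$group_size_estimate))
})

test_that("sweep reduces to a single run and reports per replicate", {
  res <- sweep_recovery(default_config(), replicates = 1, seed = 5)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_units_true, 5)
  expect_error(sweep_recovery(default_config(), replicates = 0), ">= 1")
})
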