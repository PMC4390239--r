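# Fixture builders and independent oracles shared across tests.

# Build a sighting_db directly from encounter membership lists.
# encounters: named list encounter_id -> character vector of individual ids.
toy_db <- function(encounters,
                   grades = NULL, tip = NULL,
                   dates = NULL, areas = NULL, distances = NULL) {
  ids <- sort(unique(unlist(encounters)))
  n_enc <- length(encounters)
  individuals <- data.frame(
    individual_id = ids,
    mark_grade = if (is.null(grades)) rep("PERMANENT", length(ids))
                 else unname(grades[ids]),
    tip_damage = if (is.null(tip)) rep(FALSE, length(ids))
                 else unname(tip[ids]))
  enc_ids <- names(encounters)
  encounters_df <- data.frame(
    encounter_id = enc_ids,
    date = if (is.null(dates)) as.Date("2010-06-01") + seq_len(n_enc)
           else as.Date(dates),
    area = if (is.null(areas)) rep("AREA1", n_enc) else areas,
    distance_from_shore_km = if (is.null(distances)) NA_real_ else distances)
  sightings <- data.frame(
    encounter_id = rep(enc_ids, lengths(encounters)),
    individual_id = unlist(encounters, use.names = FALSE))
  sighting_database(individuals, encounters_df, sightings)
}

# Random small database for property tests (ids P* permanent, T*/S* other).
random_db <- function(seed, n_ind = 10, n_enc = 20, p_perm = 0.6) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n_ind))
  grades <- setNames(sample(c("PERMANENT", "TEMPORARY", "SUPERFICIAL"),
                            n_ind, replace = TRUE,
                            prob = c(p_perm, (1 - p_perm) / 2,
                                     (1 - p_perm) / 2)), ids)
  encs <- list()
  for (e in seq_len(n_enc)) {
    size <- sample(1:max(2, n_ind %/% 2), 1)
    encs[[sprintf("E%02d", e)]] <- sample(ids, size)
  }
  toy_db(encs, grades = grades)
}

# Naive recount of dyad counts and HWI by a double loop over encounters —
# independent of the incidence-matrix implementation.
naive_hwi <- function(db, ids) {
  members <- lapply(split(db$sightings$individual_id,
                          db$sightings$encounter_id), unique)
  res <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      x <- ya <- yb <- 0
      for (m in members) {
        a_in <- ids[i] %in% m
        b_in <- ids[j] %in% m
        if (a_in && b_in) x <- x + 1
        else if (a_in) ya <- ya + 1
        else if (b_in) yb <- yb + 1
      }
      hwi <- if (x + ya + yb == 0) 0 else x / (x + 0.5 * (ya + yb))
      res[[length(res) + 1]] <- data.frame(
        id_a = ids[i], id_b = ids[j], x = x, y_a = ya, y_b = yb, hwi = hwi)
    }
  }
  do.call(rbind, res)
}

# Exact two-sided Mann-Whitney p by brute force over all C(n1+n2, n1)
# labelings of the pooled sample.
brute_force_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_stat <- function(xi) {
    xs <- pooled[xi]
    ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_stat(seq_len(n1)) - mu)
  labelings <- combn(n, n1)
  devs <- apply(labelings, 2, function(xi) abs(u_stat(xi) - mu))
  mean(devs >= obs - 1e-9)
}

# Chi-square upper tail by adaptive numerical integration of the density.
integrate_chisq_tail <- function(x, df) {
  dens <- function(t) t^(df / 2 - 1) * exp(-t / 2) /
    (2^(df / 2) * gamma(df / 2))
  integrate(dens, x, Inf, rel.tol = 1e-13, abs.tol = 1e-14)$value
}
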