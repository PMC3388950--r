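test_that("Moran's I matches hand evaluation and dense-matrix oracles", {
  # two mutually adjacent zones with values (0, 1): I = -1
  adj2 <- zone_adjacency(data.frame(a = "Z1", b = "Z2"), c("Z1", "Z2"))
  expect_equal(morans_i(c(0, 1), adj2), -1)
  # constant values: statistic undefined
  expect_error(morans_i(c(2, 2), adj2), "constant")
  # random instances against an independent dense-matrix implementation
  for (s in 1:10) {
    set.seed(s)
    adj <- lattice_adjacency(4, 5)
    x <- rnorm(20)
    expect_equal(morans_i(x, adj), oracle_morans_dense(x, adj))
  }
  # ape cross-check on a ring: ape row-normalises its weight matrix, which
  # coincides with binary contiguity weights only on a regular graph
  ring <- zone_adjacency(
    data.frame(a = sprintf("Z%d", 1:12),
               b = sprintf("Z%d", c(2:12, 1))), sprintf("Z%d", 1:12))
  for (s in 1:5) {
    set.seed(s + 50)
    x <- rnorm(12)
    W <- matrix(0, 12, 12)
    idx <- cbind(match(ring$edges$a, ring$zone_ids),
                 match(ring$edges$b, ring$zone_ids))
    W[idx] <- 1; W[idx[, 2:1]] <- 1
    expect_equal(morans_i(x, ring), ape::Moran.I(x, W)$observed)
  }
})

test_that("permutation test is deterministic and detects smooth fields", {
  adj <- lattice_adjacency(5, 10)
  set.seed(10)
  x <- rnorm(50)
  d1 <- morans_i_permutation_test(x, adj, 199, seed = 4)
  d2 <- morans_i_permutation_test(x, adj, 199, seed = 4)
  expect_identical(d1$p_value, d2$p_value)
  expect_gt(d1$p_value, 0)
  expect_lte(d1$p_value, 1)
  # strongly smoothed values on the lattice: decisive positive autocorrelation
  nb <- neighbour_list(adj)
  sm <- x
  names(sm) <- adj$zone_ids
  for (k in 1:6) {
    sm <- vapply(adj$zone_ids,
                 function(z) 0.3 * sm[[z]] + 0.7 * mean(sm[nb[[z]]]),
                 numeric(1))
  }
  expect_lte(morans_i_permutation_test(sm, adj, 999, seed = 1)$p_value, 0.01)
})

test_that("permuted Moran's I is centred at -1/(n-1)", {
  adj <- lattice_adjacency(5, 8)
  n <- 40
  set.seed(2)
  x <- rnorm(n)
  perms <- vapply(1:400, function(k) {
    morans_i(sample(x), adj)
  }, numeric(1))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 3 * se)
})

test_that("spatial lag covariate is the log neighbour mean", {
  adj <- zone_adjacency(data.frame(a = c("Z1", "Z1"), b = c("Z2", "Z3")),
                        c("Z1", "Z2", "Z3", "Z4"))
  got <- spatial_lag_covariate(c(10, 3, 5, 7), adj)
  expect_equal(got[1], log(1 + 4))    # neighbours Z2, Z3: counts 3, 5
  expect_equal(got[4], 0)             # isolated zone
  # relabelling zones permutes the output identically
  perm <- c(3, 1, 4, 2)
  adj_p <- zone_adjacency(data.frame(a = c("Z1", "Z1"), b = c("Z2", "Z3")),
                          c("Z1", "Z2", "Z3", "Z4"))
  vals <- c(10, 3, 5, 7)
  got_direct <- spatial_lag_covariate(vals, adj)
  # evaluate with zone order permuted in the adjacency universe
  adj2 <- zone_adjacency(data.frame(a = c("Z1", "Z1"), b = c("Z2", "Z3")),
                         c("Z2", "Z4", "Z1", "Z3"))
  got_perm <- spatial_lag_covariate(vals[c(2, 4, 1, 3)], adj2)
  expect_equal(got_perm, got_direct[c(2, 4, 1, 3)])
})

test_that("overdispersion decision picks the data-generating family", {
  set.seed(31)
  correct_pois <- 0L; correct_nb <- 0L
  for (k in 1:20) {
    n <- 150
    x <- factor(sample(letters[1:3], n, TRUE))
    mu <- exp(2 + 0.3 * (as.integer(x) - 1))
    d_p <- data.frame(y = rpois(n, mu), x = x)
    d_n <- data.frame(y = rnbinom(n, size = 3, mu = mu), x = x)
    dec_p <- overdispersion_decision(
      glm(y ~ x, poisson, d_p),
      tryCatch(suppressWarnings(MASS::glm.nb(y ~ x, d_p)),
               error = function(e) NULL))
    dec_n <- overdispersion_decision(
      glm(y ~ x, poisson, d_n),
      suppressWarnings(MASS::glm.nb(y ~ x, d_n)))
    correct_pois <- correct_pois + (dec_p$family == "poisson")
    correct_nb <- correct_nb + (dec_n$family == "nb")
  }
  expect_gte(correct_pois, 17L)
  expect_gte(correct_nb, 17L)
})

test_that("with no cluster variance the GLMM matches a single-level fit", {
  d <- sim_recovery_data(8, n_zones = 150, n_la = 5, theta = Inf, la_sd = 0)
  res <- fit_count_glmm(d, model_spec(family = "poisson"))
  ref <- glm(count ~ factor(quintile) + offset(log(population)),
             poisson, d)
  expect_equal(res$rr$rr[-1], unname(exp(coef(ref)[2:5])), tolerance = 1e-3)
  # baseline quintile has RR identically 1
  expect_equal(res$rr$rr[1], 1)
  expect_equal(res$rr$ci_low[1], 1)
})

test_that("reported intervals use the 99% normal quantile", {
  d <- sim_recovery_data(9, n_zones = 150, n_la = 5)
  res <- fit_count_glmm(d, model_spec(family = "nb", level = 0.99))
  se <- sqrt(diag(as.matrix(vcov(res$fit))))[["quintileQ3"]]
  implied_z <- log(res$rr$ci_high[3] / res$rr$rr[3]) / se
  expect_equal(implied_z, qnorm(0.995), tolerance = 1e-8)
})

test_that("missing quintiles are reported and their RRs omitted", {
  d <- sim_recovery_data(10, n_zones = 120, n_la = 4)
  d <- d[d$quintile != 4, ]
  res <- fit_count_glmm(d, model_spec(family = "poisson"))
  expect_false(4 %in% res$rr$quintile)
  expect_match(paste(res$notes, collapse = " "), "4")
})

test_that("stratified analysis covers strata and records the skipped", {
  set.seed(12)
  nz <- 90
  zones <- data.frame(zone_id = sprintf("Z%03d", 1:nz),
                      population = round(runif(nz, 500, 1000)),
                      quintile = rep(1:5, length.out = nz),
                      stratum = rep(c("urban", "rural"), each = nz / 2),
                      la_id = sprintf("LA%d", rep(1:3, length.out = nz)))
  cnt <- rpois(nz, 6)
  acc <- data.frame(zone_id = zones$zone_id, mode = "walk",
                    intensity = "moderate", threshold = 20, count = cnt,
                    adjusted_count = cnt)
  out <- stratified_analysis(acc, zones, adjacency = NULL,
                             n_permutations = 49)
  # urban and rural fitted; the empty small-town stratum is recorded
  expect_setequal(unique(out$results$stratum), c("urban", "rural"))
  expect_true(any(out$skipped$reason == "no zones in stratum"))
  # stratum partition covers all zones
  expect_equal(sum(zones$stratum == "urban") + sum(zones$stratum == "rural"),
               nz)
  # Q1 baseline rows present with RR 1
  expect_true(all(out$results$rr[out$results$quintile == 1] == 1))
})
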