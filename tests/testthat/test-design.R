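three_factors <- function() {
  list(factor_spec("temperature", c("low", "high")),
       factor_spec("humidity", c("low", "high")),
       factor_spec("co2", c("low", "high")))
}

test_that("combination enumeration is the lexicographic Cartesian product", {
  comb <- enumerate_combinations(three_factors())
  expect_equal(nrow(comb), 8)
  expect_identical(names(comb), c("temperature", "humidity", "co2"))
  # first factor slowest
  expect_identical(comb$temperature, rep(c("low", "high"), each = 4))
  expect_identical(comb$co2, rep(c("low", "high"), 4))

  expect_equal(nrow(enumerate_combinations(list(factor_spec("t", 1:2)))), 2)
  expect_equal(nrow(enumerate_combinations(
    list(factor_spec("a", 1:2), factor_spec("b", 1:3)))), 6)
  expect_error(enumerate_combinations(list()), "at least one")
  expect_error(factor_spec("t", c(1, 1)), ">= 2 distinct")
})

test_that("split-plot assignment: 112 units, balance, determinism", {
  comb <- enumerate_combinations(three_factors())
  gen <- paste0("G", 1:14)
  lay <- assign_splitplot(paste0("ch", 1:8), comb, gen, 14, seed = 21)
  expect_equal(nrow(lay$pot_table), 112)
  expect_equal(nrow(lay$chamber_table), 8)
  # every chamber gets each genotype exactly once
  tab <- table(lay$pot_table$chamber, lay$pot_table$genotype)
  expect_true(all(tab == 1))
  # every combination used exactly once across the 8 chambers
  key <- do.call(paste, lay$chamber_table[, -1])
  expect_equal(anyDuplicated(key), 0)

  # 2 combinations over 8 chambers -> 4 chambers each
  comb2 <- enumerate_combinations(list(factor_spec("temperature", c("low", "high"))))
  lay2 <- assign_splitplot(paste0("ch", 1:8), comb2, gen, 14, seed = 4)
  expect_equal(as.vector(table(lay2$chamber_table$temperature)), c(4L, 4L))

  # determinism
  expect_identical(lay, assign_splitplot(paste0("ch", 1:8), comb, gen, 14, seed = 21))
  expect_false(identical(lay$chamber_table,
                         assign_splitplot(paste0("ch", 1:8), comb, gen, 14,
                                          seed = 22)$chamber_table))

  # validation
  expect_error(assign_splitplot(paste0("ch", 1:4), comb, gen, 14, seed = 1),
               "incomplete-block")
  expect_error(assign_splitplot(paste0("ch", 1:8), comb, gen, 10, seed = 1),
               "pot positions")
})

test_that("new replications re-randomize with fresh run ids", {
  comb <- enumerate_combinations(three_factors())
  gen <- paste0("G", 1:14)
  lay <- assign_splitplot(paste0("ch", 1:8), comb, gen, 14, seed = 9)
  rep2 <- new_replication(lay)
  expect_equal(rep2$run_id, 2L)
  expect_identical(rep2$chambers, lay$chambers)
  expect_identical(rep2$genotypes, lay$genotypes)
  expect_false(identical(rep2$chamber_table, lay$chamber_table) &&
                 identical(rep2$pot_table, lay$pot_table))
  # replication is itself deterministic
  expect_identical(new_replication(lay), rep2)
})

test_that("randomization is uniform over combination x chamber pairings", {
  # 10^4 seeded draws of 8 combinations over 8 chambers; chi-square
  # goodness-of-fit per chamber must not reject uniformity at alpha 0.01
  comb <- enumerate_combinations(three_factors())
  n_draw <- 10000
  counts <- matrix(0L, 8, 8)  # chamber x combination index
  lay <- assign_splitplot(paste0("ch", 1:8), comb, "G1", 1, seed = 1000)
  for (i in seq_len(n_draw)) {
    lay <- new_replication(lay, seed = 1000 + i)
    key <- match(do.call(paste, lay$chamber_table[, -1]),
                 do.call(paste, comb))
    counts[cbind(seq_len(8), key)] <- counts[cbind(seq_len(8), key)] + 1L
  }
  expect_equal(sum(counts), 8 * n_draw)
  for (ch in 1:8) {
    p <- stats::chisq.test(counts[ch, ])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("quadratic response surface: exact fit, boundary rule, recovery", {
  lv <- c(22, 24, 26, 28)
  # exact interpolation of y = -(t - 25)^2 + 10
  d <- data.frame(genotype = "a", level = lv, response = -(lv - 25)^2 + 10)
  fit <- fit_response_surface(d, level_range = c(22, 28))
  expect_equal(fit$fits$optimum, 25)
  expect_equal(fit$fits$intercept, -615, tolerance = 1e-8)
  expect_equal(fit$fits$linear, 50, tolerance = 1e-9)
  expect_equal(fit$fits$quadratic, -1, tolerance = 1e-10)
  expect_false(fit$fits$at_boundary)

  # increasing linear response -> optimum at the upper endpoint
  d2 <- data.frame(genotype = "b", level = rep(lv, 2),
                   response = rep(2 * lv, 2) + c(rep(0, 4), rep(1e-9, 4)))
  fit2 <- fit_response_surface(d2, level_range = c(22, 28))
  expect_equal(fit2$fits$optimum, 28)
  expect_true(fit2$fits$at_boundary)

  # too few distinct levels -> flagged, not fitted
  d3 <- data.frame(genotype = "c", level = c(22, 22, 24), response = 1:3)
  expect_true(fit_response_surface(d3, c(22, 28))$fits$flagged)

  # convex fit (minimum inside range) -> pick the better endpoint
  d4 <- data.frame(genotype = "d", level = lv, response = (lv - 24)^2)
  fit4 <- fit_response_surface(d4, c(22, 28))
  expect_equal(fit4$fits$optimum, 28)  # (28-24)^2 = 16 > (22-24)^2 = 4
})

test_that("per-genotype optimum recovery on the 22-28 degC design", {
  # 14 genotypes with true optima in [23, 27]; responses from the
  # genotype-specific quadratic with sd 0.2 noise, 2 chambers per level
  set.seed(77)
  lv <- c(22, 24, 26, 28)
  n_gen <- 14
  opt_true <- runif(n_gen, 23, 27)
  rows <- list()
  for (g in seq_len(n_gen)) {
    for (t in rep(lv, each = 2)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = paste0("G", g), level = t,
        response = 10 - (t - opt_true[g])^2 + rnorm(1, 0, 0.2))
    }
  }
  d <- do.call(rbind, rows)
  fit <- fit_response_surface(d, level_range = c(22, 28))
  err <- abs(fit$fits$optimum - opt_true)
  expect_gte(mean(err <= 0.5), 0.90)

  # consistency: bias vanishes as noise -> 0
  d0 <- d
  d0$response <- 10 - (d0$level - opt_true[match(d0$genotype,
                                                 paste0("G", 1:14))])^2
  fit0 <- fit_response_surface(d0, level_range = c(22, 28))
  expect_equal(fit0$fits$optimum, opt_true, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("layouts export to CSV and JSON", {
  comb <- enumerate_combinations(three_factors())
  lay <- assign_splitplot(paste0("ch", 1:8), comb, paste0("G", 1:3), 4, seed = 2)
  fc <- tempfile(fileext = ".csv")
  export_layout(lay, fc, "csv")
  back <- utils::read.csv(fc)
  expect_equal(nrow(back), 24)
  expect_true(all(c("run", "chamber", "pot", "genotype", "temperature") %in%
                    names(back)))
  fj <- tempfile(fileext = ".json")
  export_layout(lay, fj, "json")
  backj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(backj), 24)
})
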