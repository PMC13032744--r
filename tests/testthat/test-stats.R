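test_that("animal averages weight animals, not spines", {
  d <- data.frame(animal = c("a", "a"), g = "x", v = c(1, 3))
  aa <- animal_averages(d, "v", "g")
  expect_equal(aa$groups$mean, 2)
  # unequal spine counts: group mean is the unweighted mean of animal means
  d2 <- data.frame(animal = c(rep("a", 10), "b"), g = "x",
                   v = c(rep(1, 10), 3))
  expect_equal(animal_averages(d2, "v", "g")$groups$mean, 2)
  # row order is irrelevant
  d3 <- d2[sample(nrow(d2)), ]
  expect_equal(animal_averages(d3, "v", "g")$groups,
               animal_averages(d2, "v", "g")$groups)
  # infinite sentinels are excluded and counted
  d4 <- data.frame(animal = c("a", "a", "b"), g = "x", v = c(1, Inf, 3))
  aa4 <- animal_averages(d4, "v", "g")
  expect_equal(aa4$groups$mean, 2)
  expect_equal(aa4$groups$n_excluded_infinite, 1)
  expect_error(animal_averages(d, "v", "missing_col"), "missing")
})

test_that("Tukey ladder transform finds identity and log and preserves ranks", {
  set.seed(61)
  tl <- tukey_ladder_transform(rnorm(500, mean = 10))
  expect_gte(tl$lambda, 0.7)
  expect_lte(tl$lambda, 1.3)
  tl2 <- tukey_ladder_transform(exp(rnorm(500)))
  expect_gte(tl2$lambda, -0.3)
  expect_lte(tl2$lambda, 0.3)
  x <- rexp(200)
  for (l in c(-2, -0.5, 0, 0.5, 2)) {
    tr <- tukey_ladder_transform(x, lambdas = l)
    expect_identical(rank(tr$values), rank(x))
  }
  expect_error(tukey_ladder_transform(rep(1, 10)), "non-constant")
})

test_that("hierarchical permutation test is calibrated under the null", {
  gen_null <- function() {
    d <- expand.grid(sp = 1:8, slice_i = 1:4, animal = 1:6)
    d$slice <- paste(d$animal, d$slice_i)
    an <- rnorm(6, 0, 0.5)
    sl <- rnorm(24, 0, 0.5)
    d$g <- ifelse(d$slice_i <= 2, "A", "B")
    d$val <- an[d$animal] + sl[match(d$slice, unique(d$slice))] + rnorm(nrow(d))
    d
  }
  set.seed(62)
  rej <- replicate(400, {
    d <- gen_null()
    hierarchical_permutation_test(d, "val", "g", slice = "slice",
                                  n_perm = 99)$p_value <= 0.05
  })
  # 3 binomial SE around nominal 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("permutation test has power against a configured rate doubling", {
  set.seed(63)
  p <- replicate(20, {
    cfg <- sim_config(n_animals = 10, seed = sample.int(1e6, 1))
    pop <- simulate_spine_population(cfg)
    d <- merge(pop$spines,
               pop$truth[, c("spine_id", "true_pre_rate", "true_post_rate")])
    d <- d[d$tboa == 0, ]
    d$rc <- (d$true_post_rate - d$true_pre_rate) / d$true_pre_rate
    hierarchical_permutation_test(d, "rc", "abeta", n_perm = 999)$p_value
  })
  expect_gte(mean(p < 0.01), 0.9)
})

test_that("permutation p-values respect their lower bound and design checks", {
  cfg <- sim_config(n_animals = 4, seed = 64)
  pop <- simulate_spine_population(cfg)
  d <- pop$spines
  d$v <- rnorm(nrow(d)) + 100 * d$abeta  # overwhelming effect
  pt <- hierarchical_permutation_test(d, "v", "abeta", n_perm = 50, seed = 1)
  expect_gte(pt$p_value, 1 / 51)
  # a factor varying within the exchange unit is rejected
  d$bad <- rep(c("A", "B"), length.out = nrow(d))
  expect_error(
    hierarchical_permutation_test(d, "v", "bad", n_perm = 10),
    "exchange")
  # too few exchange units per arm: one slice from each arm only
  s0 <- unique(d$slice[d$abeta == 0])[1]
  s1 <- unique(d$slice[d$abeta == 1])[1]
  one_each <- d[d$slice %in% c(s0, s1), ]
  expect_error(
    hierarchical_permutation_test(one_each, "v", "abeta", n_perm = 10),
    "2 exchange units")
})

test_that("mass-to-molar conversion reproduces the printed worked examples", {
  # amyloid-beta 1-40 (4329.8 g/mol) and 1-42 (4514.1 g/mol) ELISA values
  expect_equal(pg_per_ml_to_pM(227.2, 4329.8, digits = 1), 52.5)
  expect_equal(pg_per_ml_to_pM(140.6, 4514.1, digits = 1), 31.1)
  expect_equal(pg_per_ml_to_pM(76.1, 4329.8, digits = 1), 17.6)
  expect_equal(pg_per_ml_to_pM(452.9, 4329.8, digits = 1), 104.6)
  expect_equal(pg_per_ml_to_pM(54.8, 4514.1, digits = 2), 12.14)
  expect_equal(pg_per_ml_to_pM(75.6, 4329.8, digits = 1), 17.5)
  expect_equal(pg_per_ml_to_pM(4.1, 4514.1, digits = 2), 0.91)
  # linearity and domain errors
  expect_equal(pg_per_ml_to_pM(2 * 227.2, 4329.8),
               2 * pg_per_ml_to_pM(227.2, 4329.8))
  expect_error(pg_per_ml_to_pM(0, 4329.8), "positive")
})

test_that("report writer is deterministic and conserves counts", {
  cfg <- sim_config(n_animals = 4, seed = 65)
  pop <- simulate_spine_population(cfg)
  sp <- merge(pop$spines,
              pop$truth[, c("spine_id", "true_pre_rate", "true_post_rate")])
  sp$rate_pre <- sp$true_pre_rate
  sp$rate_post <- sp$true_post_rate
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  p1 <- build_report(sp, out1, figures = FALSE)
  p2 <- build_report(sp, out2, figures = FALSE)
  for (f in basename(p1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  loss <- read.csv(file.path(out1, "summary_spine_loss.csv"))
  expect_equal(sum(loss$n_day1), nrow(sp))
  # PsVue section present with psvue columns, absent without
  expect_true("summary_psvue_change.csv" %in% basename(p1))
  sp2 <- sp[, setdiff(names(sp), c("psvue_pre", "psvue_post"))]
  p3 <- build_report(sp2, file.path(tempdir(), "rep3"), figures = FALSE)
  expect_false("summary_psvue_change.csv" %in% basename(p3))
  expect_error(build_report(sp[, 1:3], tempdir()), "missing upstream")
  unlink(c(out1, out2, file.path(tempdir(), "rep3")), recursive = TRUE)
})
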