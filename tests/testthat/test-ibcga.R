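# ibcga_optimizer: population init, OA crossover, mutation, full runs

toy_config <- function(...) {
  defaults <- list(n_pop = 8, g_max = 3, r_start = 6, r_end = 3,
                   cv_folds = 5, seed = 1)
  do.call(ibcga_config, utils::modifyList(defaults, list(...)))
}

mk_ch <- function(idx, n, c_idx = 1, g_idx = 1) {
  genes <- logical(n); genes[idx] <- TRUE
  noderad:::new_chromosome(genes, c_idx, g_idx)
}

test_that("initialization: exact popcount, seeded determinism, boundary", {
  cfg <- ibcga_config(n_pop = 20, r_start = 70, seed = 5)
  withr::with_seed(5, pop <- initialize_population(cfg, 89))
  expect_true(all(vapply(pop, function(ch) sum(ch$genes), 0) == 70))
  withr::with_seed(5, pop2 <- initialize_population(cfg, 89))
  expect_identical(pop, pop2)

  cfgb <- ibcga_config(n_pop = 4, r_start = 70, seed = 1)
  withr::with_seed(1, popb <- initialize_population(cfgb, 70))
  expect_true(all(vapply(popb, function(ch) all(ch$genes), TRUE)))
  expect_error(initialize_population(ibcga_config(r_start = 10), 5),
               class = "noderad_config_error")
})

test_that("fitness refuses empty chromosomes and is a pure function", {
  tab <- generate_table(table_spec(20, 8, 2, 3, 2))
  xy <- noderad:::table_xy(tab)
  cfg <- toy_config()
  fold <- make_folds(xy$y, 5, 1)
  ch <- mk_ch(c(1, 2, 5), 8, 3, 4)
  f1 <- ibcga_fitness(ch, xy$X, xy$y, fold, cfg)
  expect_identical(f1, ibcga_fitness(ch, xy$X, xy$y, fold, cfg))
  expect_true(f1 >= 0 && f1 <= 1)
  expect_error(ibcga_fitness(mk_ch(integer(0), 8), xy$X, xy$y, fold, cfg),
               class = "noderad_invalid_chromosome")
})

test_that("orthogonal arrays have balanced, orthogonal two-level columns", {
  for (rows in c(8L, 16L)) {
    oa <- noderad:::orthogonal_array(rows)
    expect_equal(dim(oa), c(rows, rows - 1))
    expect_true(all(colSums(oa == 1) == rows / 2))
    # strength 2: every ordered level pair appears equally often
    for (j in 1:3) for (k in (j + 1):4) {
      tab <- table(oa[, j], oa[, k])
      expect_true(all(tab == rows / 4))
    }
  }
})

test_that("oa_crossover: identical parents return unevaluated copies", {
  p <- mk_ch(c(1, 3, 5), 10, 2, 2)
  calls <- 0
  fit <- function(ch) { calls <<- calls + 1; 0.5 }
  ch <- oa_crossover(p, p, 3, fit)
  expect_equal(calls, 0)
  expect_identical(ch[[1]]$genes, p$genes)
})

test_that("oa_crossover preserves popcount over random parent pairs", {
  set.seed(42)
  fit <- function(ch) sum(which(ch$genes)) / 100  # arbitrary deterministic
  for (rep in 1:200) {
    n <- sample(10:30, 1)
    r <- sample(3:8, 1)
    p1 <- mk_ch(sample(n, r), n, sample(4, 1), sample(4, 1))
    p2 <- mk_ch(sample(n, r), n, sample(4, 1), sample(4, 1))
    ch <- oa_crossover(p1, p2, r, fit)
    expect_equal(sum(ch[[1]]$genes), r)
    expect_equal(sum(ch[[2]]$genes), r)
  }
})

test_that("oa_crossover finds the exhaustive best of a toy landscape", {
  # two differing genes -> two one-gene factors; after popcount repair
  # the feasible combinations are exactly {1,5} and {2,5}, and the OA
  # rows enumerate both, so child 1 must be the exhaustive best
  p1 <- mk_ch(c(1, 5), 8)
  p2 <- mk_ch(c(2, 5), 8)
  score <- function(ch) 0.2 * ch$genes[1] + 0.7 * ch$genes[2] +
    0.05 * ch$genes[5]
  set.seed(7)
  ch <- oa_crossover(p1, p2, 2, score)
  expect_equal(which(ch[[1]]$genes), c(2, 5))
  expect_equal(which(ch[[2]]$genes), c(2, 5))  # main effects agree here

  # the all-level-1 OA row reproduces parent 1, so child 1 never falls
  # below it on any landscape
  set.seed(8)
  for (rep in 1:20) {
    w <- runif(10)
    fitw <- function(ch) sum(w[which(ch$genes)])
    q1 <- mk_ch(sample(10, 4), 10)
    q2 <- mk_ch(sample(10, 4), 10)
    out <- oa_crossover(q1, q2, 4, fitw)
    expect_gte(fitw(out[[1]]), fitw(q1))
  }
})

test_that("bit-swap mutation conserves popcount at Hamming distance 2", {
  set.seed(8)
  cfg <- toy_config(p_m = 0)
  for (rep in 1:50) {
    ch <- mk_ch(sample(12, 5), 12, 2, 2)
    mut <- bit_swap_mutation(ch, cfg)
    expect_equal(sum(mut$genes), 5)
    expect_equal(sum(mut$genes != ch$genes), 2)
    expect_equal(mut$c_idx, ch$c_idx)  # p_m = 0: parameter genes frozen
  }
  full <- mk_ch(1:6, 6)
  expect_warning(out <- bit_swap_mutation(full, cfg), "impossible")
  expect_identical(out$genes, full$genes)
})

test_that("swap positions are uniform over the unset genes", {
  set.seed(9)
  cfg <- toy_config(p_m = 0)
  n <- 12; r <- 4
  ch <- mk_ch(1:4, n)
  hits <- integer(n)
  n_rep <- 10000
  for (rep in seq_len(n_rep)) {
    mut <- bit_swap_mutation(ch, cfg)
    gained <- which(mut$genes & !ch$genes)
    hits[gained] <- hits[gained] + 1
  }
  p <- 1 / (n - r)
  sigma <- sqrt(n_rep * p * (1 - p))
  expect_true(all(abs(hits[5:12] - n_rep * p) < 3.5 * sigma))
  expect_true(all(hits[1:4] == 0))
})

test_that("ibcga_run: bounds, elitist monotonicity, determinism", {
  tab <- generate_table(table_spec(20, 12, 3, 3, 4))
  cfg <- toy_config(seed = 11, r_start = 8, r_end = 3)
  fit <- ibcga_run(tab, config = cfg)
  expect_s3_class(fit, "ibcga_fit")
  expect_true(fit$m >= cfg$r_end && fit$m <= cfg$r_start)
  expect_equal(fit$m, length(fit$features))
  expect_true(all(fit$per_r$fitness >= 0 & fit$per_r$fitness <= 1))
  # every phase keeps exactly r selected genes in its recorded best
  expect_equal(vapply(strsplit(fit$per_r$features, ";"), length, 0),
               fit$per_r$r)
  # elitism: best fitness never decreases within an r phase
  for (r in unique(fit$trace$r)) {
    tr <- fit$trace$best_fitness[fit$trace$r == r]
    expect_true(all(diff(tr) >= -1e-12))
  }
  # byte-for-byte determinism
  fit2 <- ibcga_run(tab, config = cfg)
  expect_identical(fit[setdiff(names(fit), "config")],
                   fit2[setdiff(names(fit2), "config")])
  # MED ranking covers exactly the selected features
  expect_setequal(fit$med$feature, fit$features)
})

test_that("with pure noise the selected m trends toward r_end", {
  tab <- generate_table(table_spec(15, 12, 0, 0, 6))  # no signal at all
  ms <- vapply(1:10, function(s) {
    cfg <- ibcga_config(n_pop = 6, g_max = 2, r_start = 8, r_end = 2,
                        cv_folds = 3, seed = s)
    ibcga_run(tab, config = cfg)$m
  }, 0)
  expect_lt(mean(ms), (8 + 2) / 2)
})
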