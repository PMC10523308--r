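test_that("virtual cohorts have the specified size, determinism, and stratification", {
  cfg <- highlifer_config(seed = 7)
  cohorts <- make_virtual_cohorts(335, cfg)
  expect_length(cohorts, 20)
  expect_true(all(lengths(cohorts) == 235))      # ceiling(0.7 * 335)
  expect_true(all(vapply(cohorts, function(ix) !anyDuplicated(ix),
                         logical(1))))

  # fraction 1: every cohort is the full sample set
  full <- make_virtual_cohorts(50, highlifer_config(subsample_fraction = 1))
  expect_true(all(vapply(full, identical, logical(1), y = 1:50)))

  # determinism contract
  expect_identical(make_virtual_cohorts(100, cfg),
                   make_virtual_cohorts(100, cfg))
  cfg2 <- highlifer_config(seed = 8)
  expect_false(identical(make_virtual_cohorts(100, cfg),
                         make_virtual_cohorts(100, cfg2)))

  # event-stratified draws preserve the event count
  ev <- rep(c(1, 0), c(30, 70))
  strat <- make_virtual_cohorts(100, highlifer_config(stratify_by = "event"),
                                event = ev)
  n_ev <- vapply(strat, function(ix) sum(ev[ix]), numeric(1))
  expect_true(all(n_ev == 21))                   # round(70 * 0.3)

  expect_error(make_virtual_cohorts(10, highlifer_config()), "fewer than 10")
})

test_that("combination draws cover every gene each round", {
  set.seed(9)
  combos <- draw_combinations(p = 137, m = 20, B = 30)
  expect_length(combos, 30)
  expect_true(all(lengths(combos) == 20))
  expect_setequal(unique(unlist(combos)), 1:137)
  expect_error(draw_combinations(p = 1000, m = 10, B = 5), "cover")
})

test_that("a planted linear driver ranks first and ranks are a permutation", {
  set.seed(110)
  n <- 120
  p <- 40
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("G%02d", 1:p)))
  time <- rexp(n, 0.05 * exp(1.5 * x[, 7]))
  event <- rbinom(n, 1, 0.85)
  rec <- rank_genes_in_round(x, time, event, cohort = 1:n,
                             config = highlifer_config(combination_size = 10,
                                                       combinations_per_round = 8),
                             round_seed = 3)
  expect_equal(unname(rec$rank["G07"]), 1L)
  expect_setequal(rec$rank, 1:p)
})

test_that("null round-level Wald statistics follow chi-square(1)", {
  nul <- simulate_null_cohort(simulation_config(n_samples = 300,
                                                n_genes = 2000, seed = 111))
  u <- cox_univariate_batch(nul$expression, nul$time, nul$event)
  ks <- suppressWarnings(stats::ks.test(u$wald, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("round aggregation arithmetic and order invariance", {
  mk <- function(rk, wd) list(rank = stats::setNames(rk, c("a", "b")),
                              wald = stats::setNames(wd, c("a", "b")),
                              mean_abs_coef = stats::setNames(c(1, 1), c("a", "b")),
                              n_failed = 0L)
  recs <- list(mk(c(1L, 2L), c(9, 2)), mk(c(1L, 2L), c(7, 3)),
               mk(c(2L, 1L), c(4, 5)))
  s <- aggregate_rounds(recs, top_k = 1)
  expect_equal(s$median_rank, c(1, 2))
  expect_equal(s$top_k_fraction, c(2 / 3, 1 / 3))
  expect_equal(s$median_wald, c(7, 3))
  expect_equal(s$rounds_observed, c(3, 3))
  s2 <- aggregate_rounds(rev(recs), top_k = 1)
  expect_equal(s2, s)
})

test_that("selection applies the consistency and Wald-floor criteria", {
  smry <- data.frame(gene_id = c("top", "lowwald", "inconsistent"),
                     median_rank = c(1, 2, 300),
                     top_k_fraction = c(1.0, 1.0, 0.5),
                     median_wald = c(20, 4.0, 25),
                     mean_abs_coef = 1, rounds_observed = 20)
  cfg <- highlifer_config()
  sel <- select_prognostic_genes(smry, cfg)
  # max median Wald 25 -> cutoff max(12.5, 4.7) = 12.5
  expect_equal(attr(sel, "wald_cutoff"), 12.5)
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE))

  # a consistent gene below the absolute 4.7 floor is excluded even when
  # it clears the relative rule
  smry2 <- data.frame(gene_id = c("weak", "other"),
                      median_rank = c(1, 500),
                      top_k_fraction = c(1.0, 0),
                      median_wald = c(4.0, 1.0),
                      mean_abs_coef = 1, rounds_observed = 20)
  sel2 <- select_prognostic_genes(smry2, cfg)
  expect_equal(attr(sel2, "wald_cutoff"), 4.7)
  expect_false(any(sel2$selected))
})

test_that("selection is monotone in the Wald floor", {
  set.seed(112)
  smry <- data.frame(gene_id = sprintf("G%03d", 1:200),
                     median_rank = sample(200),
                     top_k_fraction = runif(200),
                     median_wald = rchisq(200, 1) * 3,
                     mean_abs_coef = 1, rounds_observed = 20)
  floors <- c(0, 2, 4.7, 8, 15)
  sels <- lapply(floors, function(fl) {
    s <- select_prognostic_genes(smry, highlifer_config(wald_floor = fl,
                                                        top_k = 100))
    s$gene_id[s$selected]
  })
  for (i in seq_len(length(floors) - 1)) {
    expect_true(all(sels[[i + 1]] %in% sels[[i]]))
  }
})

test_that("definitive-outcome filter keeps recurrences and mature censored cases", {
  time <- c(10, 20, 40, 36)
  event <- c(1, 0, 0, 0)
  expect_equal(filter_definitive_outcomes(time, event, 36),
               c(TRUE, FALSE, TRUE, TRUE))
})

test_that("two-pass union is a pure function of data and config", {
  ch <- simulate_cohort(simulation_config(n_samples = 150, n_genes = 60,
                                          log_hazard_ratios = 0.5,
                                          seed = 113))
  cfg <- highlifer_config(combination_size = 15, combinations_per_round = 8,
                          top_k = 12, seed = 5)
  h1 <- highlifer(ch$expression, ch$time, ch$event, cfg)
  h2 <- highlifer(ch$expression, ch$time, ch$event, cfg)
  expect_identical(h1$selected_genes, h2$selected_genes)
  expect_identical(h1$summary, h2$summary)

  # provenance flags partition the union
  s <- h1$summary[h1$summary$selected, ]
  expect_true(all(s$pass %in% c("pass1", "pass2", "both")))
  expect_setequal(s$gene_id, h1$selected_genes)
})

test_that("with no early censoring the union equals pass 1", {
  ch <- simulate_cohort(simulation_config(n_samples = 150, n_genes = 60,
                                          log_hazard_ratios = 0.5,
                                          seed = 114))
  # push all censored follow-up past the definitive-outcome threshold
  time <- ifelse(ch$event == 0, pmax(ch$time, 37), ch$time)
  cfg <- highlifer_config(combination_size = 15, combinations_per_round = 8,
                          top_k = 12, seed = 5)
  hl <- highlifer(ch$expression, time, ch$event, cfg)
  sel1 <- hl$pass1$gene_id[hl$pass1$selected]
  expect_setequal(hl$selected_genes, sel1)
})

test_that("the definitive-outcome pass can recover genes diluted by early censoring", {
  # borderline effect sizes and heavy administrative censoring before 36
  # months: the second pass drops unknown-outcome samples and occasionally
  # clears the selection bar for a planted gene the first pass missed
  rescued <- vapply(1:10, function(r) {
    cfg <- simulation_config(n_samples = 150, n_genes = 100,
                             planted_block_size = 10, block_shift = 0,
                             block_cor = 0.3, log_hazard_ratios = 0.25,
                             censor_window = 60, baseline_hazard = 0.004,
                             seed = 300 + r)
    ch <- simulate_cohort(cfg)
    hcfg <- highlifer_config(combination_size = 20,
                             combinations_per_round = 10, top_k = 12,
                             consistency_fraction = 0.9, seed = 300 + r)
    hl <- highlifer(ch$expression, ch$time, ch$event, hcfg)
    s <- hl$summary
    sum(!is.na(s$pass) & s$pass == "pass2" &
          s$gene_id %in% ch$true_prognostic_genes) > 0
  }, logical(1))
  expect_gte(sum(rescued), 1)
})
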