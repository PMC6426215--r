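test_that("dataset assembly keeps marker rows constant across environments", {
  toy <- toy_prediction_inputs()
  d <- build_dataset(toy$blues, toy$binmap, "HM")
  expect_equal(nrow(d$records), 48)
  expect_equal(ncol(d$M), 30)
  expect_equal(ncol(d$H), 8)
  X <- pgebv:::.dataset_X(d, seq_len(nrow(d$records)))
  expect_equal(ncol(X), 38)   # HM = M then H
  g5 <- which(d$records$genotype == "G05")
  expect_equal(d$M[g5[1], ], d$M[g5[2], ])

  # genotype missing from the bin map is excluded with a message
  blues2 <- toy$blues
  blues2$genotype[blues2$genotype == "G01"] <- "GXX"
  expect_message(d2 <- build_dataset(blues2, toy$binmap, "M"), "excluded")
  expect_false("GXX" %in% d2$records$genotype)
})

test_that("pearson_rgp matches hand-computed correlations and flags degenerates", {
  expect_equal(pearson_rgp(1:5, 1:5), 1)
  expect_equal(pearson_rgp(1:5, -(1:5)), -1)
  expect_equal(pearson_rgp(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(pearson_rgp(rep(1, 5), 1:5)))
  expect_true(is.na(pearson_rgp(1:3, 1:3)))
  expect_error(pearson_rgp(1:4, 1:5), "length")
})

test_that("bootstrap SE is zero for perfect correlation and seed-stable", {
  x <- 1:20
  se <- bootstrap_se(2 * x + 3, x, n_boot = 500, seed = 4)
  expect_equal(as.numeric(se), 0)
  set.seed(2)
  x1 <- rnorm(20); y1 <- rnorm(20)
  expect_identical(bootstrap_se(x1, y1, 500, seed = 3),
                   bootstrap_se(x1, y1, 500, seed = 3))
})

test_that("bootstrap SE approximates the Fisher large-sample formula", {
  fisher <- (1 - 0.5^2) / sqrt(97 - 3)
  ses <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(97)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(97)
    as.numeric(bootstrap_se(x, y, n_boot = 10000, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(ses) - fisher) / fisher, 0.25)
})

test_that("oracle and constant learners bound the two-fold scheme", {
  toy <- toy_prediction_inputs()
  d <- build_dataset(toy$blues, toy$binmap, "M")
  r_or <- twofold_cv(d, learner_spec("oracle"), n_reps = 3, seed = 1,
                     n_boot = 100)
  expect_equal(r_or$r_gp, 1)
  r_ct <- twofold_cv(d, learner_spec("constant"), n_reps = 3, seed = 1,
                     n_boot = 100)
  expect_equal(r_ct$r_gp, 0)            # undefined correlations counted as 0
  expect_gt(r_ct$n_undefined, 0)
})

test_that("two-fold estimates are replication-stable across seeds", {
  toy <- toy_prediction_inputs()
  d <- build_dataset(toy$blues, toy$binmap, "M")
  r1 <- twofold_cv(d, learner_spec("rr"), n_reps = 25, seed = 1, n_boot = 50)
  r2 <- twofold_cv(d, learner_spec("rr"), n_reps = 25, seed = 2, n_boot = 50)
  # Monte-Carlo SE of the mean over reps
  expect_lt(abs(r1$r_gp - r2$r_gp), 0.2)
  expect_identical(twofold_cv(d, learner_spec("rr"), n_reps = 5, seed = 7,
                              n_boot = 50)$r_gp,
                   twofold_cv(d, learner_spec("rr"), n_reps = 5, seed = 7,
                              n_boot = 50)$r_gp)
})

test_that("LOEO builds one fold per environment with full training partitions", {
  toy <- toy_prediction_inputs(n_envs = 4)
  d <- build_dataset(toy$blues, toy$binmap, "M")
  res <- leave_one_env_out(d, learner_spec("oracle"))
  expect_equal(nrow(res$per_env), 4)
  expect_equal(res$r_gp, 1)
  expect_setequal(res$per_env$env, unique(d$records$env))
})

test_that("a sign-flipped GxE environment is the worst LOEO fold", {
  cfg <- sim_config(n_lines = 50, n_snps = 400, n_bands = 6, n_flights = 2,
                    seed = 17)
  g <- simulate_dh_genotypes(genetic_map_spec(n_snps = 400), 50, seed = 17)
  tr <- draw_env_structure(assign_qtl_effects(g, 5, cfg$var_g, seed = 17), cfg)
  # adversarial environment: GxE dominates and opposes the genetic signal
  gv <- tr$genetic_values
  tr$gxe[, "16DS"] <- -3 * (gv - mean(gv))
  plots <- simulate_trials(tr, cfg)
  bm <- build_binmap(apply_gbs_noise(g, 0.05, 0.02, seed = 17))
  blues <- build_blue_table(plots, features = character(0))
  d <- build_dataset(blues, bm, "M")
  res <- leave_one_env_out(d, learner_spec("rr"), seed = 1, n_boot = 100)
  worst <- res$per_env$env[which.min(res$per_env$r_gp)]
  expect_equal(worst, "16DS")
  expect_lt(min(res$per_env$r_gp), 0)
})

test_that("standardization and tuning never see the test partition", {
  toy <- toy_prediction_inputs()
  d <- build_dataset(toy$blues, toy$binmap, "HM")
  rows <- which(d$records$env == "E1")
  tr <- rows[1:12]; te <- rows[13:24]
  X_tr <- pgebv:::.dataset_X(d, tr)
  spec <- learner_spec("rr")
  set.seed(5); m1 <- fit_learner(spec, X_tr, d$y[tr], seed = 99)
  # shuffling the held-out labels cannot change anything fitted on training
  y2 <- d$y; y2[te] <- sample(y2[te])
  set.seed(5); m2 <- fit_learner(spec, X_tr, y2[tr], seed = 99)
  expect_identical(m1$coef, m2$coef)
  expect_identical(m1$std$center, m2$std$center)
})

test_that("two-fold partitions cover every genotype exactly once per rep", {
  toy <- toy_prediction_inputs()
  d <- build_dataset(toy$blues, toy$binmap, "M")
  rows <- which(d$records$env == "E1")
  set.seed(3)
  n <- length(rows)
  half <- sample.int(n, n %/% 2)
  parts <- list(half, setdiff(seq_len(n), half))
  expect_equal(sort(c(parts[[1]], parts[[2]])), seq_len(n))
  expect_equal(abs(length(parts[[1]]) - length(parts[[2]])) <= 1, TRUE)
})

test_that("the full grid reports every cell and exact input-set averages", {
  toy <- toy_prediction_inputs(n_geno = 20, n_bins = 15, n_envs = 2, n_h = 6)
  res <- run_experiment_grid(
    toy$blues, toy$binmap, n_reps = 2, seed = 1, n_boot = 50,
    hyper = list(rf = list(ntree = 30),
                 bayesb = list(n_iter = 300, burnin = 100),
                 plsr = list(max_comp = 5)))
  expect_equal(nrow(res), 24)
  expect_true(all(is.na(res$error)))
  expect_true(all(res$r_gp >= -1 & res$r_gp <= 1))
  s <- grid_summary(res)
  for (i in seq_len(nrow(s$by_input))) {
    cells <- res$r_gp[res$input_set == s$by_input$input_set[i]]
    expect_equal(s$by_input$mean_r_gp[i], mean(cells), tolerance = 1e-12)
  }
})

test_that("scheme variants: pooled splits, blanked target spectra, raw SNPs", {
  toy <- toy_prediction_inputs(n_envs = 3)
  d <- build_dataset(toy$blues, toy$binmap, "HM")
  pooled <- twofold_cv(d, learner_spec("rr"), n_reps = 3, seed = 2,
                       n_boot = 50, stratify_env = FALSE)
  expect_equal(nrow(pooled$per_env), 1L)
  expect_true(pooled$r_gp > -1 && pooled$r_gp < 1)

  with_h <- leave_one_env_out(d, learner_spec("rr"), seed = 3, n_boot = 50)
  no_h <- leave_one_env_out(d, learner_spec("rr"), seed = 3, n_boot = 50,
                            use_target_spectra = FALSE)
  expect_false(identical(with_h$r_gp, no_h$r_gp))

  # raw-SNP marker mode: genotype matrix in place of the bin map
  st <- simulate_study(sim_config(n_lines = 24, n_snps = 120, n_bands = 3,
                                  n_flights = 1, flight_days = 55, seed = 30))
  blues <- build_blue_table(st$plots)
  d_raw <- build_dataset(blues, st$geno, "M")
  expect_equal(ncol(d_raw$M), ncol(st$geno$calls))
  res <- twofold_cv(d_raw, learner_spec("rr"), n_reps = 2, seed = 1,
                    n_boot = 50)
  expect_true(is.finite(res$r_gp))
})
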