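test_that("grid search picks a realizable linear model on noise-free data", {
  set.seed(5)
  n <- 60
  age <- runif(n, 20, 90)
  X <- cbind(m1 = 0.1 + 0.005 * age, m2 = runif(n))
  gs <- grid_search_svr(X, age, k = 5, seed = 9)
  expect_identical(gs$best$kernel, "linear")
  expect_lt(gs$best$cv_mad, 0.5)
  # the chosen point minimizes the score table by construction
  expect_equal(gs$best$cv_mad, min(gs$scores$cv_mad))
  # grid of one point returns that point
  one <- data.frame(kernel = "linear", C = 1, epsilon = 0.5, gamma = NA_real_)
  expect_equal(grid_search_svr(X, age, k = 5, grid = one, seed = 1)$best$C, 1)
  # fixed seed means identical choice across runs
  gs2 <- grid_search_svr(X, age, k = 5, seed = 9)
  expect_identical(gs$best, gs2$best)
  expect_error(grid_search_svr(X[1:3, ], age[1:3], k = 10), "at least k")
})

test_that("SVR interpolates noise-free data at tiny epsilon and large C", {
  set.seed(8)
  n <- 50
  age <- runif(n, 20, 90)
  v <- rbind(m1 = 0.1 + 0.005 * age, m2 = 0.9 - 0.004 * age)
  colnames(v) <- sprintf("s%02d", 1:n)
  mat <- beta_matrix(v)
  st <- data.frame(sample_id = colnames(v), age = age, tissue = "t")
  hp <- data.frame(kernel = "linear", C = 1e4, epsilon = 1e-3,
                   gamma = NA_real_)
  clk <- train_clock(mat, st, c("m1", "m2"), hyperparams = hp)
  expect_lt(max(abs(predict_age(clk, mat) - age)), 0.1)
})

test_that("clock models survive serialization and respect sample order", {
  cfg <- one_tissue_cfg(n = 60, n_probes = 50, n_markers = 10, seed = 12)
  p <- generate_panel(cfg)
  mat <- p$beta[[1]]; st <- p$samples[[1]]
  clk <- train_clock(mat, st, planted_ids(p),
                     hyperparams = data.frame(kernel = "radial", C = 10,
                                              epsilon = 0.5, gamma = 0.05))
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(clk, path)
  expect_identical(predict_age(readRDS(path), mat), predict_age(clk, mat))
  # permuting samples permutes predictions identically
  perm <- sample(ncol(mat))
  pm <- beta_matrix(unclass(mat)[, perm])
  expect_equal(predict_age(clk, pm), predict_age(clk, mat)[perm])
  # duplicated sample columns give duplicated predictions
  v2 <- unclass(mat)[, c(1, 1)]
  colnames(v2) <- c("a", "b")
  pd <- predict_age(clk, beta_matrix(v2))
  expect_equal(unname(pd["a"]), unname(pd["b"]))
  # empty sample set -> empty output
  expect_length(predict_age(clk, beta_matrix(unclass(mat)[, 0, drop = FALSE])), 0)
  # missing marker -> error listing it
  drop_id <- clk$marker_ids[1]
  keep <- setdiff(probe_ids(mat), drop_id)
  expect_error(predict_age(clk, beta_matrix(unclass(mat)[keep, , drop = FALSE])),
               drop_id)
  expect_error(train_clock(mat, st, c(planted_ids(p), "cgNOPE")), "cgNOPE")
})

test_that("metrics match direct arithmetic from their definitions", {
  m <- evaluate_predictions(c(30, 40, 50), c(20, 40, 60))
  expect_equal(m$rmse, sqrt(200 / 3))
  expect_equal(m$mad, 20 / 3)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$mape, 100 * (0.5 + 0 + 1 / 6) / 3)
  expect_equal(m$theil_u, sqrt(200 / 3) / sqrt(800 / 3))
  # perfect fit
  perfect <- evaluate_predictions(c(20, 40, 60), c(20, 40, 60))
  expect_equal(unlist(perfect[c("rmse", "mad", "mape", "theil_u")]),
               c(rmse = 0, mad = 0, mape = 0, theil_u = 0))
  # constant shift
  shift <- evaluate_predictions(c(20, 40, 60) + 3, c(20, 40, 60))
  expect_equal(shift$mad, 3)
  expect_equal(shift$pearson_r, 1)
  # degenerate cases
  expect_error(evaluate_predictions(1:3, 1:4), "equal length")
  expect_true(is.na(evaluate_predictions(c(5, 5, 5), c(20, 40, 60))$pearson_r))
  expect_error(evaluate_predictions(c(1, 2), c(0, 2)), "MAPE")
})

test_that("RMSE dominates MAD for any residual vector", {
  set.seed(3)
  for (i in 1:30) {
    obs <- runif(sample(3:40, 1), 20, 90)
    pred <- obs + rnorm(length(obs), 0, 5)
    m <- evaluate_predictions(pred, obs)
    expect_gte(m$rmse, m$mad)
  }
})

test_that("the clock beats the mean-age baseline whenever signal exists", {
  for (noise in c(0.01, 0.03, 0.06)) {
    cfg <- one_tissue_cfg(n = 120, n_probes = 60, n_markers = 10,
                          seed = 40 + round(noise * 100), noise_sd = noise)
    p <- generate_panel(cfg)
    mat <- p$beta[[1]]; st <- p$samples[[1]]
    tr <- 1:90; te <- 91:120
    clk <- train_clock(beta_matrix(unclass(mat)[, tr]), st[tr, ],
                       planted_ids(p),
                       hyperparams = data.frame(kernel = "linear", C = 10,
                                                epsilon = 0.5, gamma = NA))
    pred <- predict_age(clk, beta_matrix(unclass(mat)[, te]))
    m <- evaluate_predictions(pred, st$age[te])
    base_mad <- mean(abs(mean(st$age[tr]) - st$age[te]))
    expect_lte(m$mad, base_mad)
    expect_lt(m$theil_u, 1)
  }
})
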