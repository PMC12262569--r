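test_that("efficiency matches the closed form and the inversion oracle", {
  set.seed(21)
  # orthonormal columns: efficiency of a unit contrast is 1, of (1,-1) is 0.5
  Q <- qr.Q(qr(matrix(rnorm(50 * 3), 50, 3)))
  colnames(Q) <- c("q1", "q2", "q3")
  grid <- time_grid(50, dt = 1, oversampling = 1)
  d <- assemble_design(as.list(as.data.frame(Q)), grid, intercept = FALSE)
  expect_equal(efficiency(d, contrast_spec(c(q1 = 1), d$column_names)), 1)
  expect_equal(efficiency(d, contrast_spec(c(q1 = 1, q2 = -1),
                                           d$column_names)), 0.5)

  # two correlated unit-norm regressors: compare to brute-force inversion
  x1 <- rnorm(60); x1 <- x1 / sqrt(sum(x1^2))
  z <- rnorm(60); z <- z - x1 * sum(x1 * z); z <- z / sqrt(sum(z^2))
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * z
  X <- cbind(a = x1, b = x2)
  d2 <- toy_design(list(a = x1, b = x2))
  cc <- contrast_spec(c(a = 1), d2$column_names)
  oracle <- 1 / (t(c(1, 0, 0)) %*%
                   solve(t(d2$values) %*% d2$values) %*% c(1, 0, 0))
  expect_equal(efficiency(d2, cc), drop(oracle), tolerance = 1e-10)

  expect_error(efficiency(d2, contrast_spec(c(a = 0, b = 0),
                                            d2$column_names)),
               "nonzero")
})

test_that("tVIF equals the two-model variance ratio computed by lm", {
  set.seed(22)
  for (rep in 1:5) {
    n <- sample(30:60, 1)
    p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    X[, 2] <- 0.8 * X[, 1] + 0.2 * X[, 2]   # induce correlation
    colnames(X) <- paste0("v", seq_len(p))
    d <- toy_design(as.list(as.data.frame(X)))
    j <- sample(colnames(X), 1)
    # oracle: unscaled coefficient variances from two independent lm fits
    y <- rnorm(n)
    full <- summary(lm(y ~ X))$cov.unscaled
    red <- summary(lm(y ~ X[, j]))$cov.unscaled
    oracle <- full[1 + match(j, colnames(X)), 1 + match(j, colnames(X))] /
      red[2, 2]
    expect_equal(tvif(d, j), oracle, tolerance = 1e-8)
  }
})

test_that("tVIF is 1 for an orthogonal regressor and errors on duplicates", {
  set.seed(23)
  # centred columns made exactly orthogonal to each other and the intercept
  M <- scale(matrix(rnorm(40 * 3), 40, 3), scale = FALSE)
  Q <- qr.Q(qr(M))
  d <- toy_design(list(a = Q[, 1], b = Q[, 2], c = Q[, 3]))
  expect_equal(tvif(d, "a"), 1, tolerance = 1e-10)

  # closed form 1/(1 - r^2) for two centred unit-norm regressors at r = 0.9
  x1 <- Q[, 1]
  x2 <- 0.9 * Q[, 1] + sqrt(1 - 0.81) * Q[, 2]
  d2 <- toy_design(list(a = x1, b = x2))
  expect_equal(tvif(d2, "a"), 1 / (1 - 0.81), tolerance = 1e-8)

  d3 <- toy_design(list(a = Q[, 1], b = Q[, 1]))
  expect_error(tvif(d3, "a"), "singular")
})

test_that("cVIF reduces to tVIF for elementary contrasts", {
  set.seed(24)
  for (rep in 1:5) {
    X <- matrix(rnorm(50 * 4), 50, 4)
    X[, 3] <- X[, 1] - 0.5 * X[, 2] + 0.3 * X[, 3]
    colnames(X) <- paste0("v", 1:4)
    d <- toy_design(as.list(as.data.frame(X)))
    for (j in colnames(X)) {
      cc <- contrast_spec(stats::setNames(1, j), d$column_names)
      expect_equal(cvif(d, cc), tvif(d, j), tolerance = 1e-8)
    }
  }
})

test_that("cVIF is invariant under orthogonal recoding while tVIF is not", {
  op <- overlapping_pair()
  grid <- op$grid
  d_cond <- assemble_design(list(A = op$A, B = op$B), grid)
  cv_orig <- cvif(d_cond, contrast_spec(c(A = 1), d_cond$column_names))
  tv_orig <- tvif(d_cond, "A")
  expect_gt(tv_orig, 2)  # the conditions genuinely overlap

  # sum/difference recoding: columns become (near-)orthogonal, tVIFs fall
  # to ~1, but the condition-A contrast (now 0.5*S + 0.5*D) keeps its cVIF
  d_rec <- assemble_design(list(S = op$A + op$B, D = op$A - op$B), grid)
  expect_lt(tvif(d_rec, "S"), 1.2)
  expect_lt(tvif(d_rec, "D"), 1.2)
  cv_rec <- cvif(d_rec, contrast_spec(c(S = 0.5, D = 0.5),
                                      d_rec$column_names))
  expect_equal(cv_rec, cv_orig, tolerance = 0.01)
})

test_that("cVIF is at least 1 for random estimable contrasts", {
  set.seed(26)
  for (rep in 1:20) {
    n <- sample(30:60, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    d <- toy_design(as.list(as.data.frame(X)))
    w <- round(rnorm(p), 2)
    if (all(w == 0)) w[1] <- 1
    cc <- contrast_spec(stats::setNames(w, colnames(X)), d$column_names)
    expect_gte(cvif(d, cc), 1 - 1e-10)
  }
})

test_that("cVIF rejects zero and non-task contrasts", {
  op <- overlapping_pair()
  d <- assemble_design(list(A = op$A, B = op$B), op$grid,
                       nuisance = cbind(drift = seq_len(63)))
  expect_error(cvif(d, c(A = 0, B = 0)), "nonzero")
  expect_error(cvif(d, contrast_spec(c(drift = 1), d$column_names)),
               "task columns")
})

test_that("variance identity: Var(c bhat) * efficiency = sigma^2", {
  set.seed(27)
  X <- matrix(rnorm(40 * 3), 40, 3)
  colnames(X) <- c("a", "b", "c")
  d <- toy_design(as.list(as.data.frame(X)))
  cc <- contrast_spec(c(a = 1, b = -1), d$column_names)
  sigma2 <- 2.3
  var_c <- sigma2 * drop(t(as.numeric(cc)) %*%
                           solve(crossprod(d$values)) %*% as.numeric(cc))
  expect_equal(var_c * efficiency(d, cc), sigma2, tolerance = 1e-10)
})

test_that("removing derivative regressors deflates an inflated cVIF", {
  # short adjacent conditions, each modelled with HRF + temporal derivative:
  # the shifted responses overlap the neighbouring condition and inflate the
  # condition-difference cVIF; dropping the derivatives resolves it
  grid <- time_grid(63, dt = 0.8, oversampling = 50)
  onsets <- seq(0, 44, by = 4.4)
  r1 <- make_regressor(event_table(onset = onsets,
                                   duration = rep(0.5, length(onsets))),
                       grid, "boxcar", with_derivative = TRUE)
  r2 <- make_regressor(event_table(onset = onsets + 1.0,
                                   duration = rep(0.5, length(onsets))),
                       grid, "boxcar", with_derivative = TRUE)
  d_with <- assemble_design(list(C1 = r1, C2 = r2), grid)
  d_without <- assemble_design(list(C1 = r1[, 1], C2 = r2[, 1]), grid)
  con <- c(C1 = 1, C2 = -1)
  cv_with <- cvif(d_with, contrast_spec(con, d_with$column_names))
  cv_without <- cvif(d_without, contrast_spec(con, d_without$column_names))
  expect_gt(cv_with, 3 * cv_without)
  expect_gt(cv_with, 20)   # flagged as excessive
  expect_lt(cv_without, 5)
})

test_that("merging adjacent short-event regressors reduces the cVIF", {
  grid <- time_grid(63, dt = 0.8, oversampling = 50)
  onsets <- seq(0, 44, by = 4.4)
  cue <- make_regressor(event_table(onset = onsets,
                                    duration = rep(0.5, length(onsets))),
                        grid, "boxcar")
  probe <- make_regressor(event_table(onset = onsets + 0.6,
                                      duration = rep(0.3, length(onsets))),
                          grid, "boxcar")
  d_split <- assemble_design(list(Cue = cue, Probe = probe), grid)
  merged <- make_regressor(event_table(onset = onsets,
                                       duration = rep(0.9, length(onsets))),
                           grid, "boxcar")
  d_merged <- assemble_design(list(CueProbe = merged), grid)
  cv_split <- cvif(d_split, contrast_spec(c(Cue = 1), d_split$column_names))
  cv_merged <- cvif(d_merged, contrast_spec(c(CueProbe = 1),
                                            d_merged$column_names))
  expect_gt(cv_split, 5)
  expect_lt(cv_merged, cv_split / 5)
})

test_that("parse_contrast handles weights, signs and unknown names", {
  cols <- c("CueLW", "CueNeut", "FB_LargeWin_Hit", "FB_SmallWin_Hit",
            "FB_LargeWin_Miss", "FB_SmallWin_Miss")
  c1 <- parse_contrast("CueLW - CueNeut", cols)
  expect_equal(unname(c1[c("CueLW", "CueNeut")]), c(1, -1))
  expect_true(all(c1[setdiff(cols, c("CueLW", "CueNeut"))] == 0))

  c2 <- parse_contrast(paste("0.5*FB_LargeWin_Hit + 0.5*FB_SmallWin_Hit",
                             "- 0.5*FB_LargeWin_Miss - 0.5*FB_SmallWin_Miss"),
                       cols)
  expect_equal(unname(c2[3:6]), c(0.5, 0.5, -0.5, -0.5))

  expect_error(parse_contrast("Foo - CueNeut", cols), "unknown column 'Foo'")
})

test_that("vif_report aggregates, flags thresholds, and warns on omission", {
  set.seed(28)
  Q <- qr.Q(qr(scale(matrix(rnorm(50 * 3), 50, 3), scale = FALSE)))
  d <- toy_design(list(a = Q[, 1], b = Q[, 2], c = Q[, 3]))
  cons <- list(a_vs_b = contrast_spec(c(a = 1, b = -1), d$column_names),
               a_only = contrast_spec(c(a = 1), d$column_names))
  rep <- vif_report(d, cons)
  expect_identical(rep$flag, c("ok", "ok"))
  expect_equal(unname(attr(rep, "thresholds")), c(5, 20))
  expect_equal(max(attr(rep, "tvif")), 1, tolerance = 1e-8)

  expect_warning(vif_report(d, cons, omitted = "probe"), "omitted")
  rep2 <- suppressWarnings(vif_report(d, cons, omitted = "probe"))
  expect_false("probe" %in% rep2$contrast)
  expect_identical(attr(rep2, "omitted"), "probe")
})
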