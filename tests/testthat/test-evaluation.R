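labels_26 <- data.frame(
  breast_id = c(sprintf("C%02d", 1:13), sprintf("H%02d", 1:13)),
  label = rep(c("cancerous", "healthy"), each = 13))

test_that("confusion reproduces the clinical-arithmetic examples", {
  # 13 cancerous with 2 false negatives -> sensitivity 11/13
  calls <- data.frame(breast_id = labels_26$breast_id,
                      positive = c(rep(TRUE, 11), FALSE, FALSE,
                                   rep(FALSE, 13)))
  cf <- confusion(calls, labels_26)
  expect_equal(cf$sensitivity, 11 / 13)
  expect_equal(cf$specificity, 1)
  # 13 healthy with 3 false positives -> specificity 10/13
  calls$positive[14:16] <- TRUE
  cf <- confusion(calls, labels_26)
  expect_equal(cf$specificity, 10 / 13)
  # all correct
  calls$positive <- labels_26$label == "cancerous"
  cf <- confusion(calls, labels_26)
  expect_equal(c(cf$sensitivity, cf$specificity), c(1, 1))
  # single-class cohorts leave the undefined rate NA
  onlyc <- labels_26[1:13, ]
  cf <- confusion(calls[1:13, ], onlyc)
  expect_true(is.na(cf$specificity))
  # indeterminate breasts are counted, not guessed
  calls$positive[1] <- NA
  cf <- confusion(calls, labels_26)
  expect_equal(cf$n_indeterminate_cancerous, 1)
  expect_equal(cf$sensitivity, 12 / 12)
})

make_tables <- function(devs) {
  # one-band tables whose max deviation equals the requested value
  lapply(seq_along(devs), function(i) {
    m <- matrix(30, 4, 4)
    m[2, ] <- 30 * (1 + devs[i])
    table_from_matrix(m, breast_id = labels_26$breast_id[i])
  })
}

test_that("the tolerance sweep is a monotone staircase with forced endpoints", {
  withr::with_seed(77, {
    devs <- c(runif(13, 0.3, 0.9), runif(13, 0.01, 0.25))
    tables <- make_tables(devs)
    cfg <- configuration(1, rep(0, 4))
    grid <- seq(0, 1, by = 0.05)
    sw <- tolerance_sweep(tables, labels_26, cfg, grid)
    expect_equal(c(sw$fpr[1], sw$tpr[1]), c(1, 1))      # tolerance 0
    expect_equal(c(sw$fpr[nrow(sw)], sw$tpr[nrow(sw)]), c(0, 0))
    expect_true(all(diff(sw$tpr) <= 0))
    expect_true(all(diff(sw$fpr) <= 0))
    # brute-force oracle: re-diagnose every breast at every tolerance
    for (k in c(3, 9, 15)) {
      pos <- vapply(tables, function(tb)
        diagnose(tb, cfg, grid[k])$is_positive, logical(1))
      expect_equal(sw$tpr[k], mean(pos[1:13]))
      expect_equal(sw$fpr[k], mean(pos[14:26]))
    }
  })
  expect_error(tolerance_sweep(make_tables(rep(0.5, 26)), labels_26,
                               configuration(1, rep(0, 4)), c(0.5, 0.2)),
               class = "dietdx_invalid_spec")
})

test_that("bootstrap pooling has the forced size, determinism and edge cases", {
  devs <- c(runif(13, 0.3, 0.9), runif(13, 0.01, 0.25))
  tables <- make_tables(devs)
  cfg <- configuration(1, rep(0, 4))
  grid <- seq(0, 1, by = 0.05)
  bp <- bootstrap_points(tables, labels_26, cfg, n_draw = 50, n_trials = 200,
                         grid = grid, seed = 9)
  expect_equal(nrow(bp), 200 * 21)
  expect_identical(bp, bootstrap_points(tables, labels_26, cfg, n_draw = 50,
                                        n_trials = 200, grid = grid, seed = 9))
  expect_false(identical(bp, bootstrap_points(tables, labels_26, cfg,
                                              n_draw = 50, n_trials = 200,
                                              grid = grid, seed = 10)))
  # single-breast draws give degenerate rates, one class per trial
  b1 <- bootstrap_points(tables, labels_26, cfg, n_draw = 1, n_trials = 50,
                         grid = grid, seed = 3)
  expect_true(all(b1$tpr %in% c(0, 1) | is.na(b1$tpr)))
  expect_true(all(b1$fpr %in% c(0, 1) | is.na(b1$fpr)))
  expect_true(all(is.na(b1$tpr) != is.na(b1$fpr)))
  expect_equal(attr(b1, "n_one_class_trials"), 50L)
})

test_that("total least squares recovers the curve parameter", {
  # zero-residual recovery from on-curve points
  xs <- seq(0.02, 0.98, length.out = 50)
  fit <- fit_exponential_roc(data.frame(fpr = xs, tpr = 1 - exp(-2 * xs)))
  expect_equal(fit$a, 2, tolerance = 1e-6)
  # single point: curve through (0.5, 0.75) has a = 2 log 4
  fit1 <- fit_exponential_roc(data.frame(fpr = 0.5, tpr = 0.75))
  expect_equal(fit1$a, 2 * log(4), tolerance = 1e-6)
  # symmetric orthogonal noise around a known curve
  withr::with_seed(41, {
    a0 <- 3
    x0 <- runif(500, 0.02, 0.95)
    y0 <- 1 - exp(-a0 * x0)
    slope <- a0 * exp(-a0 * x0)
    nx <- -slope / sqrt(1 + slope^2); ny <- 1 / sqrt(1 + slope^2)
    eps <- rnorm(500, sd = 0.03)
    pts <- data.frame(fpr = x0 + eps * nx, tpr = y0 + eps * ny)
    fit <- fit_exponential_roc(pts)
    # grid-search oracle over a with an independent distance computation
    dist2 <- function(a, px, py) {
      vapply(seq_along(px), function(i)
        optimize(function(x) (x - px[i])^2 + (1 - exp(-a * x) - py[i])^2,
                 c(0, 1), tol = 1e-10)$objective, numeric(1))
    }
    agrid <- seq(2.5, 3.5, by = 0.02)
    oracle_a <- agrid[which.min(vapply(agrid, function(a)
      sum(dist2(a, pts$fpr, pts$tpr)), numeric(1)))]
    expect_equal(fit$a, oracle_a, tolerance = 0.02)
    expect_equal(fit$a, a0, tolerance = 0.1)
  })
  expect_error(fit_exponential_roc(data.frame(fpr = 0, tpr = 0)),
               class = "dietdx_degenerate_fit")
})

test_that("the closed-form AUC matches quadrature and inverts cleanly", {
  for (a in c(0.5, 2, 6.66)) {
    q <- integrate(function(x) 1 - exp(-a * x), 0, 1,
                   rel.tol = 1e-12)$value
    expect_equal(auc_from_a(a), q, tolerance = 1e-10)
  }
  expect_equal(auc_from_a(100), 1 - (1 - exp(-100)) / 100)
  # the curve family crosses the chance diagonal near a = 1.5936
  expect_equal(auc_from_a(1.59362), 0.5, tolerance = 1e-4)
  # inverse: bisection consistent with the forward map
  expect_equal(a_from_auc(0.85), 6.658, tolerance = 1e-3)
  expect_equal(a_from_auc(auc_from_a(3)), 3, tolerance = 1e-8)
  aucs <- seq(0.55, 0.95, by = 0.05)
  expect_true(all(diff(vapply(aucs, a_from_auc, numeric(1))) > 0))
  expect_error(a_from_auc(1.2), class = "dietdx_invalid_spec")
  expect_error(auc_from_a(-1), class = "dietdx_invalid_spec")
})

test_that("operating points reproduce the published configuration summaries", {
  op85 <- operating_points(a_from_auc(0.85))
  expect_equal(op85$optimal$sensitivity_pct, 81)
  expect_equal(op85$optimal$specificity_pct, 75)
  op80 <- operating_points(a_from_auc(0.80))
  expect_equal(op80$optimal$sensitivity_pct, 76)
  expect_equal(op80$optimal$specificity_pct, 71)
  # a huge parameter approaches the perfect corner
  oph <- operating_points(5000)
  expect_equal(oph$optimal$sensitivity_pct, 100)
  expect_equal(oph$optimal$specificity_pct, 100)
})

test_that("criteria reports apply the strict screening thresholds", {
  fit <- function(auc) structure(list(a = a_from_auc(auc), auc = auc,
                                      n_points = 1, configuration = NA),
                                 class = "bootstrap_fit")
  rep85 <- criteria_report(fit(0.85))
  expect_true(rep85$auc_ok && rep85$criterion1_pass && rep85$criterion2_pass)
  rep70 <- criteria_report(fit(0.70))
  expect_false(rep70$auc_ok)
  # boundary AUC exactly 0.73 fails the strict inequality
  expect_false(criteria_report(fit(0.73))$auc_ok)
})
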