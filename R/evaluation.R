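# ROC evaluation of the tolerance classifier: discrete tolerance sweeps,
# bootstrap resampling (50 breasts with replacement, 200 trials), a
# total-least-squares fit of the one-parameter curve y = 1 - exp(-a x) to
# the pooled (FPR, TPR) points, the closed-form AUC of that curve, and the
# derived operating points used by the diagnostic criteria.

#' Sensitivity and specificity of a set of calls
#'
#' @param calls Data frame with `breast_id` and logical `positive`
#'   (`NA` = indeterminate).
#' @param labels Data frame with `breast_id` and `label`
#'   ("healthy"/"cancerous").
#' @return List with `sensitivity`, `specificity` (fractions, `NA` when the
#'   class is absent or entirely indeterminate), the confusion counts, and
#'   per-class indeterminate counts.
#' @export
confusion <- function(calls, labels) {
  m <- merge(calls, labels, by = "breast_id")
  if (nrow(m) != nrow(calls))
    stop_invalid("every diagnosed breast must be labelled")
  canc <- m$label == "cancerous"
  hlth <- m$label == "healthy"
  tp <- sum(canc & m$positive, na.rm = TRUE)
  fn <- sum(canc & !m$positive, na.rm = TRUE)
  tn <- sum(hlth & !m$positive, na.rm = TRUE)
  fp <- sum(hlth & m$positive, na.rm = TRUE)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp,
    n_indeterminate_cancerous = sum(canc & is.na(m$positive)),
    n_indeterminate_healthy = sum(hlth & is.na(m$positive))
  )
}

# Per-breast max deviations + labels, the sufficient statistic for sweeps.
breast_deviation_stats <- function(tables, labels, config,
                                   deviation = "control") {
  ids <- vapply(tables, `[[`, character(1), "breast_id")
  devs <- vapply(tables, max_deviation, numeric(1), config = config,
                 deviation = deviation)
  lab <- labels$label[match(ids, labels$breast_id)]
  if (anyNA(lab)) stop_invalid("every table's breast must be labelled")
  list(devs = devs, cancerous = lab == "cancerous")
}

rates_at <- function(devs, grid) {
  devs <- devs[!is.na(devs)]
  if (length(devs) == 0L) return(rep(NA_real_, length(grid)))
  vapply(grid, function(t) mean(devs > t), numeric(1))
}

#' Discrete ROC staircase over a tolerance grid
#'
#' Re-diagnoses the cohort at every tolerance in `grid`; a breast is positive
#' when any segment deviates from its band control by more than the
#' tolerance, so both rates are non-increasing in the tolerance.
#'
#' @param tables List of averaged `segment_table`s, one per breast.
#' @param labels Label data frame (`breast_id`, `label`).
#' @param config A [configuration()].
#' @param grid Ascending, non-empty tolerance grid (default 0--1 by 0.05).
#' @param deviation Deviation measure, see [diagnose()].
#' @return Data frame of `ROCPoint`s: `tolerance`, `fpr`, `tpr`.
#' @export
tolerance_sweep <- function(tables, labels, config,
                            grid = seq(0, 1, by = 0.05),
                            deviation = "control") {
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stop_invalid("`grid` must be non-empty and strictly ascending")
  st <- breast_deviation_stats(tables, labels, config, deviation)
  data.frame(tolerance = grid,
             fpr = rates_at(st$devs[!st$cancerous], grid),
             tpr = rates_at(st$devs[st$cancerous], grid))
}

#' Pooled bootstrap ROC points
#'
#' Each trial draws `n_draw` breasts with replacement from the cohort and
#' records the full tolerance sweep; the pooled points from all trials feed
#' the curve fit. A trial whose resample lacks one class contributes only
#' its defined rate (such trials are counted in the `n_one_class_trials`
#' attribute).
#'
#' @inheritParams tolerance_sweep
#' @param n_draw Breasts per resample (default 50).
#' @param n_trials Number of resamples (default 200).
#' @param seed Integer seed; identical seeds give identical pooled sets.
#' @return Data frame `trial`, `tolerance`, `fpr`, `tpr` with
#'   `n_trials * length(grid)` rows.
#' @export
bootstrap_points <- function(tables, labels, config, n_draw = 50,
                             n_trials = 200, grid = seq(0, 1, by = 0.05),
                             seed = 1L, deviation = "control") {
  if (length(tables) == 0L) stop_invalid("empty cohort")
  check_number(n_draw, "n_draw", lower = 1)
  check_number(n_trials, "n_trials", lower = 1)
  st <- breast_deviation_stats(tables, labels, config, deviation)
  n <- length(st$devs)
  one_class <- 0L
  out <- with_seed_(seed, {
    trials <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      idx <- sample.int(n, n_draw, replace = TRUE)
      canc <- st$cancerous[idx]
      if (all(canc) || !any(canc)) one_class <- one_class + 1L
      trials[[tr]] <- data.frame(
        trial = tr, tolerance = grid,
        fpr = rates_at(st$devs[idx][!canc], grid),
        tpr = rates_at(st$devs[idx][canc], grid))
    }
    do.call(rbind, trials)
  })
  attr(out, "n_one_class_trials") <- one_class
  out
}

# Squared orthogonal distances from points to y = 1 - exp(-a x), x in [0,1].
# Inner projection: coarse grid bracket + vectorised golden-section refine.
tls_dist2 <- function(a, px, py, n_grid = 101L, iters = 60L) {
  xs <- seq(0, 1, length.out = n_grid)
  ys <- 1 - exp(-a * xs)
  D <- outer(px, xs, `-`)^2 + outer(py, ys, `-`)^2
  best <- max.col(-D, ties.method = "first")
  lo <- xs[pmax(best - 1L, 1L)]
  hi <- xs[pmin(best + 1L, n_grid)]
  f <- function(x) (x - px)^2 + (1 - exp(-a * x) - py)^2
  gr <- (sqrt(5) - 1) / 2
  for (it in seq_len(iters)) {
    c1 <- hi - gr * (hi - lo); c2 <- lo + gr * (hi - lo)
    smaller <- f(c1) < f(c2)
    hi <- ifelse(smaller, c2, hi)
    lo <- ifelse(smaller, lo, c1)
  }
  f((lo + hi) / 2)
}

#' Total-least-squares fit of the one-parameter ROC curve
#'
#' Finds the `a` minimising the sum of squared perpendicular distances from
#' the pooled ROC points to `y = 1 - exp(-a x)` over `x` in `[0, 1]`. The
#' outer problem is solved by a deterministic log-spaced grid search refined
#' with bounded scalar minimisation; each point's orthogonal projection is
#' solved to ~1e-10.
#'
#' @param points Data frame with `fpr`, `tpr` (rows with `NA` are dropped).
#' @param a_max Upper bound for the curve parameter (default 50).
#' @param configuration_id Optional id stored on the fit.
#' @return An object of class `bootstrap_fit`: `a`, `auc`
#'   (`= 1 - (1 - exp(-a)) / a`), `n_points`, `configuration`.
#' @export
fit_exponential_roc <- function(points, a_max = 50, configuration_id = NA) {
  ok <- !is.na(points$fpr) & !is.na(points$tpr)
  px <- points$fpr[ok]; py <- points$tpr[ok]
  if (length(px) == 0L || all(px == 0 & py == 0))
    stop_dietdx("degenerate ROC points: nothing off the origin to fit",
                "dietdx_degenerate_fit")
  obj <- function(a) sum(tls_dist2(a, px, py))
  as_grid <- exp(seq(log(1e-2), log(a_max), length.out = 60))
  vals <- vapply(as_grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- as_grid[max(i - 1L, 1L)]; hi <- as_grid[min(i + 1L, length(as_grid))]
  opt <- optimize(obj, c(lo, hi), tol = 1e-10)
  a <- opt$minimum
  structure(
    list(a = a, auc = auc_from_a(a), n_points = length(px),
         configuration = configuration_id, rss = opt$objective),
    class = "bootstrap_fit"
  )
}

#' @export
print.bootstrap_fit <- function(x, ...) {
  cat(sprintf("<bootstrap_fit> a = %.4f, AUC = %.4f (%d points%s)\n",
              x$a, x$auc, x$n_points,
              if (is.na(x$configuration)) "" else
                sprintf(", configuration %s", x$configuration)))
  invisible(x)
}

#' Area under y = 1 - exp(-a x) on [0, 1]
#'
#' Closed form `1 - (1 - exp(-a)) / a`, strictly increasing in `a`
#' (0.5 at `a` ~ 1.5936, 1 in the limit).
#'
#' @param a Curve parameter, `> 0`.
#' @return AUC in `(0, 1)`.
#' @export
auc_from_a <- function(a) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  1 + expm1(-a) / a
}

#' Curve parameter from an AUC
#'
#' Unique inverse of [auc_from_a()], solved by bisection to 1e-12.
#'
#' @param auc AUC in `(0, 1)` (realistic diagnostic fits have `auc > 0.5`).
#' @return The `a` with `auc_from_a(a) = auc`.
#' @export
a_from_auc <- function(auc) {
  check_number(auc, "auc", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  hi <- 1
  while (auc_from_a(hi) < auc && hi < 1e6) hi <- hi * 2
  uniroot(function(a) auc_from_a(a) - auc, c(1e-12, hi), tol = 1e-12)$root
}

#' Operating points of the fitted ROC curve
#'
#' The optimal point is the point on `y = 1 - exp(-a x)` closest (Euclidean)
#' to the ideal corner `(0, 1)`, found from the stationarity condition
#' `x = a exp(-2 a x)` by bisection. Also returns the point at 80%
#' specificity (`tpr = 1 - exp(-0.2 a)`) and at 80% sensitivity
#' (`fpr = log(5) / a`). Percentages are rounded to the nearest integer.
#'
#' @param a Curve parameter, `> 0`.
#' @return List with `optimal`, `at_specificity_80`, `at_sensitivity_80`,
#'   each holding `fpr`, `tpr`, `sensitivity_pct`, `specificity_pct`.
#' @export
operating_points <- function(a) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  pt <- function(x) {
    y <- 1 - exp(-a * x)
    list(fpr = x, tpr = y,
         sensitivity_pct = round(100 * y),
         specificity_pct = round(100 * (1 - x)))
  }
  x_opt <- uniroot(function(x) x - a * exp(-2 * a * x), c(0, 1),
                   tol = 1e-12)$root
  list(optimal = pt(x_opt),
       at_specificity_80 = pt(0.2),
       at_sensitivity_80 = pt(log(5) / a))
}

#' Diagnostic-criteria report for a fitted curve
#'
#' Evaluates the three published screening criteria: AUC strictly above the
#' mammography benchmark 0.73; sensitivity of at least 60% when specificity
#' is 80% (mammography-like operation); and specificity of at least 65% when
#' sensitivity is 80% (highly sensitive screening). A boundary AUC of
#' exactly 0.73 fails the strict inequality.
#'
#' @param fit A `bootstrap_fit`.
#' @return An object of class `criteria_report`.
#' @export
criteria_report <- function(fit) {
  stopifnot(inherits(fit, "bootstrap_fit"))
  op <- operating_points(fit$a)
  structure(
    list(auc = fit$auc, auc_ok = fit$auc > 0.73,
         criterion1_sensitivity_at_spec80 = op$at_specificity_80$sensitivity_pct,
         criterion1_pass = op$at_specificity_80$sensitivity_pct >= 60,
         criterion2_specificity_at_sens80 = op$at_sensitivity_80$specificity_pct,
         criterion2_pass = op$at_sensitivity_80$specificity_pct >= 65,
         optimal_sensitivity = op$optimal$sensitivity_pct,
         optimal_specificity = op$optimal$specificity_pct),
    class = "criteria_report"
  )
}

#' @export
print.criteria_report <- function(x, ...) {
  yn <- function(b) if (b) "yes" else "NO"
  cat(sprintf(
    paste0("<criteria_report>\n",
           "  AUC %.3f > 0.73:                 %s\n",
           "  sensitivity at 80%% specificity: %d%% (>= 60: %s)\n",
           "  specificity at 80%% sensitivity: %d%% (>= 65: %s)\n",
           "  optimal point: %d%% sensitivity / %d%% specificity\n"),
    x$auc, yn(x$auc_ok),
    x$criterion1_sensitivity_at_spec80, yn(x$criterion1_pass),
    x$criterion2_specificity_at_sens80, yn(x$criterion2_pass),
    x$optimal_sensitivity, x$optimal_specificity))
  invisible(x)
}
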