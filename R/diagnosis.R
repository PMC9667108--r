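# Control-segment tolerance classifier. Within each z-band one radial
# segment is the control; any other segment whose mean frequency of interest
# deviates from the control by more than the percentage tolerance flags the
# breast as positive. Twelve control configurations probe robustness to
# tumor location; comparing within the breast makes the test self-normalised
# (scaling every frequency by a constant changes nothing).

#' Construct a control-segment configuration
#'
#' @param id Integer identifier.
#' @param control_map Integer vector of length 4: the control radial index
#'   (0--3) for z-bands 0--3.
#' @return An object of class `configuration`.
#' @export
configuration <- function(id, control_map) {
  check_number(id, "id")
  if (length(control_map) != 4L || !all(control_map %in% 0:3))
    stop_invalid("`control_map` must map all four z-bands to radial indices 0-3")
  structure(list(id = as.integer(id),
                 control_map = as.integer(control_map)),
            class = "configuration")
}

#' The twelve preset control-segment configurations
#'
#' Ids 1--4 hold the control quadrant constant across z-bands (quadrants
#' 0--3); ids 5--8 advance it by one quadrant per band (ascending spiral);
#' ids 9--12 retreat by one per band (descending spiral). The true clinical
#' layouts are not published in recoverable form, so this enumeration is a
#' documented stand-in and can be replaced wholesale from a YAML file of
#' `{id:, control: [4 indices]}` entries.
#'
#' @param file Optional YAML file overriding the presets verbatim.
#' @return List of 12 (or user-supplied) [configuration()] objects.
#' @export
preset_configurations <- function(file = NULL) {
  if (!is.null(file)) {
    raw <- yaml::read_yaml(file)
    return(lapply(raw, function(cf) configuration(cf$id, unlist(cf$control))))
  }
  z <- 0:3
  cfgs <- c(
    lapply(0:3, function(b) configuration(b + 1, rep(b, 4))),
    lapply(0:3, function(b) configuration(b + 5, (b + z) %% 4)),
    lapply(0:3, function(b) configuration(b + 9, (b - z) %% 4))
  )
  cfgs
}

# Relative deviations of every present non-control cell from its band
# control. Returns the comparison data frame (0 rows when nothing
# comparable) plus which z-bands had a missing control.
segment_deviations <- function(table, config,
                               deviation = c("control", "symmetric")) {
  deviation <- match.arg(deviation)
  rows <- list()
  indeterminate <- integer(0)
  for (z in 0:3) {
    ctrl <- config$control_map[z + 1]
    fc <- table$mean_foi[ctrl + 1, z + 1]
    if (is.na(fc)) {
      indeterminate <- c(indeterminate, z)
      next
    }
    for (r in setdiff(0:3, ctrl)) {
      fs <- table$mean_foi[r + 1, z + 1]
      if (is.na(fs)) next
      dev <- if (deviation == "control") abs(fs - fc) / fc
             else abs(fs - fc) / ((fs + fc) / 2)
      rows[[length(rows) + 1]] <- data.frame(
        zband = z, radial = r, control = ctrl,
        f_segment = fs, f_control = fc, deviation = dev)
    }
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    data.frame(zband = integer(0), radial = integer(0), control = integer(0),
               f_segment = numeric(0), f_control = numeric(0),
               deviation = numeric(0))
  list(comparisons = comparisons, indeterminate_zbands = indeterminate)
}

#' Diagnose one breast under one configuration
#'
#' For each z-band whose control segment is present, every other present
#' segment is compared with the control; a relative deviation above
#' `tolerance` flags it. The breast is positive when at least one comparison
#' is flagged (at most 12 comparisons; fewer when segments are missing).
#' Z-bands with a missing control contribute no comparisons and are recorded
#' as indeterminate; a breast whose four controls are all missing is
#' indeterminate as a whole — an error by default, or `is_positive = NA`
#' with `on_indeterminate = "na"`.
#'
#' @param table A `segment_table` (typically from [average_tables()]).
#' @param config A [configuration()].
#' @param tolerance Relative-deviation threshold, `>= 0` (e.g. 0.34).
#' @param deviation `"control"` measures `|f_s - f_c| / f_c` (the default);
#'   `"symmetric"` divides by the pair mean instead.
#' @param on_indeterminate `"error"` or `"na"`.
#' @return An object of class `diagnosis_outcome`.
#' @export
diagnose <- function(table, config, tolerance = 0.34,
                     deviation = c("control", "symmetric"),
                     on_indeterminate = c("error", "na")) {
  stopifnot(inherits(table, "segment_table"), inherits(config, "configuration"))
  check_number(tolerance, "tolerance", lower = 0)
  on_indeterminate <- match.arg(on_indeterminate)
  sd_ <- segment_deviations(table, config, deviation)
  comparisons <- sd_$comparisons
  if (length(sd_$indeterminate_zbands) == 4L) {
    if (on_indeterminate == "error")
      stop_dietdx(sprintf(
        "breast %s is indeterminate under configuration %d: all four control segments missing",
        table$breast_id, config$id), "dietdx_indeterminate")
    is_positive <- NA
  } else {
    is_positive <- any(comparisons$deviation > tolerance)
  }
  comparisons$flagged <- comparisons$deviation > tolerance
  structure(
    list(breast_id = table$breast_id, configuration = config$id,
         tolerance = tolerance, comparisons = comparisons,
         n_comparisons = nrow(comparisons),
         flagged = comparisons[comparisons$flagged, , drop = FALSE],
         indeterminate_zbands = sd_$indeterminate_zbands,
         is_positive = is_positive),
    class = "diagnosis_outcome"
  )
}

#' @export
print.diagnosis_outcome <- function(x, ...) {
  cat(sprintf(
    "<diagnosis_outcome> %s, configuration %d, tolerance %.0f%%: %s (%d comparisons, %d flagged)\n",
    x$breast_id, x$configuration, 100 * x$tolerance,
    if (is.na(x$is_positive)) "indeterminate"
    else if (x$is_positive) "POSITIVE" else "negative",
    x$n_comparisons, nrow(x$flagged)))
  invisible(x)
}

#' Combine outcomes across configurations by OR
#'
#' Positive when any configuration is positive. Indeterminate outcomes are
#' ignored unless every outcome is indeterminate (then `NA`).
#'
#' @param outcomes Non-empty list of `diagnosis_outcome`s (or a logical
#'   vector of per-configuration calls, `NA` = indeterminate).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
combine_or <- function(outcomes) {
  if (length(outcomes) == 0L)
    stop_invalid("`outcomes` must be non-empty")
  pos <- if (is.list(outcomes))
    vapply(outcomes, function(o) o$is_positive, logical(1)) else outcomes
  if (all(is.na(pos))) return(NA)
  any(pos, na.rm = TRUE)
}

# Largest relative deviation of any comparison (NA when none are possible):
# the breast is positive at tolerance t iff max_deviation > t, which lets
# tolerance sweeps reuse one number per breast.
max_deviation <- function(table, config, deviation = "control") {
  d <- segment_deviations(table, config, deviation)$comparisons$deviation
  if (length(d) == 0L) NA_real_ else max(d)
}
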