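#' Per-cell medians of spike characteristics
#'
#' Exocytotic activity is heterogeneous across cells; to keep highly
#' active cells from dominating, the median of each characteristic over a
#' cell's spikes is used as that cell's single value — the statistical
#' unit `n` is the cell, not the spike. Medians use the conventional
#' mean-of-middle-two rule for even counts.
#'
#' @param events Event metric table (from [measure_events()] or a
#'   ground-truth schedule remapped to the same columns) with at least
#'   `channel` and the metric columns `i_max_pA`, `t_half_ms`, `q_fC`,
#'   `n_molecules`, `q_amol_cuberoot`.
#' @param cell_map Data frame mapping `channel` to `cell_id`. If `events`
#'   already carries `cell_id`, may be NULL.
#' @return Data frame, one row per cell: `cell_id`, `n_spikes`, and
#'   `median_` columns for each characteristic.
#' @export
summarize_cells <- function(events, cell_map = NULL) {
  ev <- as.data.frame(events)
  if (!is.null(cell_map)) {
    hit <- match(ev$channel, cell_map$channel)
    if (anyNA(hit)) {
      stop("events on channel(s) with no cell mapping: ",
           paste(sort(unique(ev$channel[is.na(hit)])), collapse = ", "))
    }
    ev$cell_id <- cell_map$cell_id[hit]
  }
  if (is.null(ev$cell_id)) stop("no `cell_id` available for events")
  if (nrow(ev) == 0) stop("no events to summarise")
  metrics <- c("i_max_pA", "t_half_ms", "q_fC", "n_molecules",
               "q_amol_cuberoot")
  metrics <- metrics[metrics %in% names(ev)]
  ev[metrics] <- lapply(ev[metrics], as.numeric)   # stable median type
  dt <- data.table::as.data.table(ev)
  out <- dt[, c(list(n_spikes = .N),
                lapply(.SD, stats::median)),
            by = "cell_id", .SDcols = metrics]
  data.table::setnames(out, metrics, paste0("median_", metrics))
  as.data.frame(out)
}

#' Percent change of a treated mean relative to control
#'
#' @param control_mean,treated_mean Group means; control must be nonzero.
#' @param rounded Round to the nearest integer percent, the convention
#'   used when reporting (default TRUE).
#' @return `100 * (treated - control) / control`.
#' @export
percent_change <- function(control_mean, treated_mean, rounded = TRUE) {
  if (any(control_mean == 0)) stop("control mean must be nonzero")
  p <- 100 * (treated_mean - control_mean) / control_mean
  if (rounded) round(p) else p
}

#' Two-group comparison of per-cell values
#'
#' Two-tailed Student's t test on per-cell medians, pooled-variance by
#' default (Welch available). Backed by [stats::t.test()].
#'
#' @param control,treated Numeric vectors of per-cell values (each of
#'   length >= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p`, `mean_control`, `mean_treated`.
#' @export
two_group_test <- function(control, treated,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(control) < 2 || length(treated) < 2) {
    stop("each group needs at least 2 cells")
  }
  if (stats::var(control) == 0 && stats::var(treated) == 0 &&
      mean(control) == mean(treated)) {
    return(list(t = 0, df = length(control) + length(treated) - 2, p = 1,
                mean_control = mean(control), mean_treated = mean(treated)))
  }
  tt <- stats::t.test(control, treated, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), mean_control = mean(control),
       mean_treated = mean(treated))
}

#' Gaussian fit of cube-root quantal size
#'
#' Vesicle diameters are Gaussian and quantal charge scales with diameter
#' cubed, so per-spike `Q^(1/3)` should be Gaussian. Fits by maximum
#' likelihood (sample mean and SD) and reports a descriptive
#' Kolmogorov-Smirnov p-value against the fitted Gaussian (parameters are
#' estimated from the same data, so the p-value is indicative, not exact).
#'
#' @param q_cuberoot Per-spike cube-root quantal sizes (attomole^(1/3)),
#'   length >= 8.
#' @return List with `mean`, `sd`, `normality_p`; warns when the fit is
#'   degenerate (zero variance).
#' @export
fit_cuberoot_gaussian <- function(q_cuberoot) {
  if (length(q_cuberoot) < 8) stop("need at least 8 spikes for the fit")
  m <- mean(q_cuberoot)
  s <- stats::sd(q_cuberoot) * sqrt((length(q_cuberoot) - 1) /
                                      length(q_cuberoot))   # MLE
  if (s == 0) {
    warning("degenerate Gaussian fit: zero variance")
    return(list(mean = m, sd = 0, normality_p = NA_real_))
  }
  ks <- suppressWarnings(stats::ks.test(q_cuberoot, "pnorm", m, s))
  list(mean = m, sd = s, normality_p = unname(ks$p.value))
}

#' Box-plot statistics in the quartile-to-extreme convention
#'
#' Quartiles use linear interpolation (quantile type 7); whiskers are
#' drawn from the quartiles to the extreme values (no 1.5 IQR fencing).
#'
#' @param x Numeric vector.
#' @return List with `min`, `q1`, `median`, `q3`, `max`.
#' @export
boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x))
}

#' Full two-group quantal-release comparison report
#'
#' For each spike characteristic: group means over per-cell medians,
#' percent change, two-tailed t test on the cell medians, per-spike
#' histograms, and quartile box statistics; plus a Gaussian fit of the
#' per-spike cube-root quantal size in each group.
#'
#' @param control_events,treated_events Event metric tables.
#' @param control_cells,treated_cells Optional channel -> cell maps (NULL
#'   if the events already carry `cell_id`).
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @param bins Histogram bin count (default 30).
#' @return An object of class `group_comparison`: list with `n_control`,
#'   `n_treated` (cells), `characteristics` (per-metric stats), and
#'   `cuberoot_fit` per group.
#' @export
group_report <- function(control_events, treated_events,
                         control_cells = NULL, treated_cells = NULL,
                         variant = "pooled", bins = 30) {
  if (nrow(control_events) == 0 || nrow(treated_events) == 0) {
    stop("both groups must contain events")
  }
  cs <- summarize_cells(control_events, control_cells)
  ts <- summarize_cells(treated_events, treated_cells)
  metrics <- c(i_max_pA = "i_max", t_half_ms = "t_half", q_fC = "q",
               n_molecules = "n_molecules",
               q_amol_cuberoot = "q_cuberoot")
  characteristics <- list()
  for (col in names(metrics)) {
    med <- paste0("median_", col)
    if (!med %in% names(cs)) next
    test <- two_group_test(cs[[med]], ts[[med]], variant)
    all_vals <- c(control_events[[col]], treated_events[[col]])
    edges <- seq(min(all_vals), max(all_vals), length.out = bins + 1)
    characteristics[[metrics[[col]]]] <- list(
      mean_control = test$mean_control,
      mean_treated = test$mean_treated,
      percent_change = percent_change(test$mean_control,
                                      test$mean_treated),
      t = test$t, df = test$df, p = test$p,
      box_control = boxplot_stats(cs[[med]]),
      box_treated = boxplot_stats(ts[[med]]),
      hist = list(
        breaks = edges,
        counts_control = graphics::hist(control_events[[col]],
                                        breaks = edges,
                                        plot = FALSE)$counts,
        counts_treated = graphics::hist(treated_events[[col]],
                                        breaks = edges,
                                        plot = FALSE)$counts
      )
    )
  }
  fit <- list(
    control = if (nrow(control_events) >= 8)
      fit_cuberoot_gaussian(control_events$q_amol_cuberoot) else NULL,
    treated = if (nrow(treated_events) >= 8)
      fit_cuberoot_gaussian(treated_events$q_amol_cuberoot) else NULL
  )
  structure(list(n_control = nrow(cs), n_treated = nrow(ts),
                 n_spikes_control = nrow(control_events),
                 n_spikes_treated = nrow(treated_events),
                 characteristics = characteristics,
                 cuberoot_fit = fit,
                 cell_summaries = list(control = cs, treated = ts)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d control vs %d treated cells (%d / %d spikes)\n",
              x$n_control, x$n_treated, x$n_spikes_control,
              x$n_spikes_treated))
  for (nm in names(x$characteristics)) {
    ch <- x$characteristics[[nm]]
    cat(sprintf("  %-11s %8.3g -> %8.3g  (%+d%%)  t=%.2f, p=%.3g\n",
                nm, ch$mean_control, ch$mean_treated, ch$percent_change,
                ch$t, ch$p))
  }
  invisible(x)
}

#' Write a group comparison as JSON
#'
#' @param x A `group_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_report <- function(x, path) {
  out <- unclass(x)
  out$cell_summaries <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
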