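# Index aggregation: weighted means of scaled simulations over any scope,
# with median, 95% CI, simulation-based p-values, trend series and
# documentation-gap diagnostics.

#' Compute the index for one scope and date
#'
#' For each Monte-Carlo replicate s, the index is the weighted sum of the
#' scaled values of all documented cells in scope,
#' `NI(s) = sum W_ijkt * s_ijkt(s)`, with weights from
#' [build_weight_table()] (renormalized over documented cells). The result
#' is summarized as the median of the `n` simulated index values with a 95%
#' confidence interval given by the 2.5% and 97.5% quantiles
#' (linear-interpolation quantiles, [stats::quantile()] type 7).
#'
#' @param scaled an `ni_scaled` object covering all cells in scope.
#' @param dataset the [ni_dataset()].
#' @param scope an [ni_scope()].
#' @param date single study date.
#' @param weights optional precomputed `ni_weights` table (e.g. a thematic
#'   mask); built from `dataset`, `scope` and `date` when omitted.
#' @return object of class `ni_index`: list with `scope`, `date`, `sims`
#'   (the n index draws), `median`, `ci_low`, `ci_high`, `n_documented`,
#'   `source_counts` (monitoring/model/expert) and `weight_deficit` (weight
#'   lost to undocumented cells before renormalization).
#' @export
compute_index <- function(scaled, dataset, scope = ni_scope(), date,
                          weights = NULL) {
  stopifnot(inherits(scaled, "ni_scaled"), inherits(dataset, "ni_dataset"))
  if (is.null(weights))
    weights <- build_weight_table(dataset, scope, date)
  ids <- cell_id(weights$indicator_id, weights$ecosystem_id,
                 weights$unit_id, weights$date)
  rows <- match(ids, rownames(scaled$values))
  if (anyNA(rows))
    stop("scaled simulations missing for weighted cell ",
         .cell_label(weights$indicator_id[which(is.na(rows))[1]],
                     weights$ecosystem_id[which(is.na(rows))[1]],
                     weights$unit_id[which(is.na(rows))[1]], date),
         call. = FALSE)
  sims <- drop(crossprod(scaled$values[rows, , drop = FALSE],
                         weights$weight))
  qs <- stats::quantile(sims, c(0.025, 0.975), names = FALSE, type = 7)
  rec <- dataset$records
  rid <- cell_id(rec$indicator_id, rec$ecosystem_id, rec$unit_id, rec$date)
  src <- table(factor(rec$source[match(ids, rid)], .SOURCE_LEVELS))
  structure(list(scope = attr(weights, "scope"), date = date, sims = sims,
                 median = stats::median(sims), ci_low = qs[1],
                 ci_high = qs[2], n_documented = nrow(weights),
                 source_counts = c(src),
                 weight_deficit = attr(weights, "deficit")),
            class = "ni_index")
}

#' @export
print.ni_index <- function(x, ...) {
  cat(sprintf(
    "index at %s: median %.3f  95%% CI [%.3f, %.3f]  (%d cells, n=%d)\n",
    format(x$date), x$median, x$ci_low, x$ci_high, x$n_documented,
    length(x$sims)))
  invisible(x)
}

#' Simulation-based comparison of two dates
#'
#' One-sided p-value for "the index at the first date exceeds the second":
#' the fraction of replicates with `NI_t1(s) > NI_t2(s)`, ties counted as
#' one half (which makes the null p symmetric around 0.5). The two-sided
#' p-value is `2 * min(p, 1 - p)` capped at 1; values below the simulation
#' resolution 1/n are reported as such, not as exactly zero probability.
#'
#' @param res1,res2 `ni_index` results with identical scope and the same
#'   number of replicates.
#' @return object of class `ni_comparison`: `dates`, `p_one_sided`,
#'   `p_two_sided`, `median_difference` (first minus second), `n`.
#' @export
compare_dates <- function(res1, res2) {
  stopifnot(inherits(res1, "ni_index"), inherits(res2, "ni_index"))
  if (!identical(res1$scope, res2$scope))
    stop("index results have different scopes", call. = FALSE)
  n <- length(res1$sims)
  if (n != length(res2$sims))
    stop("index results have different numbers of replicates",
         call. = FALSE)
  p1 <- (sum(res1$sims > res2$sims) + 0.5 * sum(res1$sims == res2$sims)) / n
  structure(list(dates = c(res1$date, res2$date), p_one_sided = p1,
                 p_two_sided = min(1, 2 * min(p1, 1 - p1)),
                 median_difference = res1$median - res2$median, n = n),
            class = "ni_comparison")
}

#' @export
print.ni_comparison <- function(x, ...) {
  p2 <- if (x$p_two_sided < 1 / x$n)
    sprintf("< %.4g", 1 / x$n) else sprintf("%.4g", x$p_two_sided)
  cat(sprintf(
    "comparison %s vs %s: diff of medians %+0.4f, one-sided p = %.4g, two-sided p %s\n",
    format(x$dates[1]), format(x$dates[2]), x$median_difference,
    x$p_one_sided, p2))
  invisible(x)
}

#' Index trend over several dates
#'
#' One [compute_index()] result per date under a constant scope; a date with
#' no documented cell in scope becomes a flagged gap entry rather than a
#' failure, preserving the length of the series.
#'
#' @param scaled an `ni_scaled` object.
#' @param dataset the [ni_dataset()].
#' @param scope an [ni_scope()].
#' @param dates integer vector of dates; defaults to the dataset's dates.
#' @return object of class `ni_trend`: list of `ni_index` entries and gap
#'   markers, with an `as.data.frame` method.
#' @export
trend_series <- function(scaled, dataset, scope = ni_scope(),
                         dates = dataset$dates) {
  res <- lapply(dates, function(t)
    tryCatch(compute_index(scaled, dataset, scope, t),
             error = function(e) list(date = t, gap = TRUE,
                                      message = conditionMessage(e))))
  structure(res, dates = dates, scope = scope, class = "ni_trend")
}

#' @export
as.data.frame.ni_trend <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    if (isTRUE(r$gap))
      data.frame(date = r$date, median = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n_documented = 0L,
                 monitoring = NA_integer_, model = NA_integer_,
                 expert = NA_integer_, gap = TRUE)
    else
      data.frame(date = r$date, median = r$median, ci_low = r$ci_low,
                 ci_high = r$ci_high, n_documented = r$n_documented,
                 monitoring = r$source_counts[["monitoring"]],
                 model = r$source_counts[["model"]],
                 expert = r$source_counts[["expert"]], gap = FALSE)
  }))
}

#' @export
print.ni_trend <- function(x, ...) {
  cat("index trend:\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.ni_trend <- function(x, ylim = c(0, 1), xlab = "date",
                          ylab = "index", ...) {
  df <- as.data.frame(x)
  graphics::plot(df$date, df$median, type = "b", pch = 16, ylim = ylim,
                 xlab = xlab, ylab = ylab, ...)
  graphics::arrows(df$date, df$ci_low, df$date, df$ci_high, angle = 90,
                   code = 3, length = 0.04, col = "grey40")
  invisible(df)
}

#' Filter spatial units by ecosystem share
#'
#' Selects units where an ecosystem covers at least a given fraction of the
#' total area — e.g. restricting a mountain index to municipalities that are
#' at least 20% mountain.
#'
#' @param units spatial-unit table (or an `ni_dataset`).
#' @param ecosystem_id the ecosystem.
#' @param threshold minimum area fraction in \[0, 1\] (default 0.2).
#' @return character vector of unit ids.
#' @export
mountain_filter <- function(units, ecosystem_id, threshold = 0.2) {
  if (inherits(units, "ni_dataset")) units <- units$units
  stopifnot(threshold >= 0, threshold <= 1)
  u <- units[units$ecosystem_id == ecosystem_id, ]
  frac <- u$ecosystem_area / u$total_area
  all_units <- unique(units$unit_id)
  sel <- u$unit_id[frac >= threshold]
  if (threshold == 0) all_units else sel
}

#' Documentation-gap statistics
#'
#' Quantifies lack of knowledge: for each (ecosystem, date, source), the
#' mean over relevant spatial units (those where the ecosystem is present)
#' of the number of documented indicators — units with no documentation
#' count as zero. Also reports the share of expert-judgment records per
#' ecosystem, the data-source uncertainty diagnostic.
#'
#' @param dataset an [ni_dataset()].
#' @return object of class `ni_gaps`: list with `mean_documented` (data
#'   frame `ecosystem_id`, `date`, `source`, `mean_count`) and
#'   `expert_share` (data frame `ecosystem_id`, `n_records`,
#'   `expert_pct`).
#' @export
gap_statistics <- function(dataset) {
  stopifnot(inherits(dataset, "ni_dataset"))
  rec <- dataset$records
  pres <- dataset$units[dataset$units$ecosystem_area > 0,
                        c("unit_id", "ecosystem_id")]
  n_units <- tapply(pres$unit_id, pres$ecosystem_id,
                    function(u) length(unique(u)))
  grid <- expand.grid(ecosystem_id = sort(unique(pres$ecosystem_id)),
                      date = dataset$dates, source = .SOURCE_LEVELS,
                      stringsAsFactors = FALSE)
  if (nrow(rec)) {
    key <- paste(rec$ecosystem_id, rec$date, rec$source, sep = .CELL_SEP)
    counts <- tapply(rec$indicator_id, key, length)
    gkey <- paste(grid$ecosystem_id, grid$date, grid$source, sep = .CELL_SEP)
    tot <- counts[match(gkey, names(counts))]
    tot[is.na(tot)] <- 0
  } else tot <- rep(0, nrow(grid))
  grid$mean_count <- as.numeric(tot) / as.numeric(n_units[grid$ecosystem_id])
  grid <- grid[order(grid$ecosystem_id, grid$date, grid$source), ]
  rownames(grid) <- NULL

  if (nrow(rec)) {
    n_rec <- tapply(rec$source, rec$ecosystem_id, length)
    n_exp <- tapply(rec$source == "expert", rec$ecosystem_id, sum)
    share <- data.frame(ecosystem_id = names(n_rec),
                        n_records = as.integer(n_rec),
                        expert_pct = 100 * as.numeric(n_exp) /
                          as.numeric(n_rec), row.names = NULL)
  } else {
    share <- data.frame(ecosystem_id = character(), n_records = integer(),
                        expert_pct = numeric())
  }
  structure(list(mean_documented = grid, expert_share = share),
            class = "ni_gaps")
}

#' @export
print.ni_gaps <- function(x, ...) {
  cat("mean documented indicators per unit (ecosystem x date x source):\n")
  print(x$mean_documented, row.names = FALSE)
  cat("\nexpert-judgment share per ecosystem:\n")
  print(x$expert_share, row.names = FALSE)
  invisible(x)
}

#' Full pipeline: elicitation table to index trend
#'
#' Convenience wrapper chaining [fit_dataset()], [draw_replicates()],
#' [scale_dataset()] and [trend_series()].
#'
#' @param dataset an [ni_dataset()].
#' @param scope an [ni_scope()].
#' @param dates dates to compute; defaults to the dataset's dates.
#' @param n_sim Monte-Carlo replicates per cell (default 999).
#' @param seed master RNG seed.
#' @return an `ni_trend`; the scaled simulations are attached as attribute
#'   `scaled` for reuse (e.g. in [compare_dates()] via [compute_index()]).
#' @examples
#' ds <- generate_dataset(ni_generator_config(seed = 42))$dataset
#' tr <- nature_index(ds, n_sim = 199, seed = 1)
#' as.data.frame(tr)
#' @export
nature_index <- function(dataset, scope = ni_scope(), dates = dataset$dates,
                         n_sim = 999, seed = 1) {
  fits <- fit_dataset(dataset)
  sims <- draw_replicates(fits, n_sim = n_sim, seed = seed)
  scaled <- scale_dataset(sims, dataset)
  out <- trend_series(scaled, dataset, scope, dates)
  attr(out, "scaled") <- scaled
  out
}
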