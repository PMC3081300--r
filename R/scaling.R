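# Scaling of simulated observations against reference states.
#
# A scaled value lies in [0, 1]: 0 is a completely degraded situation, 1 the
# reference (optimal) situation.  Three models cover the ways experts
# interpret a reference value r:
#   minimal  — degradation only below r (precautionary level):  min(x/r, 1)
#   maximal  — degradation only above r (proliferation limit):  min(r/x, 1)
#   optimal  — degradation on both sides:  min of the two, so the value is 1
#              exactly at x = r and decays hyperbolically above.

#' Scale an observation against its reference state
#'
#' @param x non-negative observed (or simulated) value(s), natural units.
#' @param r positive reference value(s), recycled against `x`.
#' @param model `"optimal"`, `"minimal"` or `"maximal"` (scalar or
#'   recycled).
#' @return values in \[0, 1\]. Under `maximal`, `x = 0` maps to 1: a value
#'   at or below the proliferation threshold is not penalized.
#' @examples
#' scale_value(25, 50, "minimal")   # 0.5
#' scale_value(150, 50, "maximal")  # 1/3
#' scale_value(50, 50, "optimal")   # 1
#' @export
scale_value <- function(x, r, model) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("observed values must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("reference values must be finite and positive", call. = FALSE)
  if (any(!model %in% .SCALING_MODELS))
    stop("unknown scaling model: ",
         paste(setdiff(unique(model), .SCALING_MODELS), collapse = ", "),
         call. = FALSE)
  n <- max(length(x), length(r), length(model))
  x <- rep_len(x, n); r <- rep_len(r, n); model <- rep_len(model, n)
  below <- pmin(x / r, 1)                    # minimal
  above <- ifelse(x <= r, 1, r / x)          # maximal
  out <- ifelse(model == "minimal", below,
                ifelse(model == "maximal", above, pmin(below, above)))
  pmin(pmax(out, 0), 1)
}

#' Scale a full set of simulated values
#'
#' Applies [scale_value()] element-wise to every simulated vector, using the
#' reference value and scaling model declared for each cell's (indicator,
#' ecosystem, unit) in the reference table. Shape is preserved: one row per
#' documented cell, `n_sim` columns.
#'
#' @param sims an `ni_sims` object from [draw_replicates()].
#' @param dataset the [ni_dataset()] supplying the reference table.
#' @return object of class `ni_scaled` with elements `cells`, `values`
#'   (matrix in \[0, 1\]), `n_sim`, `seed`.
#' @export
scale_dataset <- function(sims, dataset) {
  stopifnot(inherits(sims, "ni_sims"), inherits(dataset, "ni_dataset"))
  refs <- dataset$references
  rkey <- paste(refs$indicator_id, refs$ecosystem_id, refs$unit_id,
                sep = .CELL_SEP)
  m <- match(paste(sims$cells$indicator_id, sims$cells$ecosystem_id,
                   sims$cells$unit_id, sep = .CELL_SEP), rkey)
  if (anyNA(m)) {
    i <- which(is.na(m))[1]
    stop("missing reference state for simulated cell ",
         .cell_label(sims$cells$indicator_id[i], sims$cells$ecosystem_id[i],
                     sims$cells$unit_id[i], sims$cells$date[i]),
         call. = FALSE)
  }
  r <- refs$ref_value[m]
  model <- refs$scaling_model[m]
  vals <- sims$values
  for (i in seq_len(nrow(vals)))
    vals[i, ] <- scale_value(vals[i, ], r[i], model[i])
  structure(list(cells = sims$cells, values = vals, n_sim = sims$n_sim,
                 seed = sims$seed),
            class = "ni_scaled")
}

#' @export
print.ni_scaled <- function(x, ...) {
  cat(sprintf("ni_scaled: %d cells x %d replicates, values in [%.3f, %.3f]\n",
              nrow(x$values), x$n_sim, min(x$values), max(x$values)))
  invisible(x)
}

#' Per-cell summary of scaled simulations
#'
#' Convenience export for inspection: median and quartiles of each cell's
#' scaled vector.
#'
#' @param scaled an `ni_scaled` object.
#' @return data frame with cell keys and `q25`, `median`, `q75`.
#' @export
summarize_scaled <- function(scaled) {
  stopifnot(inherits(scaled, "ni_scaled"))
  qs <- t(apply(scaled$values, 1, stats::quantile,
                probs = c(0.25, 0.5, 0.75), names = FALSE))
  cbind(scaled$cells[, c("indicator_id", "ecosystem_id", "unit_id", "date")],
        data.frame(q25 = qs[, 1], median = qs[, 2], q75 = qs[, 3]))
}
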