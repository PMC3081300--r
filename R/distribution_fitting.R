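# Distribution fitting from an elicited (mean, q25, q75) triple.
#
# Each documented observation carries three numbers elicited from an expert:
# the mean and the lower/upper quartiles.  A two-parameter family L(a, b) is
# chosen by minimizing the discrepancy criterion
#     C = m^2 + q_l^2 + q_u^2,
# where m, q_l and q_u are the deviations of the fitted expectation and
# quartiles from the elicited values.  Candidate families are
# truncated-normal (at 0), Gumbel, log-normal, Weibull and gamma for
# continuous variables, and Poisson, zero-inflated Poisson and negative
# binomial for discrete ones.  Monte-Carlo replicates of the elicitation are
# then drawn from the retained family.

.EULER_GAMMA <- 0.5772156649015329
.CONT_FAMILIES <- c("truncated_normal", "gumbel", "lognormal", "weibull",
                    "gamma")
.DISC_FAMILIES <- c("poisson", "zip", "negbinom")

#' Discrepancy criterion for a candidate distribution
#'
#' Combines the deviation of the fitted expectation from the elicited mean
#' (`m`) and the deviations of the fitted lower/upper quartiles from the
#' elicited quartiles (`q_l`, `q_u`) into the scalar minimized during family
#' selection: the sum of squared deviations. The combination rule is
#' isolated here so an alternative (e.g. absolute deviations) is a one-line
#' change.
#'
#' @param m,q_l,q_u finite deviations (elicited minus fitted).
#' @return non-negative scalar; zero iff all three deviations vanish.
#' @examples
#' criterion_c(0, 0, 0)   # 0
#' criterion_c(1, 2, 2)   # 9
#' @export
criterion_c <- function(m, q_l, q_u) {
  stopifnot(is.finite(m), is.finite(q_l), is.finite(q_u))
  m^2 + q_l^2 + q_u^2
}

# -- continuous family primitives ------------------------------------------
# Each family: natural parameters (a, b); expectation, quartile and sampler.
# Parameters are optimized on an unconstrained scale (log for positives).

.tn_mills <- function(alpha)
  exp(stats::dnorm(alpha, log = TRUE) -
        stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))

.cont_spec <- list(
  truncated_normal = list(
    to_nat = function(th) c(th[1], exp(th[2])),
    to_opt = function(p) c(p[1], log(p[2])),
    expectation = function(p) p[1] + p[2] * .tn_mills(-p[1] / p[2]),
    quantile = function(q, p) {
      Fa <- stats::pnorm(-p[1] / p[2])
      p[1] + p[2] * stats::qnorm(Fa + q * (1 - Fa))
    },
    draw = function(n, p) {
      Fa <- stats::pnorm(-p[1] / p[2])
      p[1] + p[2] * stats::qnorm(stats::runif(n, Fa, 1))
    },
    starts = function(m, ql, qu) {
      s0 <- max((qu - ql) / 1.349, m / 4, 1e-3)
      list(c(m, log(s0)), c((ql + qu) / 2, log(s0)), c(m / 2, log(2 * s0)))
    }),
  gumbel = list(
    to_nat = function(th) c(th[1], exp(th[2])),
    to_opt = function(p) c(p[1], log(p[2])),
    expectation = function(p) p[1] + p[2] * .EULER_GAMMA,
    quantile = function(q, p) p[1] - p[2] * log(-log(q)),
    draw = function(n, p) p[1] - p[2] * log(-log(stats::runif(n))),
    starts = function(m, ql, qu) {
      b0 <- max((qu - ql) / 1.5725, 1e-3)
      list(c(m - .EULER_GAMMA * b0, log(b0)),
           c(ql + 0.3266 * b0, log(b0)))
    }),
  lognormal = list(
    to_nat = function(th) c(th[1], exp(th[2])),
    to_opt = function(p) c(p[1], log(p[2])),
    expectation = function(p) exp(p[1] + p[2]^2 / 2),
    quantile = function(q, p) stats::qlnorm(q, p[1], p[2]),
    draw = function(n, p) stats::rlnorm(n, p[1], p[2]),
    starts = function(m, ql, qu) {
      s0 <- if (ql > 0 && qu > ql) log(qu / ql) / 1.349 else 0.5
      s0 <- min(max(s0, 1e-3), 3)
      mu_m <- log(max(m, 1e-6)) - s0^2 / 2
      mu_q <- if (ql > 0) log(sqrt(ql * qu)) else mu_m
      list(c(mu_m, log(s0)), c(mu_q, log(s0)))
    }),
  weibull = list(
    to_nat = function(th) exp(th),
    to_opt = function(p) log(p),
    expectation = function(p) p[2] * gamma(1 + 1 / p[1]),
    quantile = function(q, p) stats::qweibull(q, p[1], p[2]),
    draw = function(n, p) stats::rweibull(n, p[1], p[2]),
    starts = function(m, ql, qu) {
      k0 <- if (ql > 0 && qu > ql)
        log(log(4) / log(4 / 3)) / log(qu / ql) else 2
      k0 <- min(max(k0, 0.1), 50)
      sc <- max(qu, m, 1e-6) / log(4)^(1 / k0)
      list(log(c(k0, sc)), log(c(max(1, k0 / 2), max(m, 1e-6))))
    }),
  gamma = list(
    to_nat = function(th) exp(th),
    to_opt = function(p) log(p),
    expectation = function(p) p[1] / p[2],
    quantile = function(q, p) stats::qgamma(q, p[1], p[2]),
    draw = function(n, p) stats::rgamma(n, p[1], p[2]),
    starts = function(m, ql, qu) {
      sd0 <- max((qu - ql) / 1.349, m / 10, 1e-4)
      sh0 <- min(max((max(m, 1e-6) / sd0)^2, 1e-2), 1e5)
      list(log(c(sh0, sh0 / max(m, 1e-6))),
           log(c(sh0 / 3, sh0 / 3 / max(m, 1e-6))),
           log(c(sh0 * 3, sh0 * 3 / max(m, 1e-6))))
    })
)

.fit_one_continuous <- function(fam, m, ql, qu) {
  sp <- .cont_spec[[fam]]
  obj <- function(th) {
    p <- sp$to_nat(th)
    if (any(!is.finite(p))) return(1e12)
    e <- sp$expectation(p)
    lo <- sp$quantile(0.25, p)
    hi <- sp$quantile(0.75, p)
    if (!is.finite(e) || !is.finite(lo) || !is.finite(hi)) return(1e12)
    (m - e)^2 + (ql - lo)^2 + (qu - hi)^2
  }
  starts <- sp$starts(m, ql, qu)
  best <- list(par = starts[[1]], value = obj(starts[[1]]))
  for (th0 in starts) {
    o <- tryCatch(stats::optim(th0, obj, method = "Nelder-Mead",
                               control = list(maxit = 500, reltol = 1e-13)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best$value) best <- o
  }
  # polish from the incumbent
  o <- tryCatch(stats::optim(best$par, obj, method = "Nelder-Mead",
                             control = list(maxit = 500, reltol = 1e-13)),
                error = function(e) NULL)
  if (!is.null(o) && o$value < best$value) best <- o
  p <- sp$to_nat(best$par)
  list(family = fam, a = p[1], b = p[2],
       m = m - sp$expectation(p),
       q_l = ql - sp$quantile(0.25, p),
       q_u = qu - sp$quantile(0.75, p))
}

# -- discrete families ------------------------------------------------------
# Quartiles follow the type-1 convention (smallest k with CDF >= p), which is
# what the base q-functions return.  C is piecewise smooth in the parameters
# (quartiles jump), so fitting is done by staged grid search with an exact
# interior candidate for the mean term.

.zip_quantile <- function(q, pi0, lam) {
  p <- pmin(pmax((q - pi0) / (1 - pi0), 0), 1)
  ifelse(q <= pi0, 0, stats::qpois(p, lam))
}

.fit_poisson <- function(m, ql, qu) {
  top <- max(3 * max(m, qu, 1), 2)
  lam <- c(seq(1e-8, top, length.out = 4001), if (m > 0) m)
  C <- (m - lam)^2 + (ql - stats::qpois(0.25, lam))^2 +
    (qu - stats::qpois(0.75, lam))^2
  b <- lam[which.min(C)]
  step <- top / 4000
  lam2 <- unique(pmax(seq(b - step, b + step, length.out = 801), 1e-8))
  C2 <- (m - lam2)^2 + (ql - stats::qpois(0.25, lam2))^2 +
    (qu - stats::qpois(0.75, lam2))^2
  i <- which.min(C2)
  list(family = "poisson", a = lam2[i], b = NA_real_,
       m = m - lam2[i], q_l = ql - stats::qpois(0.25, lam2[i]),
       q_u = qu - stats::qpois(0.75, lam2[i]))
}

.zip_grid <- function(m, ql, qu, pis, lams) {
  g <- expand.grid(pi0 = pis, lam = lams)
  C <- (m - (1 - g$pi0) * g$lam)^2 +
    (ql - .zip_quantile(0.25, g$pi0, g$lam))^2 +
    (qu - .zip_quantile(0.75, g$pi0, g$lam))^2
  g[which.min(C), ]
}

.fit_zip <- function(m, ql, qu) {
  top <- max(3 * max(m, qu, 1), 2)
  b <- .zip_grid(m, ql, qu, seq(0, 0.98, length.out = 99),
                 seq(1e-8, top, length.out = 400))
  b <- .zip_grid(m, ql, qu,
                 seq(max(0, b$pi0 - 0.0102), min(0.999, b$pi0 + 0.0102),
                     length.out = 83),
                 pmax(seq(b$lam - top / 399, b$lam + top / 399,
                          length.out = 161), 1e-8))
  # the global optimum often sits on the exact-mean curve lambda =
  # m / (1 - pi), where only the quartile terms vary; scan it densely
  if (m > 0) {
    pis <- seq(0, 0.9995, length.out = 4000)
    lams <- m / (1 - pis)
    Cc <- (ql - .zip_quantile(0.25, pis, lams))^2 +
      (qu - .zip_quantile(0.75, pis, lams))^2
    i <- which.min(Cc)
    Cb <- (m - (1 - b$pi0) * b$lam)^2 +
      (ql - .zip_quantile(0.25, b$pi0, b$lam))^2 +
      (qu - .zip_quantile(0.75, b$pi0, b$lam))^2
    if (Cc[i] < Cb) b <- data.frame(pi0 = pis[i], lam = lams[i])
  }
  list(family = "zip", a = b$pi0, b = b$lam,
       m = m - (1 - b$pi0) * b$lam,
       q_l = ql - .zip_quantile(0.25, b$pi0, b$lam),
       q_u = qu - .zip_quantile(0.75, b$pi0, b$lam))
}

.nb_grid <- function(m, ql, qu, sizes, mus) {
  g <- expand.grid(size = sizes, mu = mus)
  C <- (m - g$mu)^2 +
    (ql - stats::qnbinom(0.25, size = g$size, mu = g$mu))^2 +
    (qu - stats::qnbinom(0.75, size = g$size, mu = g$mu))^2
  g[which.min(C), ]
}

.fit_negbinom <- function(m, ql, qu) {
  M <- max(m, (ql + qu) / 2, 0.5)
  sizes <- 10^seq(log10(0.02), 3, length.out = 120)
  mus <- seq(max(M / 4, 1e-8), 3 * M, length.out = 200)
  b <- .nb_grid(m, ql, qu, sizes, mus)
  b <- .nb_grid(m, ql, qu,
                10^seq(log10(b$size) - 0.05, log10(b$size) + 0.05,
                       length.out = 41),
                pmax(seq(b$mu - 3 * M / 199, b$mu + 3 * M / 199,
                         length.out = 81), 1e-8))
  if (m > 0) {
    # scan the exact-mean curve mu = m over a dense size grid, then refine
    sz <- 10^seq(log10(0.02), 3, length.out = 4000)
    Cc <- (ql - stats::qnbinom(0.25, size = sz, mu = m))^2 +
      (qu - stats::qnbinom(0.75, size = sz, mu = m))^2
    i <- which.min(Cc)
    cand <- .nb_grid(m, ql, qu,
                     10^seq(log10(sz[i]) - 0.002, log10(sz[i]) + 0.002,
                            length.out = 21),
                     pmax(seq(m * 0.98, m * 1.02, length.out = 41), 1e-8))
    Cc2 <- (m - cand$mu)^2 +
      (ql - stats::qnbinom(0.25, size = cand$size, mu = cand$mu))^2 +
      (qu - stats::qnbinom(0.75, size = cand$size, mu = cand$mu))^2
    Cb <- (m - b$mu)^2 +
      (ql - stats::qnbinom(0.25, size = b$size, mu = b$mu))^2 +
      (qu - stats::qnbinom(0.75, size = b$size, mu = b$mu))^2
    if (Cc2 < Cb) b <- cand
  }
  list(family = "negbinom", a = b$size, b = b$mu,
       m = m - b$mu,
       q_l = ql - stats::qnbinom(0.25, size = b$size, mu = b$mu),
       q_u = qu - stats::qnbinom(0.75, size = b$size, mu = b$mu))
}

.point_mass_fit <- function(v)
  list(family = "point_mass", a = v, b = NA_real_, C_value = 0,
       m = 0, q_l = 0, q_u = 0)

.select_fit <- function(fits) {
  # fixed candidate order breaks exact ties (within 1e-12)
  Cs <- vapply(fits, function(f) criterion_c(f$m, f$q_l, f$q_u), numeric(1))
  best <- which(Cs <= min(Cs) + 1e-12)[1]
  out <- fits[[best]]
  out$C_value <- Cs[best]
  out
}

.fit_continuous_norm <- function(m, ql, qu) {
  .select_fit(lapply(.CONT_FAMILIES, .fit_one_continuous, m = m, ql = ql,
                     qu = qu))
}

#' Fit a statistical distribution to an elicited triple
#'
#' Selects, among the candidate two-parameter families for the variable
#' kind, the distribution whose expectation and quartiles best match the
#' elicited mean and quartiles in the least-squares sense of
#' [criterion_c()]. Continuous candidates: truncated normal (at zero),
#' Gumbel, log-normal, Weibull, gamma. Discrete candidates: Poisson,
#' zero-inflated Poisson, negative binomial. A fully degenerate elicitation
#' (`q25 == q75 == mean`) is represented as a point mass.
#'
#' Continuous optimization runs multi-start Nelder-Mead from
#' moment/quantile-matching starting values on a mean-normalized copy of the
#' triple (all five continuous families are scale families, so parameters
#' rescale exactly). Discrete fitting uses staged grid search because the
#' type-1 quartiles are step functions of the parameters.
#'
#' @param mean_value,q25,q75 non-negative elicited values with
#'   `q25 <= q75`.
#' @param variable_kind `"continuous"` or `"discrete"`.
#' @return object of class `ni_fit`: list with `family`, parameters `a`
#'   and `b` (`b` is `NA` for one-parameter families; for `zip`, `a` is the
#'   zero-inflation probability and `b` the Poisson rate; for `negbinom`,
#'   `a` is the size and `b` the mean), criterion value `C_value` and the
#'   deviations `m`, `q_l`, `q_u` (elicited minus fitted).
#' @examples
#' fit_distribution(2, 1, 3, "discrete")      # Poisson(2), C = 0
#' fit_distribution(100, 93.3, 106.7, "continuous")
#' @export
fit_distribution <- function(mean_value, q25, q75,
                             variable_kind = c("continuous", "discrete")) {
  variable_kind <- match.arg(variable_kind)
  if (!all(is.finite(c(mean_value, q25, q75))))
    stop("elicited values must be finite", call. = FALSE)
  if (min(mean_value, q25, q75) < 0)
    stop("elicited values must be non-negative", call. = FALSE)
  if (q25 > q75) stop("q25 must not exceed q75", call. = FALSE)

  if (q25 == q75 && q25 == mean_value)
    return(structure(.point_mass_fit(mean_value), class = "ni_fit"))

  if (variable_kind == "discrete") {
    fit <- .select_fit(list(.fit_poisson(mean_value, q25, q75),
                            .fit_zip(mean_value, q25, q75),
                            .fit_negbinom(mean_value, q25, q75)))
    return(structure(fit, class = "ni_fit"))
  }

  s0 <- if (mean_value > 0) mean_value else q75
  if (s0 == 0)  # mean = q75 = 0, q25 = 0 handled above
    return(structure(.point_mass_fit(0), class = "ni_fit"))
  fit <- .fit_continuous_norm(mean_value / s0, q25 / s0, q75 / s0)
  structure(.rescale_fit(fit, s0), class = "ni_fit")
}

# Undo the mean-normalization: every continuous candidate is a scale family.
.rescale_fit <- function(fit, s0) {
  fit$m <- fit$m * s0; fit$q_l <- fit$q_l * s0; fit$q_u <- fit$q_u * s0
  fit$C_value <- fit$C_value * s0^2
  switch(fit$family,
         truncated_normal = , gumbel = {
           fit$a <- fit$a * s0; fit$b <- fit$b * s0
         },
         lognormal = fit$a <- fit$a + log(s0),
         weibull = fit$b <- fit$b * s0,
         gamma = fit$b <- fit$b / s0,
         point_mass = fit$a <- fit$a * s0)
  fit
}

#' @export
print.ni_fit <- function(x, ...) {
  cat(sprintf("ni_fit: %s(a=%.6g%s)  C=%.4g  dev(m,ql,qu)=(%.3g, %.3g, %.3g)\n",
              x$family, x$a,
              if (is.na(x$b)) "" else sprintf(", b=%.6g", x$b),
              x$C_value, x$m, x$q_l, x$q_u))
  invisible(x)
}

#' Fit distributions for every documented cell of a dataset
#'
#' Applies [fit_distribution()] to each observation. Identical elicitations
#' (including the mean-normalized form of continuous triples, which differ
#' only by scale) are fitted once and reused, so datasets with duplicated or
#' proportional elicitations fit quickly.
#'
#' @param dataset an [ni_dataset()].
#' @return data frame of class `ni_fits`, one row per documented cell:
#'   cell keys, `family`, `a`, `b`, `C_value`, `m`, `q_l`, `q_u`,
#'   `duplication_group`. Exportable with [utils::write.csv()] as an audit
#'   trail.
#' @export
fit_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ni_dataset"))
  rec <- dataset$records
  n <- nrow(rec)
  out <- data.frame(indicator_id = rec$indicator_id,
                    ecosystem_id = rec$ecosystem_id,
                    unit_id = rec$unit_id, date = rec$date,
                    family = character(n), a = numeric(n), b = numeric(n),
                    C_value = numeric(n), m = numeric(n), q_l = numeric(n),
                    q_u = numeric(n),
                    duplication_group = rec$duplication_group,
                    stringsAsFactors = FALSE)
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    mv <- rec$mean_value[i]; ql <- rec$q25[i]; qu <- rec$q75[i]
    kind <- rec$variable_kind[i]
    if (kind == "continuous" && !(ql == qu && ql == mv) &&
        max(mv, qu) > 0) {
      s0 <- if (mv > 0) mv else qu
      key <- sprintf("c|%.15g|%.15g|%.15g", mv / s0, ql / s0, qu / s0)
      fit <- memo[[key]]
      if (is.null(fit)) {
        fit <- .fit_continuous_norm(mv / s0, ql / s0, qu / s0)
        memo[[key]] <- fit
      }
      fit <- .rescale_fit(fit, s0)
    } else {
      key <- sprintf("%s|%.15g|%.15g|%.15g", kind, mv, ql, qu)
      fit <- memo[[key]]
      if (is.null(fit)) {
        fit <- unclass(fit_distribution(mv, ql, qu, kind))
        memo[[key]] <- fit
      }
    }
    out$family[i] <- fit$family
    out$a[i] <- fit$a; out$b[i] <- fit$b
    out$C_value[i] <- fit$C_value
    out$m[i] <- fit$m; out$q_l[i] <- fit$q_l; out$q_u[i] <- fit$q_u
  }
  class(out) <- c("ni_fits", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Monte-Carlo replication of the elicitation process.

# Deterministic 31-bit substream seed from the master seed and a stream key.
# A simple polynomial hash keeps all intermediates exactly representable in
# doubles; cells seed independently, so adding a cell never perturbs the
# draws of any other cell.
.substream_seed <- function(seed, key) {
  M <- 2147483647
  h <- 2166136261 %% M
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% M
  as.integer((h + (as.numeric(seed) %% M) * 7919) %% M)
}

.draw_family <- function(family, a, b, n) {
  x <- switch(family,
              point_mass = rep(a, n),
              truncated_normal = .cont_spec$truncated_normal$draw(n, c(a, b)),
              gumbel = .cont_spec$gumbel$draw(n, c(a, b)),
              lognormal = stats::rlnorm(n, a, b),
              weibull = stats::rweibull(n, a, b),
              gamma = stats::rgamma(n, a, b),
              poisson = stats::rpois(n, a),
              zip = (stats::runif(n) >= a) * stats::rpois(n, b),
              negbinom = stats::rnbinom(n, size = a, mu = b),
              stop("unknown distribution family: ", family, call. = FALSE))
  pmax(x, 0)  # Gumbel support extends below zero; observations cannot
}

#' Draw Monte-Carlo replicates of the data-collection process
#'
#' Draws `n_sim` independent replicates from each cell's fitted
#' distribution, clipped to be non-negative. Cells sharing a
#' `duplication_group` — one expert elicitation copied to several
#' localities — receive one identical simulated vector, mimicking how the
#' data were entered. Each cell (or duplication group) uses its own RNG
#' substream keyed by its identity, so results are reproducible and adding a
#' cell never changes another cell's draws.
#'
#' @param fits an `ni_fits` table from [fit_dataset()].
#' @param n_sim number of replicates per cell (default 999).
#' @param seed master integer seed.
#' @return object of class `ni_sims`: list with `cells` (key columns of
#'   `fits`), `values` (matrix, one row per cell, `n_sim` columns),
#'   `n_sim`, `seed`.
#' @export
draw_replicates <- function(fits, n_sim = 999, seed = 1) {
  stopifnot(inherits(fits, "ni_fits"), n_sim >= 1)
  if (!all(fits$family %in% c(.CONT_FAMILIES, .DISC_FAMILIES, "point_mass")))
    stop("unknown distribution family: ",
         setdiff(fits$family, c(.CONT_FAMILIES, .DISC_FAMILIES,
                                "point_mass"))[1], call. = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  ids <- cell_id(fits$indicator_id, fits$ecosystem_id, fits$unit_id,
                 fits$date)
  skey <- ifelse(is.na(fits$duplication_group),
                 paste0("cell:", ids),
                 paste0("dup:", fits$duplication_group))
  vals <- matrix(NA_real_, nrow(fits), n_sim)
  rownames(vals) <- ids
  for (k in unique(skey)) {
    rows <- which(skey == k)
    i <- rows[1]
    set.seed(.substream_seed(seed, k))
    v <- .draw_family(fits$family[i], fits$a[i], fits$b[i], n_sim)
    vals[rows, ] <- rep(v, each = length(rows))
  }
  structure(list(cells = fits[, c("indicator_id", "ecosystem_id", "unit_id",
                                  "date", "duplication_group")],
                 values = vals, n_sim = n_sim, seed = seed),
            class = "ni_sims")
}

#' @export
print.ni_sims <- function(x, ...) {
  cat(sprintf("ni_sims: %d cells x %d replicates (seed %s)\n",
              nrow(x$values), x$n_sim, format(x$seed)))
  invisible(x)
}
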