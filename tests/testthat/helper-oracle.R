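# Independent brute-force oracle for the distribution fitter: staged dense
# grid search over (a, b) for every candidate family.  Expectations are
# computed by quantile averaging during ranking and by adaptive numerical
# integration of x * density(x) at the final polish, so the oracle shares no
# code path with the package's optimizer.

.or_Q <- list(
  truncated_normal = function(u, a, b) {
    Fa <- pnorm(-a / b)
    a + b * qnorm(Fa + u * (1 - Fa))
  },
  gumbel = function(u, a, b) a - b * log(-log(u)),
  lognormal = function(u, a, b) qlnorm(u, a, b),
  weibull = function(u, a, b) qweibull(u, a, b),
  gamma = function(u, a, b) qgamma(u, a, b)
)

.or_E_exact <- list(
  truncated_normal = function(a, b) {
    Z <- pnorm(0, a, b, lower.tail = FALSE)
    integrate(function(x) x * dnorm(x, a, b) / Z, 0, Inf,
              rel.tol = 1e-10)$value
  },
  gumbel = function(a, b)
    integrate(function(x) {
      z <- (x - a) / b
      x / b * exp(-z - exp(-z))
    }, -Inf, Inf, rel.tol = 1e-10)$value,
  lognormal = function(a, b)
    integrate(function(x) x * dlnorm(x, a, b), 0, Inf,
              rel.tol = 1e-10)$value,
  weibull = function(a, b)
    integrate(function(x) x * dweibull(x, a, b), 0, Inf,
              rel.tol = 1e-10)$value,
  gamma = function(a, b)
    integrate(function(x) x * dgamma(x, a, b), 0, Inf,
              rel.tol = 1e-10)$value
)

# Grids are laid out in coordinates where the objective's valley is roughly
# axis-aligned: Weibull as (shape, median), gamma as (shape, mean); `map`
# converts grid coordinates to the family's natural parameters.
.or_grids <- function(fam, s, med) {
  id <- function(a, b) list(a = a, b = b)
  switch(fam,
         truncated_normal = ,
         gumbel = list(a = seq(-2 * s, 2 * s, length.out = 32),
                       b = exp(seq(log(s / 50), log(3 * s),
                                   length.out = 32)),
                       sa = "lin", sb = "log", map = id),
         lognormal = list(a = seq(log(s) - 3, log(s) + 1.5,
                                  length.out = 32),
                          b = exp(seq(log(0.005), log(3), length.out = 32)),
                          sa = "lin", sb = "log", map = id),
         weibull = list(a = exp(seq(log(0.2), log(800), length.out = 48)),
                        b = exp(seq(log(med / 3), log(3 * med),
                                    length.out = 32)),
                        sa = "log", sb = "log",
                        map = function(a, b)
                          list(a = a, b = b / log(2)^(1 / a))),
         gamma = list(a = exp(seq(log(0.1), log(5000), length.out = 48)),
                      b = exp(seq(log(s / 3), log(3 * s), length.out = 32)),
                      sa = "log", sb = "log",
                      map = function(a, b) list(a = a, b = a / b)))
}

.or_refine <- function(vals, best, scale, len = 17) {
  t <- if (scale == "log") log(vals) else vals
  tb <- if (scale == "log") log(best) else best
  step <- mean(diff(sort(unique(t))))
  out <- seq(tb - step, tb + step, length.out = len)
  if (scale == "log") exp(out) else out
}

.or_stage <- function(Q, map, m, ql, qu, avec, bvec, nu = 128) {
  g <- expand.grid(a = avec, b = bvec)
  nat <- map(g$a, g$b)
  umid <- (seq_len(nu) - 0.5) / nu
  Eap <- colMeans(matrix(Q(rep(umid, nrow(g)), rep(nat$a, each = nu),
                           rep(nat$b, each = nu)), nu, nrow(g)))
  C <- (m - Eap)^2 + (ql - Q(0.25, nat$a, nat$b))^2 +
    (qu - Q(0.75, nat$a, nat$b))^2
  C[!is.finite(C)] <- Inf
  g[which.min(C), ]
}

oracle_fit_family_cont <- function(fam, m, ql, qu) {
  Q <- .or_Q[[fam]]
  gr <- .or_grids(fam, max(m, qu, 1e-6), max((ql + qu) / 2, 1e-6))
  avec <- gr$a; bvec <- gr$b
  best <- suppressWarnings(.or_stage(Q, gr$map, m, ql, qu, avec, bvec))
  for (r in 1:3) {
    avec2 <- .or_refine(avec, best$a, gr$sa)
    bvec2 <- .or_refine(bvec, best$b, gr$sb)
    best <- suppressWarnings(.or_stage(Q, gr$map, m, ql, qu, avec2, bvec2))
    avec <- avec2; bvec <- bvec2
  }
  # final polish on a small grid scored with exact (integrated) expectations
  avec <- .or_refine(avec, best$a, gr$sa, len = 9)
  bvec <- .or_refine(bvec, best$b, gr$sb, len = 9)
  g <- expand.grid(a = avec, b = bvec)
  nat <- gr$map(g$a, g$b)
  C <- vapply(seq_len(nrow(g)), function(i) {
    e <- tryCatch(.or_E_exact[[fam]](nat$a[i], nat$b[i]),
                  error = function(err) NA_real_)
    if (!is.finite(e)) return(Inf)
    (m - e)^2 + (ql - Q(0.25, nat$a[i], nat$b[i]))^2 +
      (qu - Q(0.75, nat$a[i], nat$b[i]))^2
  }, numeric(1))
  min(C)
}

oracle_fit_disc <- function(m, ql, qu) {
  zq <- function(p, pi0, lam) {
    pp <- pmin(pmax((p - pi0) / (1 - pi0), 0), 1)
    ifelse(p <= pi0, 0, qpois(pp, lam))
  }
  top <- 3 * max(m, qu, 1)
  # Poisson
  lam <- seq(1e-8, top, length.out = 5001)
  Cp <- (m - lam)^2 + (ql - qpois(0.25, lam))^2 + (qu - qpois(0.75, lam))^2
  b <- lam[which.min(Cp)]
  lam <- pmax(seq(b - top / 5000, b + top / 5000, length.out = 2001), 1e-8)
  Cp <- min((m - lam)^2 + (ql - qpois(0.25, lam))^2 +
              (qu - qpois(0.75, lam))^2)
  # zero-inflated Poisson
  g <- expand.grid(pi0 = seq(0, 0.98, length.out = 99),
                   lam = seq(1e-8, top, length.out = 400))
  Cz_all <- (m - (1 - g$pi0) * g$lam)^2 + (ql - zq(0.25, g$pi0, g$lam))^2 +
    (qu - zq(0.75, g$pi0, g$lam))^2
  bz <- g[which.min(Cz_all), ]
  g <- expand.grid(pi0 = seq(max(0, bz$pi0 - 0.01),
                             min(0.999, bz$pi0 + 0.01), length.out = 81),
                   lam = pmax(seq(bz$lam - top / 399, bz$lam + top / 399,
                                  length.out = 161), 1e-8))
  Cz <- min((m - (1 - g$pi0) * g$lam)^2 + (ql - zq(0.25, g$pi0, g$lam))^2 +
              (qu - zq(0.75, g$pi0, g$lam))^2)
  if (m > 0) {  # exact-mean curve lambda = m / (1 - pi)
    pis <- seq(0, 0.9995, length.out = 4000)
    Cz <- min(Cz, (ql - zq(0.25, pis, m / (1 - pis)))^2 +
                (qu - zq(0.75, pis, m / (1 - pis)))^2)
  }
  # negative binomial
  M <- max(m, (ql + qu) / 2, 0.5)
  g <- expand.grid(size = 10^seq(log10(0.02), 3, length.out = 120),
                   mu = seq(max(M / 4, 1e-8), 3 * M, length.out = 200))
  Cn_all <- (m - g$mu)^2 +
    (ql - qnbinom(0.25, size = g$size, mu = g$mu))^2 +
    (qu - qnbinom(0.75, size = g$size, mu = g$mu))^2
  bn <- g[which.min(Cn_all), ]
  g <- expand.grid(size = 10^seq(log10(bn$size) - 0.05,
                                 log10(bn$size) + 0.05, length.out = 41),
                   mu = pmax(seq(bn$mu - 3 * M / 199, bn$mu + 3 * M / 199,
                                 length.out = 81), 1e-8))
  Cn <- min((m - g$mu)^2 +
              (ql - qnbinom(0.25, size = g$size, mu = g$mu))^2 +
              (qu - qnbinom(0.75, size = g$size, mu = g$mu))^2)
  if (m > 0) {  # exact-mean curve mu = m over a dense size grid
    sz <- 10^seq(log10(0.02), 3, length.out = 4000)
    Cn <- min(Cn, (ql - qnbinom(0.25, size = sz, mu = m))^2 +
                (qu - qnbinom(0.75, size = sz, mu = m))^2)
  }
  min(Cp, Cz, Cn)
}

# Minimal C over all candidate families for the variable kind.
oracle_fit_C <- function(mean, q25, q75, kind) {
  if (kind == "discrete") return(oracle_fit_disc(mean, q25, q75))
  min(vapply(names(.or_Q), oracle_fit_family_cont, numeric(1),
             m = mean, ql = q25, qu = q75))
}
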