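# Surface tension from the pressure tensor, area strain, the area
# compressibility modulus K_A from a surface-tension series, and the
# two-sample t comparison of K_A estimates.

#' Autocorrelation-corrected standard error of a stationary series
#'
#' Standard error of the mean of a correlated series using the integrated
#' autocorrelation time: the normalized autocorrelation function is summed
#' from lag 1 until it first drops below zero (initial-positive-sum
#' truncation), giving `tau`; the effective sample size is
#' `n_eff = N / (1 + 2 tau)` and `se = sd / sqrt(n_eff)`.
#'
#' @param series numeric vector, length >= 10 (constant series of any
#'   length >= 2 are allowed and return `se = 0`).
#' @return List with `se`, `n_eff`, `tau` and `mean`.
#' @export
stationary_se <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2) stop("stationary_se needs a series of length >= 2")
  s2 <- stats::var(series)
  if (s2 == 0) return(list(se = 0, n_eff = n, tau = 0, mean = series[1]))
  if (n < 10) stop("stationary_se needs >= 10 observations for a non-constant series")
  ac <- stats::acf(series, lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  rho <- ac[-1]  # lags 1..n-1
  neg <- which(rho < 0)
  kmax <- if (length(neg)) neg[1] - 1L else length(rho)
  tau <- if (kmax >= 1L) sum(rho[seq_len(kmax)]) else 0
  n_eff <- n / (1 + 2 * tau)
  n_eff <- max(1, min(n_eff, n))
  list(se = sqrt(s2 / n_eff), n_eff = n_eff, tau = tau, mean = mean(series))
}

# Autocorrelation-aware SE that degrades gracefully on short series.
series_se <- function(x) {
  n <- length(x)
  if (n == 1) return(list(se = 0, n_eff = 1, tau = 0, mean = x))
  if (n >= 10 || stats::var(x) == 0) return(stationary_se(x))
  list(se = stats::sd(x) / sqrt(n), n_eff = n, tau = 0, mean = mean(x))
}

#' Surface tension from pressure-tensor records
#'
#' For each record, `gamma = Lz * (Pzz - (Pxx + Pyy)/2)` converted from
#' bar*A to mN/m (1 bar*A = 0.01 mN/m). The mean carries an
#' autocorrelation-corrected standard error.
#'
#' @param records data.frame with columns `Pxx_bar`, `Pyy_bar`, `Pzz_bar`,
#'   `Lz_A` and optionally `time_ps`.
#' @return List with `gamma` (per-record, mN/m), `mean`, `se`, `n_eff`.
#' @export
surface_tension <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  req <- c("Pxx_bar", "Pyy_bar", "Pzz_bar", "Lz_A")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("pressure records lack columns: ", paste(miss, collapse = ", "))
  if (any(records$Lz_A <= 0)) stop("Lz must be positive")
  k <- mm_units()[["bar_A_to_mN_per_m"]]
  g <- records$Lz_A * (records$Pzz_bar - (records$Pxx_bar + records$Pyy_bar) / 2) * k
  ss <- series_se(g)
  list(gamma = g, mean = ss$mean, se = ss$se, n_eff = ss$n_eff)
}

#' Area strain relative to the tensionless reference area
#'
#' @param A area (or area per lipid), same units as `A0`.
#' @param A0 reference area at zero surface tension; must be positive.
#' @return Dimensionless strain `(A - A0)/A0`.
#' @export
area_strain <- function(A, A0) {
  if (any(A0 <= 0)) stop("A0 must be positive")
  (A - A0) / A0
}

#' Fit the area compressibility modulus from a tension series
#'
#' K_A is the slope of imposed surface tension versus area strain. The
#' tensionless point defines the reference area A0, so the fitted line is
#' pinned through the origin; the remaining points are fitted by weighted
#' least squares with weights from the propagated per-point strain
#' uncertainties. The slope uncertainty combines, in quadrature, the
#' delta-method variance from the per-point APL uncertainties and the
#' propagated uncertainty of A0 itself.
#'
#' @param points data.frame with columns `gamma` (mN/m), `apl_mean` (A^2),
#'   `apl_se` (A^2) and optionally `n_eff`. Exactly one row must have
#'   `gamma == 0`.
#' @param weighted logical; use 1/se^2 weights (default). With `FALSE`, or
#'   when all `apl_se` are zero, ordinary least squares is used.
#' @param zero_intercept logical; pin the fit through the origin (default).
#'   `FALSE` fits a free intercept (diagnostic alternative).
#' @return An `mm_elasticity` object: list with `K_A`, `K_A_se` (mN/m),
#'   `A0`, `A0_se` (A^2), `strain` (per point), `residuals` (mN/m),
#'   `r_squared`, `points` (augmented input) and `intercept`.
#' @export
fit_area_compressibility <- function(points, weighted = TRUE,
                                     zero_intercept = TRUE) {
  stopifnot(is.data.frame(points))
  req <- c("gamma", "apl_mean", "apl_se")
  miss <- setdiff(req, names(points))
  if (length(miss)) stop("tension points lack columns: ", paste(miss, collapse = ", "))
  if (nrow(points) < 2) stop("need >= 2 tension points")
  iz <- which(points$gamma == 0)
  if (length(iz) != 1) stop("exactly one point must have gamma = 0 (defines A0)")
  if (length(unique(points$gamma)) < 2) stop("need >= 2 distinct tensions")
  A0 <- points$apl_mean[iz]
  A0_se <- points$apl_se[iz]
  eps <- area_strain(points$apl_mean, A0)
  if (all(eps[-iz] == 0)) stop("all strains identical; cannot fit a slope")
  se_eps <- points$apl_se / A0

  slope_fn <- function(A0v) {
    e <- (points$apl_mean - A0v) / A0v
    if (zero_intercept) {
      w <- if (weighted && any(se_eps > 0)) {
        wv <- ifelse(se_eps > 0, 1 / se_eps^2, 0)
        # the gamma = 0 point has e = 0 and contributes nothing to the slope
        wv[iz] <- 0
        wv
      } else {
        wv <- rep(1, nrow(points)); wv[iz] <- 0; wv
      }
      sum(w * e * points$gamma) / sum(w * e^2)
    } else {
      w <- if (weighted && any(se_eps > 0)) ifelse(se_eps > 0, 1 / se_eps^2, 1)
           else rep(1, nrow(points))
      stats::coef(stats::lm(points$gamma ~ e, weights = w))[["e"]]
    }
  }
  K <- slope_fn(A0)

  # delta method: dK/d(eps_i) for the pinned, weighted slope
  var_K <- 0
  if (zero_intercept) {
    w <- if (weighted && any(se_eps > 0)) {
      wv <- ifelse(se_eps > 0, 1 / se_eps^2, 0); wv[iz] <- 0; wv
    } else {
      wv <- rep(1, nrow(points)); wv[iz] <- 0; wv
    }
    Sxx <- sum(w * eps^2)
    Sxy <- sum(w * eps * points$gamma)
    dK_de <- w * (points$gamma * Sxx - 2 * eps * Sxy) / Sxx^2
    var_K <- sum((dK_de * se_eps)^2)
  } else {
    # free intercept: numeric propagation of each point's strain
    h <- pmax(se_eps, 1e-8)
    for (i in seq_len(nrow(points))) {
      if (se_eps[i] == 0) next
      p2 <- points; p2$apl_mean[i] <- p2$apl_mean[i] + h[i] * A0
      K2 <- tryCatch(fit_area_compressibility(p2, weighted, FALSE)$K_A,
                     error = function(e) K)
      var_K <- var_K + ((K2 - K) / (h[i] * A0) * points$apl_se[i])^2
    }
  }
  # propagate A0's own uncertainty numerically
  if (A0_se > 0) {
    h0 <- A0_se
    K_hi <- slope_fn(A0 + h0)
    K_lo <- slope_fn(A0 - h0)
    var_K <- var_K + ((K_hi - K_lo) / 2)^2
  }
  fitted <- K * eps
  resid <- points$gamma - fitted
  ssr <- sum(resid[-iz]^2)
  sst <- sum((points$gamma[-iz] - mean(points$gamma[-iz]))^2)
  out <- list(
    K_A = K, K_A_se = sqrt(var_K), A0 = A0, A0_se = A0_se,
    strain = eps, residuals = resid,
    r_squared = if (sst > 0) 1 - ssr / sst else 1,
    intercept = 0,
    points = cbind(points, strain = eps, fitted_gamma = fitted)
  )
  class(out) <- "mm_elasticity"
  out
}

#' @export
print.mm_elasticity <- function(x, ...) {
  cat("<mm_elasticity> K_A = ", format(x$K_A, digits = 5), " +/- ",
      format(x$K_A_se, digits = 3), " mN/m;  A0 = ",
      format(x$A0, digits = 5), " A^2;  R^2 = ",
      format(x$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Two-sample t comparison of two K_A estimates
#'
#' Pooled-variance two-sample t test treating each K_A as the mean of `n`
#' tension-condition estimates whose group standard deviation is
#' reconstructed from the reported standard error as `sd = se * sqrt(n)`.
#' With the four-tension design of both groups, `df = n1 + n2 - 2 = 6` and
#' the two-tailed 95% critical value is `qt(0.975, 6) = 2.447`.
#'
#' @param ka1,ka2 the two K_A estimates (mN/m).
#' @param se1,se2 their standard errors (mN/m).
#' @param n1,n2 number of tension conditions per estimate (default 4).
#' @param alpha significance level for the `significant` flag (default 0.05,
#'   two-tailed).
#' @param method `"pooled_t"` (default) or `"z"`: the z alternative compares
#'   the estimates directly through their standard errors,
#'   `z = (ka1 - ka2)/sqrt(se1^2 + se2^2)`, with a normal two-tailed p.
#' @return An `mm_ttest` object: list with `t`, `df`, `p`, `critical`
#'   (two-tailed critical value at `alpha`) and `significant`.
#' @export
compare_ka <- function(ka1, se1, ka2, se2, n1 = 4, n2 = 4, alpha = 0.05,
                       method = c("pooled_t", "z")) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if ((se1 <= 0 || se2 <= 0) && ka1 != ka2) stop("standard errors must be positive")
  if (method == "z") {
    z <- if (ka1 == ka2) 0 else (ka1 - ka2) / sqrt(se1^2 + se2^2)
    p <- 2 * stats::pnorm(-abs(z))
    crit <- stats::qnorm(1 - alpha / 2)
    out <- list(t = z, df = Inf, p = p, critical = crit,
                significant = abs(z) > crit, method = "z")
  } else {
    df <- n1 + n2 - 2
    s1 <- se1 * sqrt(n1)
    s2 <- se2 * sqrt(n2)
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    tval <- if (ka1 == ka2) 0
            else (ka1 - ka2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- if (tval == 0) 1 else 2 * stats::pt(-abs(tval), df)
    crit <- stats::qt(1 - alpha / 2, df)
    out <- list(t = tval, df = df, p = p, critical = crit,
                significant = abs(tval) > crit, method = "pooled_t")
  }
  class(out) <- "mm_ttest"
  out
}

#' @export
print.mm_ttest <- function(x, ...) {
  cat("<mm_ttest> t = ", format(x$t, digits = 4), ", df = ", x$df,
      ", p = ", format(x$p, digits = 3),
      if (x$significant) " (significant)" else " (not significant)",
      "\n", sep = "")
  invisible(x)
}
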