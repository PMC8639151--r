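#' Two-proportion z test (binomial proportion test)
#'
#' `z = (p2 - p1) / SE` with `p_i = k_i / n_i`. The pooled variant uses
#' `SE = sqrt(p(1-p)(1/n1 + 1/n2))` with `p = (k1+k2)/(n1+n2)`; the unpooled
#' variant uses `SE = sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`. Two-tailed normal
#' p-value. The sign of `z` follows `p2 - p1`; swapping the groups negates it.
#' Both variants are provided because published z statistics for counts of
#' irregular steps are internally consistent only under a per-analysis
#' variance convention; the variant is always recorded in the result.
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @param variant `"unpooled"` (default) or `"pooled"`.
#' @return list with `k1`, `n1`, `k2`, `n2`, `p1`, `p2`, `variant`, `z`, `p`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2, variant = c("unpooled", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  se <- if (variant == "pooled") {
    pp <- (k1 + k2) / (n1 + n2)
    sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  } else {
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  if (se == 0) stop("standard error is zero (degenerate proportions)")
  z <- (p2 - p1) / se
  list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
       variant = variant, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Watson two-sample U-squared statistic on circular fractions in [0,1).
# EDF form: at the N pooled sorted points, d = F - G cumulative fractions;
# U2 = (n*m/N^2) * sum((d - mean(d))^2), ties processed together.
.watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  v <- c(a, b)
  is_a <- c(rep(TRUE, n), rep(FALSE, m))
  o <- order(v)
  v <- v[o]; is_a <- is_a[o]
  d <- numeric(N)
  Fa <- 0; Gb <- 0
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && v[j + 1] == v[i]) j <- j + 1  # tie block
    Fa <- Fa + sum(is_a[i:j]) / n
    Gb <- Gb + sum(!is_a[i:j]) / m
    d[i:j] <- Fa - Gb
    i <- j + 1
  }
  (n * m / N^2) * sum((d - mean(d))^2)
}

# asymptotic tail probability of Watson U2
.watson_u2_p_asymptotic <- function(u2, terms = 50) {
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
  min(max(p, 0), 1)
}

#' Watson two-sample U² test for circular data
#'
#' Nonparametric comparison of two samples of circular values (fractions of a
#' cycle): are the two coupling-pattern distributions the same around the
#' circle? The statistic compares the pooled empirical distribution functions
#' and is invariant to a common rotation of both samples. The p-value is
#' obtained by seeded label permutation (default) or by the asymptotic series
#' for larger samples.
#'
#' @param sample_a,sample_b circular fractions in `[0, 1)`.
#' @param n_permutations permutation count (default 9999).
#' @param seed integer seed for the permutation stream (`NULL` = use current
#'   RNG state).
#' @param method `"permutation"` or `"asymptotic"`.
#' @return list with `u2`, `p`, `n1`, `n2`, `method`, `n_permutations`,
#'   `seed`.
#' @export
watson_u2 <- function(sample_a, sample_b, n_permutations = 9999, seed = NULL,
                      method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  a <- sample_a %% 1; b <- sample_b %% 1
  n <- length(a); m <- length(b)
  if (method == "permutation" && (n < 4 || m < 4))
    stop("permutation mode requires at least 4 values per sample")
  u2 <- .watson_u2_stat(a, b)
  if (length(unique(c(a, b))) == 1) {
    return(list(u2 = 0, p = 1, n1 = n, n2 = m, method = method,
                n_permutations = 0L, seed = seed))
  }
  if (method == "asymptotic") {
    p <- .watson_u2_p_asymptotic(u2)
    nperm <- 0L
  } else {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
      }
      set.seed(seed)
    }
    pool <- c(a, b)
    ge <- 0L
    for (i in seq_len(n_permutations)) {
      idx <- sample.int(n + m, n)
      if (.watson_u2_stat(pool[idx], pool[-idx]) >= u2 - 1e-12) ge <- ge + 1L
    }
    p <- (ge + 1) / (n_permutations + 1)
    nperm <- as.integer(n_permutations)
  }
  list(u2 = u2, p = p, n1 = n, n2 = m, method = method,
       n_permutations = nperm, seed = seed)
}

#' Circular descriptive statistics for phase fractions
#'
#' Values are mapped to angles (`2 * pi * x`), vector-averaged, and the mean
#' direction mapped back to a fraction. `R` is the mean resultant length and
#' the circular SD is `sqrt(-2 * log(R))` (radians; divide by `2 * pi` for
#' cycle fraction). When `R` is numerically zero the mean direction is
#' undefined and returned as `NA`.
#'
#' @param values circular fractions.
#' @return list with `mean` (fraction in `[0,1)` or `NA`), `R`,
#'   `circ_sd_rad`, `n`.
#' @export
circular_descriptives <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  ang <- 2 * pi * (values %% 1)
  C <- mean(cos(ang)); S <- mean(sin(ang))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-12) {
    return(list(mean = NA_real_, R = R, circ_sd_rad = Inf,
                n = length(values)))
  }
  list(mean = (atan2(S, C) / (2 * pi)) %% 1, R = R,
       circ_sd_rad = sqrt(-2 * log(R)), n = length(values))
}

#' Fit a speed-dependent spatiotemporal curve
#'
#' Least-squares fit of a gait measure against instantaneous speed, either
#' exponential decay `y = y0 + a * exp(-b * x)` (stance and stride times) or
#' linear (stride distance). Returns the coefficients, `R^2`, residual SD,
#' and a 95% prediction-interval function built from the residual variance
#' with a t quantile at `n - p` degrees of freedom.
#'
#' @param x speeds (cm/s).
#' @param y measure values.
#' @param model `"exponential_decay"` or `"linear"`.
#' @param level prediction-interval coverage.
#' @return object of class `speed_curve_fit`: `model`, `coefficients`,
#'   `r_squared`, `residual_sd`, `df`, `predict(x)`,
#'   `prediction_interval(x)`.
#' @export
fit_speed_curve <- function(x, y, model = c("exponential_decay", "linear"),
                            level = 0.95) {
  model <- match.arg(model)
  n <- length(x)
  stopifnot(length(y) == n)
  p <- if (model == "linear") 2L else 3L
  if (n < p + 2) stop("too few points for the requested model")
  if (model == "exponential_decay" && diff(range(x)) <= 0)
    stop("exponential model requires positive spread in x")
  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    cf <- c(intercept = unname(stats::coef(fit)[1]),
            slope = unname(stats::coef(fit)[2]))
    pred <- function(newx) cf[["intercept"]] + cf[["slope"]] * newx
    fitted_y <- pred(x)
  } else {
    # coarse grid on the rate, conditionally linear in (y0, a), then refine
    bgrid <- exp(seq(log(1e-3), log(1), length.out = 40)) / diff(range(x)) * 5
    sse <- sapply(bgrid, function(b) {
      z <- exp(-b * x)
      f <- stats::lm(y ~ z)
      sum(stats::resid(f)^2)
    })
    b0 <- bgrid[which.min(sse)]
    z <- exp(-b0 * x)
    lf <- stats::coef(stats::lm(y ~ z))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y0 + a * exp(-b * x),
                        start = list(y0 = lf[[1]], a = lf[[2]], b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("exponential fit failed to converge: ",
                               conditionMessage(e)))
    cf <- stats::coef(fit)
    cf <- c(y0 = unname(cf["y0"]), a = unname(cf["a"]), b = unname(cf["b"]))
    pred <- function(newx) cf[["y0"]] + cf[["a"]] * exp(-cf[["b"]] * newx)
    fitted_y <- pred(x)
  }
  res <- y - fitted_y
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
  df <- n - p
  s <- sqrt(sum(res^2) / df)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  structure(list(
    model = model, coefficients = cf, r_squared = r2, residual_sd = s,
    df = df, n = n, predict = pred,
    prediction_interval = function(newx) {
      f <- pred(newx)
      data.frame(x = newx, fit = f, lwr = f - tq * s, upr = f + tq * s)
    }
  ), class = "speed_curve_fit")
}

#' Paired t test with a zero-variance guard
#'
#' Standard paired t on the differences (`df = n - 1`, two-tailed); errors
#' when the differences have zero variance, where the statistic is undefined.
#'
#' @param a,b paired value vectors of equal length `n >= 2`.
#' @return list with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  if (stats::sd(d) == 0) stop("zero variance of paired differences")
  ht <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = mean(d))
}
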