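#' Fit the base-2 exponential growth law to an observed series
#'
#' Fits \eqn{X(t) = X_0\,2^{(t + t_0)/\tau}} to an observed quantity
#' (apex count, 3-degree vertex count, or total length) with `t0` held
#' fixed.  For the `pure` model the fit is a weighted linear least squares
#' in the log2 domain (uncertainties mapped as \eqn{\sigma/(X \ln 2)};
#' points with \eqn{X \le \sigma} are excluded).  The `v3_polynomial`
#' model multiplies the base-2 law by a first-order polynomial,
#' \eqn{X(t) = 2^{(t+t_0)/\tau} (c_0 + c_1 t)}, the empirical form of the
#' observed 3-degree count whose dominant term is geometric crossings.
#' The `saturating` model fits \eqn{X(t) = 1/(b + c\,2^{-a t})}, the
#' bounded law that reduces to \eqn{c^{-1} 2^{a t}} while \eqn{c \gg b}.
#'
#' @param series data.frame with columns `t` and the fitted quantity
#'   (`N_V1ob`, `N_V3ob` or `L`) plus optionally its uncertainty column
#'   (`sigma_V1`, `sigma_V3`, `sigma_L`); missing uncertainties default to
#'   Poisson (`sqrt(X)`) for counts and 5% for lengths.
#' @param quantity One of `"N_V1ob"`, `"N_V3ob"`, `"L"`.
#' @param t0 Temporal offset (fixed during the fit), hours.
#' @param range Fit window `(tMin, tMax)`; points outside are excluded
#'   (early points sit in the lag phase, late points leave the exponential
#'   phase).
#' @param model `"pure"`, `"v3_polynomial"` or `"saturating"`.
#' @return An object of class `base2Fit`: list with `X0`, `tau`, `t0`,
#'   `cov` (covariance of `(X0, tau)`), `chi2`, `chi2Reduced`, `dof`,
#'   `fitRange`, `model`, `n`, `seX0`, `seTau` and model-specific
#'   coefficients (`c0`, `c1` or `a`, `b`, `c`).
#' @examples
#' t <- 2:15
#' s <- data.frame(t = t, N_V1ob = 3 * 2^((t + 1.7) / 1.8))
#' fitBase2Growth(s, "N_V1ob", t0 = 1.7)  # recovers X0 = 3, tau = 1.8
#' @export
fitBase2Growth <- function(series, quantity = c("N_V1ob", "N_V3ob", "L"),
                           t0 = 0, range = c(2, 15),
                           model = c("pure", "v3_polynomial", "saturating")) {
  quantity <- match.arg(quantity)
  model <- match.arg(model)
  stopifnot(all(c("t", quantity) %in% names(series)))
  sigCol <- c(N_V1ob = "sigma_V1", N_V3ob = "sigma_V3", L = "sigma_L")[quantity]
  keep <- series$t >= range[1] & series$t <= range[2]
  d <- series[keep, , drop = FALSE]
  X <- d[[quantity]]
  autoPoisson <- !(sigCol %in% names(d)) && quantity != "L"
  sig <- if (sigCol %in% names(d)) d[[sigCol]]
         else if (quantity == "L") 0.05 * X else sqrt(pmax(1, X))
  bad <- !is.finite(X) | X <= 0
  if (model == "pure") bad <- bad | X <= sig
  if (any(bad)) {
    if (any(X[!is.na(X)] <= 0))
      warning("non-positive points dropped from log-domain fit")
    d <- d[!bad, , drop = FALSE]; X <- X[!bad]; sig <- sig[!bad]
  }
  if (nrow(d) < 4) stop("need at least 4 points inside the fit range")
  tt <- d$t
  out <- list(t0 = t0, fitRange = range, model = model, n = length(X),
              quantity = quantity)
  if (model == "pure") {
    y <- log2(X)
    wsd <- sig / (X * log(2))
    fit <- lm(y ~ tt, weights = 1 / wsd^2)
    # reweight once from the fitted curve: weights built from the observed
    # counts are correlated with their own noise and underestimate the
    # parameter covariance
    Xfit <- 2^(coef(fit)[[1]] + coef(fit)[[2]] * tt)
    sigFit <- if (autoPoisson) sqrt(pmax(1, Xfit)) else sig
    wsd <- sigFit / (Xfit * log(2))
    fit <- lm(y ~ tt, weights = 1 / wsd^2)
    slope <- coef(fit)[[2]]; inter <- coef(fit)[[1]]
    if (slope <= 0) stop("fitted growth rate is non-positive")
    tau <- 1 / slope
    X0 <- 2^(inter - t0 * slope)
    # delta method: (X0, tau) from (inter, slope)
    Vc <- vcov(fit)
    J <- rbind(c(X0 * log(2), -X0 * log(2) * t0), c(0, -tau^2))
    cv <- J %*% Vc %*% t(J)
    res <- (y - inter - slope * tt) / wsd
    chi2 <- sum(res^2)
    out <- c(out, list(X0 = X0, tau = tau, cov = cv, chi2 = chi2,
                       dof = length(X) - 2L,
                       chi2Reduced = chi2 / (length(X) - 2L),
                       seX0 = sqrt(cv[1, 1]), seTau = sqrt(cv[2, 2])))
  } else if (model == "v3_polynomial") {
    tauGuess <- 1 / max(0.1, coef(lm(log2(X) ~ tt))[[2]])
    fit <- minpack.lm::nlsLM(
      X ~ 2^((tt + t0) / tau) * (c0 + c1 * tt),
      start = list(tau = tauGuess,
                   c0 = max(X[1] / 2^((tt[1] + t0) / tauGuess), 0.1),
                   c1 = 0.01),
      lower = c(tau = 1e-3, c0 = 0, c1 = 0),
      weights = 1 / sig^2, control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    chi2 <- sum(((X - predict(fit)) / sig)^2)
    tau <- cf[["tau"]]
    X0 <- cf[["c0"]]  # amplitude at the onset t = 0 given the offset t0
    Vc <- vcov(fit)
    out <- c(out, list(X0 = X0, tau = tau, c0 = cf[["c0"]], c1 = cf[["c1"]],
                       cov = Vc[c("c0", "tau"), c("c0", "tau")], chi2 = chi2,
                       dof = length(X) - 3L,
                       chi2Reduced = chi2 / (length(X) - 3L),
                       seX0 = sqrt(Vc["c0", "c0"]),
                       seTau = sqrt(Vc["tau", "tau"])))
  } else {
    sl <- max(coef(lm(log2(X) ~ tt))[[2]], 0.1)
    fit <- minpack.lm::nlsLM(
      X ~ 1 / (b + cc * 2^(-a * tt)),
      start = list(a = sl, b = 1 / (2 * max(X)),
                   cc = 2^(sl * tt[1]) / max(X[1], 1)),
      weights = 1 / sig^2, control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- coef(fit)
    chi2 <- sum(((X - predict(fit)) / sig)^2)
    Vc <- vcov(fit)
    tau <- 1 / cf[["a"]]
    out <- c(out, list(a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]],
                       tau = tau, X0 = 1 / cf[["cc"]] * 2^(t0 * cf[["a"]]),
                       cov = Vc, chi2 = chi2, dof = length(X) - 3L,
                       chi2Reduced = chi2 / (length(X) - 3L),
                       seTau = sqrt(Vc["a", "a"]) / cf[["a"]]^2,
                       seX0 = NA_real_))
  }
  class(out) <- "base2Fit"
  out
}

#' @export
print.base2Fit <- function(x, ...) {
  cat(sprintf("base-2 growth fit of %s (%s model)\n", x$quantity, x$model))
  cat(sprintf("  X0 = %.4g, tau = %.4g (se %.2g), t0 = %g fixed\n",
              x$X0, x$tau, x$seTau, x$t0))
  cat(sprintf("  chi2 = %.3g on %d dof (reduced %.3g), n = %d in [%g, %g]\n",
              x$chi2, x$dof, x$chi2Reduced, x$n,
              x$fitRange[1], x$fitRange[2]))
  invisible(x)
}

#' Scan the temporal offset of a growth fit
#'
#' The offset `t0` is a fixed parameter of [fitBase2Growth()]; this helper
#' scans a grid of offsets and returns the one whose fitted onset amplitude
#' `X0` lands closest to its expected window (about 3 apexes, about 1
#' three-degree vertex, 10-20 hyphal diameters of length at growth onset).
#'
#' @inheritParams fitBase2Growth
#' @param t0Grid Candidate offsets (hours).
#' @param target Expected onset amplitude for the chosen quantity.
#' @return List with `t0` (selected), `fit` (the fit at that offset) and
#'   `scan` (data.frame of t0, X0, chi2).
#' @export
scanT0 <- function(series, quantity = c("N_V1ob", "N_V3ob", "L"),
                   t0Grid = seq(0, 4, by = 0.1),
                   target = c(N_V1ob = 3, N_V3ob = 1, L = 0.25)[quantity],
                   range = c(2, 15)) {
  quantity <- match.arg(quantity)
  fits <- lapply(t0Grid, function(t0)
    tryCatch(fitBase2Growth(series, quantity, t0 = t0, range = range),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no t0 in the grid admits a fit")
  X0 <- vapply(fits[ok], `[[`, numeric(1), "X0")
  chi2 <- vapply(fits[ok], `[[`, numeric(1), "chi2")
  grid <- t0Grid[ok]
  best <- which.min(abs(log(X0 / target)))
  list(t0 = grid[best], fit = fits[ok][[best]],
       scan = data.frame(t0 = grid, X0 = X0, chi2 = chi2))
}

#' Linear map from data time to simulation time
#'
#' Calibrates the simulation clock on the data clock by equating the fitted
#' base-2 growth laws, \eqn{(A\,2^{a t})_{data} = (A\,2^{a t'})_{sim}} with
#' \eqn{t'} linear in \eqn{t}: `slope = tauSim / tauData` and
#' `offset = tauSim * log2(Adata / Asim)` where \eqn{A = X_0 2^{t_0/\tau}}.
#' Uncertainties are propagated from both fit covariances.
#'
#' @param fitData,fitSim `base2Fit` objects for the data and the simulation.
#' @return List with `slope`, `offset`, `seSlope`, `seOffset`.
#' @export
timeScaleMap <- function(fitData, fitSim) {
  stopifnot(inherits(fitData, "base2Fit"), inherits(fitSim, "base2Fit"))
  if (fitData$tau <= 0 || fitSim$tau <= 0) stop("tau must be positive")
  slope <- fitSim$tau / fitData$tau
  A <- function(f) f$X0 * 2^(f$t0 / f$tau)
  offset <- fitSim$tau * log2(A(fitData) / A(fitSim))
  seSlope <- slope * sqrt((fitSim$seTau / fitSim$tau)^2 +
                            (fitData$seTau / fitData$tau)^2)
  # d offset / d log2(A) terms, with log2(A) = log2(X0) + t0 / tau
  seLog2A <- function(f) sqrt((f$seX0 / (f$X0 * log(2)))^2 +
                                (f$t0 * f$seTau / f$tau^2)^2)
  seOffset <- sqrt((fitSim$tau)^2 * (seLog2A(fitData)^2 + seLog2A(fitSim)^2) +
                     (fitSim$seTau * offset / fitSim$tau)^2)
  list(slope = slope, offset = offset, seSlope = seSlope, seOffset = seOffset)
}

#' Length-per-vertex calibration ratios
#'
#' `r1` is the total network length per observed apex and `r3` the length
#' per observed 3-degree vertex.  For a deep binary tree `r1` plateaus at
#' \eqn{\langle\ell\rangle (2 - 2^{2-g})(1+p)/(1+2p)} with `p` the lateral
#' branch fraction, while `r3` keeps decreasing as geometric crossings
#' accumulate.
#'
#' @param x A [Thallus-class] (ratios from true counts, laterals included),
#'   an [ObservedThallus-class], or a data.frame series with columns
#'   `N_V1ob`, `N_V3ob`, `L` (row-wise ratios).
#' @return List (or data.frame for a series) with `r1` and `r3` (mm).
#' @export
lengthRatios <- function(x) {
  if (is(x, "Thallus")) {
    sm <- summarizeThallus(x)
    n1 <- sm$nV1 + sm$nV1l; n3 <- sm$nV3 + sm$nV3l
    if (n1 == 0) stop("zero apex count")
    return(list(r1 = sm$totalLength / n1,
                r3 = if (n3 > 0) sm$totalLength / n3 else NA_real_))
  }
  if (is(x, "ObservedThallus")) {
    n <- x@counts
    if (n[["N_V1ob"]] == 0 || n[["N_V3ob"]] == 0) stop("zero vertex counts")
    return(list(r1 = n[["L_ob"]] / n[["N_V1ob"]],
                r3 = n[["L_ob"]] / n[["N_V3ob"]]))
  }
  stopifnot(all(c("N_V1ob", "N_V3ob", "L") %in% names(x)))
  if (any(x$N_V1ob == 0) || any(x$N_V3ob == 0)) stop("zero vertex counts")
  data.frame(t = x$t, r1 = x$L / x$N_V1ob, r3 = x$L / x$N_V3ob)
}

#' Expected apex length ratio of a binary tree
#'
#' Closed form of the `r1` plateau:
#' \eqn{\langle\ell\rangle (2 - 2^{2-g}) (1+p)/(1+2p)}.
#'
#' @param g Generation index.
#' @param p Lateral branch fraction (lateral branches per apical branch).
#' @param meanLength Mean drawn branch length (mm).
#' @return Expected `r1` (mm).
#' @export
expectedLengthRatio <- function(g, p = 0, meanLength = 1) {
  meanLength * (2 - 2^(2 - g)) * (1 + p) / (1 + 2 * p)
}

#' Lateral branch fraction of a thallus
#'
#' The mean fraction of lateral branches per apical branch,
#' `p = S / (D - S)` with `S` the lateral-origin drawn branches and `D` all
#' drawn branches (lateral splits do not double count).
#'
#' @param thallus A [Thallus-class] object.
#' @return Fraction in `[0, Inf)`.
#' @export
lateralFraction <- function(thallus) summarizeThallus(thallus)$pLateral

#' Inertia tensor and sphericity of a vertex cloud
#'
#' Builds the 2x2 inertia tensor of a point cloud (sums of centered second
#' moments), diagonalizes it and reports the sphericity
#' \eqn{s = 2\lambda_2 / (\lambda_1 + \lambda_2)}: 1 for a disk-like
#' (isotropic) cloud, 0 for a collinear one.  The cloud shape of a growing
#' thallus is expected to be stationary in time.
#'
#' @param points Two-column matrix or data.frame of positions (mm).
#' @return List with `centroid`, `tensor`, `eigenvalues` (sorted
#'   decreasing), `sphericity` and `axisAngle` (principal axis, degrees in
#'   (-90, 90]).
#' @examples
#' inertiaSphericity(rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2)))
#' @export
inertiaSphericity <- function(points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 3)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  if (all(abs(cen) < .Machine$double.eps * 100))
    stop("all points coincident")
  I <- crossprod(cen)
  ev <- eigen(I, symmetric = TRUE)
  lam <- ev$values
  ax <- ev$vectors[, 1]
  ang <- atan2(ax[2], ax[1]) / pi * 180
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(centroid = ctr, tensor = I, eigenvalues = lam,
       sphericity = 2 * lam[2] / (lam[1] + lam[2]), axisAngle = ang)
}

#' Nonparametric bootstrap of a statistic
#'
#' Resamples rows (or elements) with replacement and returns the bootstrap
#' standard error and a central 1-sigma (68.3%) percentile interval.
#' Degenerate resamples for which the statistic fails are redrawn (and
#' counted).
#'
#' @param x Vector, matrix or data.frame.
#' @param statistic Function of a resample returning a single number.
#' @param B Number of replicates (>= 100).
#' @param seed RNG seed (NA leaves the RNG state untouched).
#' @param probs Interval probabilities (default the central 68.3%).
#' @return List with `estimate`, `se`, `ci`, `B`, `redraws`.
#' @export
bootstrapCI <- function(x, statistic, B = 1000, seed = NA,
                        probs = c(0.1585, 0.8415)) {
  stopifnot(B >= 100)
  if (!is.na(seed)) set.seed(as.integer(seed))
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  take <- function(idx) if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
  est <- statistic(x)
  vals <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                    error = function(e) NA_real_)
      if (is.finite(v)) break
      redraws <- redraws + 1L
      if (redraws > 10 * B) stop("too many degenerate bootstrap resamples")
    }
    vals[b] <- v
  }
  list(estimate = est, se = sd(vals), ci = unname(quantile(vals, probs)),
       B = B, redraws = redraws)
}
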