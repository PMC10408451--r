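## Correlation evaluation protocol and grid-search parameter fitting.
##
## Objective (metric) scores are compared with subjective MOS/DMOS by
## Spearman rank correlation, and by Pearson correlation after mapping the
## metric through a fitted four-parameter logistic — the standard protocol
## for validating quality metrics against observer data.

validate_scored_set <- function(objective, subjective, min_n = 3L) {
  objective <- as.numeric(objective)
  subjective <- as.numeric(subjective)
  if (length(objective) != length(subjective))
    stop("objective and subjective vectors must have equal length",
         call. = FALSE)
  if (length(objective) < min_n)
    stop("need at least ", min_n, " scored pairs, got ", length(objective),
         call. = FALSE)
  if (!all(is.finite(objective)) || !all(is.finite(subjective)))
    stop("scores contain non-finite values", call. = FALSE)
  list(objective = objective, subjective = subjective)
}

#' Spearman rank correlation (SRCC)
#'
#' Average ranks are used for ties.  A constant vector has no defined rank
#' correlation and raises an error rather than returning NA.
#'
#' @param objective,subjective Paired numeric vectors, length >= 3.
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' srcc(1:5, c(1, 3, 2, 5, 4))  # 0.7
srcc <- function(objective, subjective) {
  d <- validate_scored_set(objective, subjective)
  if (sd(d$objective) == 0 || sd(d$subjective) == 0)
    stop("rank correlation undefined for a constant score vector",
         call. = FALSE)
  cor(d$objective, d$subjective, method = "spearman")
}

#' Four-parameter logistic mapping
#'
#' \deqn{\hat y(x) = \beta_2 + \frac{\beta_1 - \beta_2}{1 + e^{-(x - \beta_3)/|\beta_4|}}}
#' Monotone in x (increasing when beta1 > beta2), asymptotes beta2 (x ->
#' -Inf) and beta1 (x -> +Inf), midpoint (beta1+beta2)/2 at x = beta3.
#'
#' @param x Numeric vector.
#' @param beta Numeric vector `c(beta1, beta2, beta3, beta4)`; `beta4`
#'   enters through its absolute value and must be nonzero.
#' @return Numeric vector of mapped values.
#' @export
logistic4 <- function(x, beta) {
  if (length(beta) != 4L || !all(is.finite(beta)))
    stop("'beta' must be four finite numbers", call. = FALSE)
  if (beta[4] == 0) stop("beta4 must be nonzero", call. = FALSE)
  beta[2] + (beta[1] - beta[2]) / (1 + exp(-(x - beta[3]) / abs(beta[4])))
}

#' Fit the four-parameter logistic to metric/MOS pairs
#'
#' Nonlinear least squares of [logistic4()] mapped objective scores onto
#' subjective scores.  Initialization: beta1 = max(subjective), beta2 =
#' min(subjective), beta3 = median(objective), beta4 = sd(objective); beta1
#' and beta2 are swapped when the raw Pearson correlation is negative, as
#' for distance metrics that anti-correlate with opinion scores.  `nls`
#' (port algorithm) is tried first and a Nelder-Mead/BFGS fallback covers
#' the cases where it fails to start.
#'
#' @param objective,subjective Paired numeric vectors, length >= 5,
#'   objective not constant.
#' @return A list with `beta` (length 4), `fitted` values, `residual_norm`,
#'   and `method`.
#' @export
fit_logistic4 <- function(objective, subjective) {
  d <- validate_scored_set(objective, subjective, min_n = 5L)
  x <- d$objective; y <- d$subjective
  if (sd(x) == 0)
    stop("objective scores are constant; logistic fit undefined",
         call. = FALSE)
  if (sd(y) == 0)
    stop("subjective scores are constant; logistic fit undefined",
         call. = FALSE)
  b1 <- max(y); b2 <- min(y)
  if (cor(x, y) < 0) { tmp <- b1; b1 <- b2; b2 <- tmp }
  b4 <- sd(x); if (b4 == 0) b4 <- 1
  start <- c(b1 = b1, b2 = b2, b3 = median(x), b4 = b4)

  fit <- NULL; method <- "nls-port"
  fit <- tryCatch({
    m <- stats::nls(y ~ b2 + (b1 - b2) / (1 + exp(-(x - b3) / abs(b4))),
                    start = as.list(start), algorithm = "port",
                    control = stats::nls.control(maxiter = 500,
                                                 warnOnly = FALSE))
    stats::coef(m)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    method <- "optim"
    sse <- function(b) {
      if (b[4] == 0) return(Inf)
      sum((y - logistic4(x, b))^2)
    }
    o <- optim(start, sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, sse, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    if (!is.finite(o$value))
      stop("logistic fit failed to converge (start: ",
           paste(signif(start, 4), collapse = ", "), ")", call. = FALSE)
    fit <- o$par
  }
  beta <- unname(fit)
  if (beta[4] == 0)
    stop("logistic fit degenerate: |beta4| collapsed to zero", call. = FALSE)
  yhat <- logistic4(x, beta)
  list(beta = beta, fitted = yhat,
       residual_norm = sqrt(sum((y - yhat)^2)), method = method)
}

#' Pearson correlation after logistic mapping (PLCC)
#'
#' Fits the four-parameter logistic with [fit_logistic4()] and returns the
#' Pearson correlation between the mapped objective scores and the
#' subjective scores.  Because the logistic absorbs orientation and any
#' monotone saturation, a perfectly (anti-)monotone logistic relationship
#' yields PLCC = 1.
#'
#' @inheritParams fit_logistic4
#' @return A number in \[-1, 1\] (1 for a noiseless logistic relation).
#' @export
plcc_after_fit <- function(objective, subjective) {
  f <- fit_logistic4(objective, subjective)
  if (sd(f$fitted) == 0) {
    # flat fit: no linear association recoverable
    return(0)
  }
  cor(f$fitted, subjective)
}

#' Grid-search optimization of the metric parameters
#'
#' Exhaustively evaluates every combination of candidate `sigma_m`,
#' `sigma_w`, `sigma_g`, `lambda` values: for each grid point the image
#' metric is computed on all reference/distorted pairs and correlated with
#' the subjective scores; the argmax of the chosen criterion is returned.
#' For `objective_fn = "plcc"` the criterion is [plcc_after_fit()] (the
#' logistic mapping absorbs the metric's orientation); for `"srcc"` it is
#' the absolute Spearman correlation, since a distance metric legitimately
#' anti-correlates with opinion scores.  Ties break to the smallest
#' (sigma_m, sigma_w, sigma_g, lambda) in lexicographic order, so the
#' result is reproducible bit for bit.  A grid point where the metric or
#' the fit fails is recorded in the scan log with an `error` message and
#' skipped.
#'
#' @param pairs List of `list(ref = , dist = )` image pairs.
#' @param subjective Numeric vector of MOS/DMOS, one per pair.
#' @param grid List with numeric vectors `sigma_m`, `sigma_w`, `sigma_g`,
#'   `lambda` (defaults span the useful range around the published
#'   optimum).
#' @param objective_fn `"plcc"` (default) or `"srcc"`.
#' @param luminance,exact Passed to the metric, see [inrf_iqa()].
#' @return The winning [inrf_params()]; the full scan log (one row per grid
#'   point: parameters, criterion, error) is attached as attribute
#'   `scan_log`, the winning criterion value as `criterion`.
#' @export
grid_search <- function(pairs, subjective,
                        grid = list(sigma_m = c(0.5, 1, 1.74, 2.5, 4),
                                    sigma_w = c(5, 10, 25, 50),
                                    sigma_g = c(0.5, 1, 2),
                                    lambda = c(1, 2, 3, 5)),
                        objective_fn = c("plcc", "srcc"),
                        luminance = "luma601", exact = FALSE) {
  objective_fn <- match.arg(objective_fn)
  if (!is.list(pairs) || length(pairs) < 5L)
    stop("need at least 5 scored image pairs", call. = FALSE)
  if (length(subjective) != length(pairs))
    stop("one subjective score per pair is required", call. = FALSE)
  for (nm in c("sigma_m", "sigma_w", "sigma_g", "lambda"))
    if (!length(grid[[nm]]))
      stop("grid is missing candidate values for '", nm, "'", call. = FALSE)

  pts <- expand.grid(sigma_m = sort(grid$sigma_m),
                     sigma_w = sort(grid$sigma_w),
                     sigma_g = sort(grid$sigma_g),
                     lambda = sort(grid$lambda),
                     KEEP.OUT.ATTRS = FALSE)
  # lexicographic order in (sigma_m, sigma_w, sigma_g, lambda): last key
  # varies slowest under expand.grid, so reorder rows explicitly
  pts <- pts[order(pts$sigma_m, pts$sigma_w, pts$sigma_g, pts$lambda), ,
             drop = FALSE]
  pts <- unique(pts)

  # many pairs share a reference image: transform each distinct luminance
  # image once per grid point instead of once per pair
  lums <- list(); ref_ix <- dist_ix <- integer(length(pairs))
  intern <- function(img) {
    lum <- to_luminance(img, luminance)
    for (u in seq_along(lums)) if (identical(lums[[u]], lum)) return(u)
    lums[[length(lums) + 1L]] <<- lum
    length(lums)
  }
  for (i in seq_along(pairs)) {
    if (is.null(pairs[[i]]$ref) || is.null(pairs[[i]]$dist))
      stop("each pair must be a list(ref = , dist = )", call. = FALSE)
    ref_ix[i] <- intern(pairs[[i]]$ref)
    dist_ix[i] <- intern(pairs[[i]]$dist)
  }

  crit <- rep(NA_real_, nrow(pts))
  errs <- rep(NA_character_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    res <- tryCatch({
      p <- inrf_params(sigma_m = pts$sigma_m[i], sigma_w = pts$sigma_w[i],
                       sigma_g = pts$sigma_g[i], lambda = pts$lambda[i])
      tr <- lapply(lums, inrf_transform, params = p, exact = exact)
      scores <- vapply(seq_along(pairs), function(j)
        mean((tr[[ref_ix[j]]] - tr[[dist_ix[j]]])^2), numeric(1))
      if (objective_fn == "plcc") plcc_after_fit(scores, subjective)
      else abs(srcc(scores, subjective))
    }, error = function(e) e)
    if (inherits(res, "error")) errs[i] <- conditionMessage(res)
    else crit[i] <- res
  }
  if (all(is.na(crit)))
    stop("every grid point failed; first error: ",
         errs[which(!is.na(errs))[1]], call. = FALSE)
  best <- which(crit == max(crit, na.rm = TRUE))[1]  # rows already lex-sorted
  out <- inrf_params(sigma_m = pts$sigma_m[best], sigma_w = pts$sigma_w[best],
                     sigma_g = pts$sigma_g[best], lambda = pts$lambda[best])
  attr(out, "criterion") <- crit[best]
  attr(out, "scan_log") <- cbind(pts, criterion = crit, error = errs)
  out
}
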