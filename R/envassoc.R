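# Association of per-cell morph frequency with abiotic covariates:
# weighted correlation/regression screens, variance inflation factors,
# and generalized least squares with an exponential spatial
# correlation structure and per-cell variance weights.
#
# The GLS covariance is Sigma_ij = sigma2 * sqrt(v_i v_j) * exp(-d_ij /
# rho) off-diagonal and sigma2 * v_i on the diagonal, where v_i = 1 /
# n_i (inverse of the number of records in cell i) and d_ij is the
# Euclidean distance between cell centres in degrees, matching an
# exponential correlation structure combined with fixed variance
# weights.

.ENV_COVARIATES <- c("bio01", "bio20", "bio12", "bio28")

#' Weighted Pearson correlation
#'
#' Weighted moment correlation between `x` and `y` with non-negative
#' weights `w`; the p-value uses the t approximation with `n - 2`
#' degrees of freedom where `n` is the number of points. Equal weights
#' reproduce the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param w weights (default equal: unweighted correlation).
#' @return list with `r`, `p`, `n`.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  if (length(x) < 3) stop("need at least 3 points")
  if (any(w < 0) || sum(w) == 0) stop("weights must be non-negative, not all zero")
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
  if (cxx == 0 || cyy == 0) stop("zero variance in x or y")
  r <- cxy / sqrt(cxx * cyy)
  n <- length(x)
  r_t <- min(max(r, -1), 1)
  if (abs(r_t) >= 1) {
    p <- 0
  } else {
    tstat <- r_t * sqrt((n - 2) / (1 - r_t^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Weighted least-squares regression
#'
#' `y` on the columns of `X` (intercept added) with weights `w`,
#' typically the number of records per cell.
#'
#' @param y response vector.
#' @param X numeric matrix or data.frame of covariates.
#' @param w weights.
#' @return list with `beta`, `se`, `t`, `p` (per coefficient),
#'   `r_squared`, `n`.
#' @export
weighted_linreg <- function(y, X, w = rep(1, length(y))) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df, weights = w)
  if (any(is.na(stats::coef(fit)))) stop("design matrix is rank deficient")
  s <- summary(fit)
  list(beta = stats::coef(fit), se = s$coefficients[, "Std. Error"],
       t = s$coefficients[, "t value"],
       p = s$coefficients[, "Pr(>|t|)"],
       r_squared = s$r.squared, n = length(y))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing covariate
#' j on the remaining covariates (with intercept). Perfect
#' collinearity yields `Inf` rather than an error.
#'
#' @param X matrix or data.frame with at least two non-constant
#'   columns.
#' @return named numeric vector, one VIF per column.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two covariates")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant covariate column")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit))$r.squared  # perfect fit -> Inf
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(X)
  out
}

.env_design <- function(cells, covariates) {
  stopifnot(all(c("y", "n_records", "centre_lon", "centre_lat") %in%
                  names(cells)))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(cells[, covariates, drop = FALSE]))
  v <- 1 / cells$n_records
  D <- as.matrix(stats::dist(cells[, c("centre_lon", "centre_lat")]))
  list(y = cells$y, X = X, v = v, D = D, n = nrow(cells))
}

.gls_sigma <- function(v, D, rho) {
  C <- exp(-D / rho)
  diag(C) <- 1
  sv <- sqrt(v)
  (sv %o% sv) * C
}

#' Gaussian log-likelihood of the spatial GLS model
#'
#' Multivariate-normal log-likelihood of the per-cell response under
#' mean `X beta` and covariance `sigma2 * sqrt(v_i v_j) exp(-d_ij /
#' rho)` (diagonal `sigma2 * v_i`), with `v_i = 1 / n_records_i` and
#' `d_ij` the Euclidean distance between cell centres in degrees.
#'
#' @param beta coefficient vector (intercept first) matching
#'   `covariates`.
#' @param sigma2 residual variance scale (> 0).
#' @param rho spatial correlation range in degrees (> 0).
#' @param cells environmental cell table (see [attach_environment()]):
#'   columns `y`, `n_records`, `centre_lon`, `centre_lat` and the
#'   covariates.
#' @param covariates character vector of covariate column names
#'   (possibly empty for the intercept-only model).
#' @return log-likelihood.
#' @export
gls_loglik <- function(beta, sigma2, rho, cells,
                       covariates = .ENV_COVARIATES) {
  stopifnot(sigma2 > 0, rho > 0)
  d <- .env_design(cells, covariates)
  stopifnot(length(beta) == ncol(d$X))
  S <- sigma2 * .gls_sigma(d$v, d$D, rho)
  ch <- tryCatch(chol(S), error = function(e)
    stop("covariance matrix not positive definite (condition: ",
         format(kappa(S)), ")"))
  r <- d$y - drop(d$X %*% beta)
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (d$n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Profile log-likelihood over rho: given the correlation matrix, the
# GLS beta-hat and the ML sigma2-hat have closed forms.
.gls_profile <- function(d, rho) {
  W <- .gls_sigma(d$v, d$D, rho)
  ch <- chol(W)
  Xs <- backsolve(ch, d$X, transpose = TRUE)
  ys <- backsolve(ch, d$y, transpose = TRUE)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, ys)
  names(beta) <- colnames(d$X)
  r <- ys - Xs %*% beta
  sigma2 <- sum(r^2) / d$n
  logL <- -0.5 * (d$n * log(2 * pi) + d$n * log(sigma2) +
                    2 * sum(log(diag(ch))) + d$n)
  XtWX_inv <- chol2inv(qr.R(qrX))
  # Wald covariance uses the n - p denominator (the standard GLS
  # convention); the likelihood itself stays ML so AIC is comparable
  sigma2_se <- sum(r^2) / (d$n - ncol(d$X))
  list(beta = drop(beta), sigma2 = sigma2, logL = logL,
       cov_beta = sigma2_se * XtWX_inv, chol = ch)
}

#' Fit a spatial GLS model by maximum likelihood
#'
#' Profiles the coefficients and variance scale in closed form given
#' the correlation range `rho`, and maximises the profile likelihood
#' over `log(rho)` by 1-D bounded search. ML (not REML) is used so
#' that AIC values are comparable across fixed-effect structures.
#' Wald standard errors come from `(X' Sigma^-1 X)^-1`.
#'
#' @inheritParams gls_loglik
#' @param rho optional fixed correlation range; when supplied the 1-D
#'   search is skipped (useful for the `rho -> 0` weighted-OLS limit).
#' @param rho_bounds search interval for `rho` (degrees); default
#'   spans 1e-3 x the median to 10 x the maximum inter-cell distance.
#' @return object of class `gls_fit`: `covariates`, `beta`, `se`
#'   (Wald, with the residual variance on its `n - p` denominator as
#'   in standard GLS software), `t`, `p` (t tests on `n - p` df),
#'   `rho`, `sigma2` (ML scale), `logL`, `aic` (`-2 logL + 2k`, `k` =
#'   coefficients + 2), `n`.
#' @export
fit_gls <- function(cells, covariates = .ENV_COVARIATES, rho = NULL,
                    rho_bounds = NULL) {
  d <- .env_design(cells, covariates)
  if (d$n < length(covariates) + 3)
    stop("need at least ", length(covariates) + 3, " cells")
  if (is.null(rho)) {
    dpos <- d$D[upper.tri(d$D)]
    dpos <- dpos[dpos > 0]
    if (length(dpos) == 0) stop("all cells at identical coordinates")
    if (is.null(rho_bounds))
      rho_bounds <- c(1e-3 * stats::median(dpos), 10 * max(dpos))
    obj <- function(lr) -.gls_profile(d, exp(lr))$logL
    opt <- stats::optimize(obj, log(rho_bounds), tol = 1e-8)
    rho <- exp(opt$minimum)
  }
  pr <- .gls_profile(d, rho)
  se <- sqrt(diag(pr$cov_beta))
  names(se) <- names(pr$beta)
  z <- pr$beta / se
  k <- length(pr$beta) + 2
  df <- d$n - length(pr$beta)
  structure(list(covariates = covariates, beta = pr$beta, se = se,
                 t = z, p = 2 * stats::pt(-abs(z), df = df), df = df,
                 rho = rho, sigma2 = pr$sigma2, logL = pr$logL,
                 aic = -2 * pr$logL + 2 * k, k = k, n = d$n),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("gls_fit: y ~ ",
      if (length(x$covariates)) paste(x$covariates, collapse = " + ")
      else "1",
      "  (", x$n, " cells)\n", sep = "")
  cat(sprintf("  rho = %.3g, sigma2 = %.3g, logL = %.3f, AIC = %.2f\n",
              x$rho, x$sigma2, x$logL, x$aic))
  tab <- data.frame(beta = x$beta, se = x$se, z = x$t, p = x$p)
  print(tab, digits = 4)
  invisible(x)
}

#' Fit the null model and all covariate combinations
#'
#' One GLS fit per subset of the four covariates (16 models including
#' the intercept-only null), ordered by AIC. Per-model failures are
#' reported in the table, not fatal.
#'
#' @inheritParams gls_loglik
#' @return data.frame with one row per model (`formula`, `k`, `logL`,
#'   `aic`, `delta_aic`) and attribute `fits` (the `gls_fit` objects,
#'   in table order); attribute `inclusion` tabulates each covariate's
#'   presence in the top five models.
#' @export
gls_model_grid <- function(cells, covariates = .ENV_COVARIATES) {
  subsets <- list(character(0))
  for (k in seq_along(covariates))
    subsets <- c(subsets, utils::combn(covariates, k, simplify = FALSE))
  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    fit <- tryCatch(fit_gls(cells, subsets[[i]]), error = function(e) e)
    label <- if (length(subsets[[i]])) paste(subsets[[i]], collapse = " + ")
             else "(null)"
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(formula = label, k = NA, logL = NA_real_,
                              aic = NA_real_, error = conditionMessage(fit))
    } else {
      fits[[i]] <- fit
      rows[[i]] <- data.frame(formula = label, k = fit$k, logL = fit$logL,
                              aic = fit$aic, error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  rownames(tab) <- NULL
  top5 <- fits[!vapply(fits, is.null, TRUE)][1:5]
  inclusion <- vapply(covariates, function(cv)
    sum(vapply(top5, function(f) cv %in% f$covariates, TRUE)), 0L)
  attr(tab, "fits") <- fits
  attr(tab, "inclusion") <- inclusion
  tab
}

#' Univariate screens of each covariate against morph frequency
#'
#' For each covariate: the pairwise linear regression of `y` on that
#' covariate weighted by the number of records per cell, and both
#' weighted and unweighted Pearson correlations.
#'
#' @inheritParams gls_loglik
#' @return data.frame, one row per covariate, with slope/p of the
#'   weighted regression and r/p of the weighted and unweighted
#'   correlations.
#' @export
env_screens <- function(cells, covariates = .ENV_COVARIATES) {
  w <- cells$n_records
  do.call(rbind, lapply(covariates, function(cv) {
    lr <- weighted_linreg(cells$y, cells[, cv, drop = FALSE], w)
    wp <- weighted_pearson(cells[[cv]], cells$y, w)
    up <- weighted_pearson(cells[[cv]], cells$y)
    data.frame(covariate = cv,
               slope = unname(lr$beta[2]), slope_p = unname(lr$p[2]),
               r_weighted = wp$r, p_weighted = wp$p,
               r_unweighted = up$r, p_unweighted = up$p)
  }))
}

#' Covariate verdicts against the three support criteria
#'
#' For each covariate, evaluates: (i) inclusion in all of the top five
#' best-fitting GLS models; (ii) a Wald effect significantly different
#' from zero in the best-fitting model (false if absent from it);
#' (iii) significance in the weighted pairwise linear model and in the
#' unweighted Pearson correlation. The verdict is the conjunction.
#'
#' @param grid_result a [gls_model_grid()] table.
#' @param screens an [env_screens()] table on the same cells.
#' @param alpha significance level (default 0.05).
#' @return data.frame with the three criteria and `passes` per
#'   covariate.
#' @export
criteria_report <- function(grid_result, screens, alpha = 0.05) {
  fits <- attr(grid_result, "fits")
  fits <- fits[!vapply(fits, is.null, TRUE)]
  best <- fits[[1]]
  inclusion <- attr(grid_result, "inclusion")
  out <- do.call(rbind, lapply(screens$covariate, function(cv) {
    in_top5 <- unname(inclusion[cv] == 5L)
    effect_sig <- if (cv %in% best$covariates)
      unname(best$p[cv] < alpha) else FALSE
    sc <- screens[screens$covariate == cv, ]
    linear_sig <- sc$slope_p < alpha
    pearson_sig <- sc$p_unweighted < alpha
    data.frame(covariate = cv, in_top5 = in_top5,
               effect_sig = effect_sig,
               linear_sig = linear_sig, pearson_sig = pearson_sig,
               passes = in_top5 && effect_sig && linear_sig && pearson_sig)
  }))
  rownames(out) <- NULL
  out
}
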