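# One-dimensional geographic cline models: a central sigmoid in
# along-transect distance, optionally with exponential tails beyond
# offsets deltaL/deltaR from the centre (slope ratios tauL/tauR), and
# optional scaling of the asymptotic frequencies to [pmin, pmax].
# Fitted to per-cell allele-frequency estimates by binomial maximum
# likelihood and explored by random-walk Metropolis MCMC.

.PAR_NAMES <- c("centre", "width", "pmin", "pmax",
                "deltaL", "deltaR", "tauL", "tauR")

#' Cline model specification
#'
#' A model is named by its (scaling, tails) pair. `scaling = "none"`
#' pins the asymptotes to 0 and 1; `"fixed"` pins them to the observed
#' minimum and maximum frequency; `"free"` estimates them. `tails =
#' "both"` adds exponential left and right tails (four extra
#' parameters). The free-parameter count `k` is 2 (centre, width) plus
#' 2 for free scaling plus 4 for tails.
#'
#' @param scaling `"none"`, `"fixed"` or `"free"`.
#' @param tails `"none"` or `"both"`.
#' @return object of class `cline_model_spec`.
#' @export
cline_model_spec <- function(scaling = c("none", "fixed", "free"),
                             tails = c("none", "both")) {
  scaling <- match.arg(scaling)
  tails <- match.arg(tails)
  k <- 2L + 2L * (scaling == "free") + 4L * (tails == "both")
  structure(list(scaling = scaling, tails = tails, k = k),
            class = "cline_model_spec")
}

#' @export
print.cline_model_spec <- function(x, ...) {
  cat("cline model (scaling = ", x$scaling, ", tails = ", x$tails,
      "), k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Cline parameter set
#'
#' @param centre cline centre, km along the transect.
#' @param width cline width, km (> 0); the inverse of the maximum
#'   slope scaled by 4, so the central sigmoid is
#'   `1 / (1 + exp(-4 (x - centre) / width))`.
#' @param pmin,pmax asymptotic minimum/maximum frequency,
#'   `0 <= pmin < pmax <= 1`.
#' @param deltaL,deltaR distances from the centre (km, >= 0) at which
#'   the left/right exponential tails take over.
#' @param tauL,tauR tail slope ratios in \[0, 1\]; 1 matches the
#'   sigmoid's slope at the junction (continuous first derivative).
#' @return object of class `cline_params`.
#' @export
cline_params <- function(centre, width, pmin = 0, pmax = 1,
                         deltaL = 0, deltaR = 0, tauL = 1, tauR = 1) {
  stopifnot(is.finite(centre), width > 0,
            pmin >= 0, pmax <= 1, pmin < pmax,
            deltaL >= 0, deltaR >= 0,
            tauL >= 0, tauL <= 1, tauR >= 0, tauR <= 1)
  structure(list(centre = centre, width = width, pmin = pmin, pmax = pmax,
                 deltaL = deltaL, deltaR = deltaR, tauL = tauL, tauR = tauR),
            class = "cline_params")
}

.par_vec <- function(params) {
  unlist(params[.PAR_NAMES], use.names = FALSE)
}

#' Evaluate a cline model
#'
#' The central shape is `f(x) = 1 / (1 + exp(-4 (x - c) / w))`. With
#' tails, for `x < c - deltaL`,
#' `f(x) = [1 / (1 + exp(4 deltaL / w))] *
#'   exp(4 tauL (x - c + deltaL) / w / (1 + exp(-4 deltaL / w)))`,
#' and symmetrically (reflected) on the right. The returned frequency
#' is `pmin + (pmax - pmin) f(x)`.
#'
#' @param x positions along the transect, km (vectorised).
#' @param params a [cline_params].
#' @param spec a [cline_model_spec]; only its `tails` field matters
#'   here (scaling is already embodied in `pmin`/`pmax`).
#' @return frequencies in \[0, 1\].
#' @export
cline_value <- function(x, params, spec = cline_model_spec()) {
  c0 <- params$centre; w <- params$width
  f <- stats::plogis(4 * (x - c0) / w)
  if (spec$tails == "both") {
    dL <- params$deltaL; dR <- params$deltaR
    tL <- params$tauL; tR <- params$tauR
    left <- x < c0 - dL
    if (any(left)) {
      f[left] <- (1 / (1 + exp(4 * dL / w))) *
        exp((4 * tL * (x[left] - c0 + dL) / w) / (1 + exp(-4 * dL / w)))
    }
    right <- x > c0 + dR
    if (any(right)) {
      f[right] <- 1 - (1 / (1 + exp(4 * dR / w))) *
        exp((-4 * tR * (x[right] - c0 - dR) / w) / (1 + exp(-4 * dR / w)))
    }
  }
  params$pmin + (params$pmax - params$pmin) * f
}

.cells_xqm <- function(cells, allele_counts) {
  stopifnot(nrow(cells) >= 1, all(c("along_km", "qhat", "n") %in% names(cells)))
  mult <- if (allele_counts == "2n") 2 else 1
  list(x = cells$along_km, q = cells$qhat, m = mult * cells$n)
}

#' Binomial log-likelihood of a cline model
#'
#' `LL = sum_i m_i [q_i log p(x_i) + (1 - q_i) log(1 - p(x_i))]` with
#' `p` clamped to `[eps, 1 - eps]`. `m_i` is the allele count of cell
#' i: `2 n_i` under the default convention (the HWE-estimated
#' frequency treated as a binomial proportion of 2n alleles), or `n_i`
#' with `allele_counts = "n"`.
#'
#' @param params a [cline_params].
#' @param spec a [cline_model_spec].
#' @param cells data.frame of projected cells with columns `along_km`,
#'   `qhat`, `n` (see [project_cells()]).
#' @param allele_counts `"2n"` (default) or `"n"`.
#' @param eps frequency clamp keeping the likelihood finite at
#'   observed 0/1 frequencies.
#' @return log-likelihood (a scalar).
#' @export
cline_loglik <- function(params, spec, cells, allele_counts = c("2n", "n"),
                         eps = 1e-6) {
  allele_counts <- match.arg(allele_counts)
  d <- .cells_xqm(cells, allele_counts)
  p <- pmin(pmax(cline_value(d$x, params, spec), eps), 1 - eps)
  sum(d$m * (d$q * log(p) + (1 - d$q) * log1p(-p)))
}

# Parameter bounds used for ML optimisation and as MCMC prior support:
# centre over [min x - span, max x + span], width over (0, 4 span],
# delta over [0, 2 span], tau over [0, 1], pmin/pmax over [0, 1].
.cline_bounds <- function(x) {
  span <- diff(range(x))
  if (span <= 0) stop("all cells at the same along-transect position")
  list(span = span,
       lower = c(min(x) - span, 1e-2, 0, 0, 0, 0, 0, 0),
       upper = c(max(x) + span, 4 * span, 1, 1, 2 * span, 2 * span, 1, 1))
}

# Optimisation variables for a given spec: centre, width, then
# (pmin, dp) under free scaling with pmax = pmin + dp (1 - pmin) to
# keep the order constraint smooth, then the four tail parameters.
.opt_pack <- function(spec) {
  vars <- c("centre", "width")
  if (spec$scaling == "free") vars <- c(vars, "pmin", "dp")
  if (spec$tails == "both") vars <- c(vars, "deltaL", "deltaR", "tauL", "tauR")
  vars
}

.opt_to_par <- function(v, vars, spec, fixed_minmax, bounds) {
  th <- c(v[["centre"]], v[["width"]], 0, 1, 0, 0, 1, 1)
  names(th) <- .PAR_NAMES
  if (spec$scaling == "fixed") {
    th["pmin"] <- fixed_minmax[1]; th["pmax"] <- fixed_minmax[2]
  } else if (spec$scaling == "free") {
    th["pmin"] <- v[["pmin"]]
    th["pmax"] <- v[["pmin"]] + v[["dp"]] * (1 - v[["pmin"]])
  }
  if (spec$tails == "both") {
    th["deltaL"] <- v[["deltaL"]]; th["deltaR"] <- v[["deltaR"]]
    th["tauL"] <- v[["tauL"]]; th["tauR"] <- v[["tauR"]]
  }
  th
}

.theta_to_params <- function(th) {
  cline_params(centre = th[1], width = th[2],
               pmin = th[3], pmax = th[4],
               deltaL = th[5], deltaR = th[6],
               tauL = min(th[7], 1), tauR = min(th[8], 1))
}

#' Maximum-likelihood cline fit
#'
#' Bounded quasi-Newton maximisation of [cline_loglik()] from 10
#' dispersed deterministic starting points (five centre positions
#' crossed with two widths). Decreasing clines are fitted on the
#' complement frequency `1 - q` with the orientation recorded, so the
#' fitted width is always positive and the fitted cline increasing.
#'
#' @inheritParams cline_loglik
#' @return list with `params` ([cline_params] on the fitted,
#'   increasing orientation), `logL`, `orientation` (`"increasing"` or
#'   `"decreasing"`), `spec`, `flags` (character vector; e.g.
#'   `"width_at_bound"` for effectively flat data).
#' @export
fit_cline_ml <- function(spec, cells, allele_counts = c("2n", "n"),
                         eps = 1e-6) {
  allele_counts <- match.arg(allele_counts)
  d <- .cells_xqm(cells, allele_counts)
  if (nrow(cells) < spec$k + 1)
    stop("need at least k + 1 = ", spec$k + 1, " cells")
  orientation <- "increasing"
  q <- d$q
  sl <- stats::coef(stats::lm(q ~ d$x, weights = d$m))[2]
  if (is.finite(sl) && sl < 0) {
    orientation <- "decreasing"
    q <- 1 - q
  }
  bounds <- .cline_bounds(d$x)
  fixed_minmax <- range(q)
  if (spec$scaling == "fixed" && diff(fixed_minmax) <= 0)
    stop("fixed scaling undefined: all observed frequencies identical")
  vars <- .opt_pack(spec)
  lower <- c(centre = bounds$lower[1], width = bounds$lower[2],
             pmin = 0, dp = 1e-3,
             deltaL = 0, deltaR = 0, tauL = 0, tauR = 0)[vars]
  upper <- c(centre = bounds$upper[1], width = bounds$upper[2],
             pmin = 0.999, dp = 1,
             deltaL = bounds$upper[5], deltaR = bounds$upper[6],
             tauL = 1, tauR = 1)[vars]
  negll <- function(v) {
    names(v) <- vars
    th <- .opt_to_par(v, vars, spec, fixed_minmax, bounds)
    -.cline_loglik_cpp(th, spec$tails == "both", d$x, q, d$m, eps)
  }
  centre_starts <- min(d$x) + c(0.1, 0.3, 0.5, 0.7, 0.9) * bounds$span
  width_starts <- c(bounds$span / 4, bounds$span)
  best <- NULL
  for (cs in centre_starts) for (ws in width_starts) {
    v0 <- c(centre = cs, width = ws, pmin = max(fixed_minmax[1], 1e-3),
            dp = 0.9, deltaL = bounds$span / 4, deltaR = bounds$span / 4,
            tauL = 0.5, tauR = 0.5)[vars]
    v0 <- pmin(pmax(v0, lower), upper)
    fit <- tryCatch(
      stats::optim(v0, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("all ML starts failed to converge")
  v <- best$par; names(v) <- vars
  th <- .opt_to_par(v, vars, spec, fixed_minmax, bounds)
  flags <- character()
  if (th["width"] > 0.98 * bounds$upper[2]) {
    flags <- c(flags, "width_at_bound")
    warning("fitted width at its upper bound: cline effectively flat")
  }
  list(params = .theta_to_params(th), logL = -best$value,
       orientation = orientation, spec = spec, flags = flags,
       allele_counts = allele_counts)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param logL maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations (grid cells).
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and compare all six cline model specifications
#'
#' Fits every (scaling, tails) combination by maximum likelihood and
#' ranks them by AICc over the projected cells; ties are broken toward
#' fewer parameters. Models that fail to fit are reported with `NA`
#' scores rather than aborting the comparison.
#'
#' @inheritParams cline_loglik
#' @return data.frame with one row per model: `scaling`, `tails`, `k`,
#'   `logL`, `aicc`, `delta_aicc`, `best` flag; attribute `fits` holds
#'   the individual [fit_cline_ml()] results.
#' @export
compare_cline_models <- function(cells, allele_counts = c("2n", "n")) {
  allele_counts <- match.arg(allele_counts)
  combos <- expand.grid(scaling = c("none", "fixed", "free"),
                        tails = c("none", "both"),
                        stringsAsFactors = FALSE)
  fits <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    spec <- cline_model_spec(combos$scaling[i], combos$tails[i])
    fit <- tryCatch(
      suppressWarnings(fit_cline_ml(spec, cells, allele_counts)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(scaling = spec$scaling, tails = spec$tails,
                              k = spec$k, logL = NA_real_, aicc = NA_real_,
                              error = conditionMessage(fit))
    } else {
      fits[[i]] <- fit
      rows[[i]] <- data.frame(scaling = spec$scaling, tails = spec$tails,
                              k = spec$k, logL = fit$logL,
                              aicc = aicc(fit$logL, spec$k, nrow(cells)),
                              error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$aicc, tab$k, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - min(tab$aicc, na.rm = TRUE)
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

.rhat <- function(chain_draws) {
  m <- length(chain_draws)
  n <- length(chain_draws[[1]])
  means <- vapply(chain_draws, mean, 0)
  vars <- vapply(chain_draws, stats::var, 0)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Metropolis MCMC sampling of a cline posterior
#'
#' Random-walk Metropolis with per-parameter Gaussian proposals whose
#' scales adapt during burn-in only, and uniform priors over a box:
#' centre over `[min x - span, max x + span]`, width over
#' `(0, 4 span]`, tail offsets over `[0, 2 span]`, tail slope ratios
#' and asymptotes over `[0, 1]` with `pmin < pmax`. Chains start from
#' the ML estimate, jittered independently per chain.
#'
#' @inheritParams cline_loglik
#' @param chains number of independent chains (default 3).
#' @param burn_in generations discarded (and used for proposal
#'   adaptation) per chain (default 1e4).
#' @param generations post-burn-in generations per chain (default 1e5).
#' @param thin keep every `thin`-th generation (default 10).
#' @param seed RNG seed; if `NULL` the current RNG state is used.
#' @param ml optional precomputed [fit_cline_ml()] result.
#' @return object of class `cline_mcmc`: pooled `draws` matrix (one
#'   column per parameter, inactive parameters constant), per-chain
#'   draws, per-parameter acceptance rates and split-free Gelman-Rubin
#'   `rhat`, the ML fit, and bookkeeping fields. A warning is attached
#'   (field `convergence_warning`) when any rhat exceeds 1.1.
#' @export
cline_mcmc <- function(spec, cells, chains = 3, burn_in = 1e4,
                       generations = 1e5, thin = 10, seed = NULL,
                       ml = NULL, allele_counts = c("2n", "n"),
                       eps = 1e-6) {
  allele_counts <- match.arg(allele_counts)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ml))
    ml <- fit_cline_ml(spec, cells, allele_counts, eps = eps)
  d <- .cells_xqm(cells, allele_counts)
  q <- if (ml$orientation == "decreasing") 1 - d$q else d$q
  bounds <- .cline_bounds(d$x)
  active <- c(TRUE, TRUE,
              spec$scaling == "free", spec$scaling == "free",
              rep(spec$tails == "both", 4))
  th0 <- .par_vec(ml$params)
  lower <- bounds$lower; upper <- bounds$upper
  scale0 <- pmax((upper - lower) * 0.02, 1e-6)
  chain_res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    st <- th0
    jit <- stats::rnorm(8, 0, 0.01 * (upper - lower))
    st[active] <- st[active] + jit[active]
    st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    if (active[3] && st[3] >= st[4]) {
      mid <- (st[3] + st[4]) / 2
      st[3] <- max(mid - 1e-3, 0); st[4] <- min(mid + 1e-3, 1)
    }
    chain_res[[ch]] <- .cline_mcmc_cpp(
      st, active, spec$tails == "both", d$x, q, d$m,
      lower, upper, scale0, as.integer(burn_in), as.integer(generations),
      as.integer(thin), eps)
  }
  draws_list <- lapply(chain_res, function(r) {
    colnames(r$draws) <- .PAR_NAMES
    r$draws
  })
  pooled <- do.call(rbind, draws_list)
  rhat <- rep(NA_real_, 8); names(rhat) <- .PAR_NAMES
  if (chains >= 2) {
    for (j in which(active))
      rhat[j] <- .rhat(lapply(draws_list, function(dd) dd[, j]))
  }
  acc <- do.call(rbind, lapply(chain_res, `[[`, "acceptance"))
  colnames(acc) <- .PAR_NAMES
  conv_warn <- NULL
  if (any(rhat[active] > 1.1, na.rm = TRUE)) {
    conv_warn <- paste("Gelman-Rubin rhat exceeds 1.1 for:",
                       paste(.PAR_NAMES[active][rhat[active] > 1.1],
                             collapse = ", "))
    warning(conv_warn)
  }
  structure(list(draws = pooled, chains = draws_list, rhat = rhat,
                 acceptance = acc, ml = ml, spec = spec,
                 orientation = ml$orientation, active = active,
                 x_range = range(d$x), allele_counts = allele_counts,
                 convergence_warning = conv_warn),
            class = "cline_mcmc")
}

#' Posterior credible intervals and fuzzy cline envelope
#'
#' Centre and width credible intervals are the 2.5-97.5% quantiles of
#' the pooled posterior draws. The envelope is the pointwise 2.5/50/
#' 97.5% band of the cline curve evaluated over the draws at each
#' position, on the data orientation (decreasing clines are reflected
#' back).
#'
#' @param mcmc a [cline_mcmc] result.
#' @param x_grid positions (km) at which to evaluate the envelope;
#'   default 101 points over the observed range.
#' @param level credible level (default 0.95).
#' @param max_envelope_draws cap on the number of draws used for the
#'   envelope (the intervals always use all draws).
#' @return list with `centre_ci`, `width_ci` (named 2-vectors),
#'   `centre_median`, `width_median`, and `envelope`, a data.frame
#'   `x_km, p_lo, p_med, p_hi`.
#' @export
credible_region <- function(mcmc, x_grid = NULL, level = 0.95,
                            max_envelope_draws = 5000) {
  draws <- mcmc$draws
  if (nrow(draws) < 1000) stop("need at least 1000 retained draws")
  a <- (1 - level) / 2
  probs <- c(a, 1 - a)
  if (is.null(x_grid))
    x_grid <- seq(mcmc$x_range[1], mcmc$x_range[2], length.out = 101)
  centre_ci <- stats::quantile(draws[, "centre"], probs, names = FALSE)
  width_ci <- stats::quantile(draws[, "width"], probs, names = FALSE)
  sub <- draws
  if (nrow(sub) > max_envelope_draws)
    sub <- sub[round(seq(1, nrow(sub), length.out = max_envelope_draws)), ,
               drop = FALSE]
  tails <- mcmc$spec$tails == "both"
  env <- vapply(seq_along(x_grid), function(i) {
    p <- .cline_value_rows(x_grid[i], sub, tails)
    if (mcmc$orientation == "decreasing") p <- 1 - p
    stats::quantile(p, c(a, 0.5, 1 - a), names = FALSE)
  }, numeric(3))
  list(centre_ci = centre_ci, width_ci = width_ci,
       centre_median = stats::median(draws[, "centre"]),
       width_median = stats::median(draws[, "width"]),
       envelope = data.frame(x_km = x_grid, p_lo = env[1, ],
                             p_med = env[2, ], p_hi = env[3, ]))
}

# cline_value for a scalar x over a matrix of parameter rows
.cline_value_rows <- function(x, th, tails) {
  c0 <- th[, 1]; w <- th[, 2]
  f <- stats::plogis(4 * (x - c0) / w)
  if (tails) {
    dL <- th[, 5]; dR <- th[, 6]; tL <- th[, 7]; tR <- th[, 8]
    left <- x < c0 - dL
    if (any(left))
      f[left] <- (1 / (1 + exp(4 * dL[left] / w[left]))) *
        exp((4 * tL[left] * (x - c0[left] + dL[left]) / w[left]) /
              (1 + exp(-4 * dL[left] / w[left])))
    right <- x > c0 + dR
    if (any(right))
      f[right] <- 1 - (1 / (1 + exp(4 * dR[right] / w[right]))) *
        exp((-4 * tR[right] * (x - c0[right] - dR[right]) / w[right]) /
              (1 + exp(-4 * dR[right] / w[right])))
  }
  th[, 3] + (th[, 4] - th[, 3]) * f
}

#' Offset between two cline centres with a credible interval
#'
#' The point offset is the absolute difference of the posterior median
#' centres; the interval comes from the 2.5-97.5% quantiles of
#' differences of paired posterior draws (the two posteriors are
#' independent, so the pairing is arbitrary).
#'
#' @param fit_a,fit_b [cline_mcmc] (or [fit_cline]) results on the
#'   same transect coordinate system.
#' @return list with `offset_km`, `ci` (signed difference a - b), and
#'   the two medians.
#' @export
centre_offset <- function(fit_a, fit_b) {
  ga <- if (inherits(fit_a, "cline_fit")) fit_a$mcmc else fit_a
  gb <- if (inherits(fit_b, "cline_fit")) fit_b$mcmc else fit_b
  ta <- attr(ga, "transect_name"); tb <- attr(gb, "transect_name")
  if (!is.null(ta) && !is.null(tb) && !identical(ta, tb))
    stop("fits are from different transects: ", ta, " vs ", tb)
  ca <- ga$draws[, "centre"]; cb <- gb$draws[, "centre"]
  n <- min(length(ca), length(cb))
  diffs <- ca[seq_len(n)] - cb[seq_len(n)]
  list(offset_km = abs(stats::median(ca) - stats::median(cb)),
       ci = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
       median_a = stats::median(ca), median_b = stats::median(cb))
}

.derive_seed <- function(...) {
  s <- paste(..., collapse = "|")
  as.integer(sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483647L)
}

#' Full cline analysis of one locus along one transect
#'
#' Projects grid cells onto the transect, selects a cline model by
#' AICc (or uses a forced model), samples its posterior by MCMC and
#' summarises the credible region.
#'
#' @param grid a `frequency_grid`.
#' @param t a [transect].
#' @param locus `"A"`, `"B"` or `"C"`.
#' @param model `"select"` for AICc selection over all six models, or
#'   a [cline_model_spec] to force one (e.g.
#'   `cline_model_spec("fixed", "both")`).
#' @inheritParams cline_mcmc
#' @return object of class `cline_fit` with fields `cells`,
#'   `model_table` (when selected), `ml`, `mcmc`, `region`, `locus`,
#'   `transect`.
#' @export
fit_cline <- function(grid, t, locus = c("A", "B", "C"), model = "select",
                      chains = 3, burn_in = 1e4, generations = 1e5,
                      thin = 10, seed = NULL,
                      allele_counts = c("2n", "n")) {
  locus <- match.arg(locus)
  allele_counts <- match.arg(allele_counts)
  cells <- project_cells(grid, t, locus)
  if (is.null(seed)) seed <- .derive_seed(t$name, locus)
  model_table <- NULL
  if (identical(model, "select")) {
    model_table <- compare_cline_models(cells, allele_counts)
    spec <- cline_model_spec(model_table$scaling[1], model_table$tails[1])
    ml <- attr(model_table, "fits")[[1]]
  } else {
    stopifnot(inherits(model, "cline_model_spec"))
    spec <- model
    ml <- fit_cline_ml(spec, cells, allele_counts)
  }
  mcmc <- cline_mcmc(spec, cells, chains = chains, burn_in = burn_in,
                     generations = generations, thin = thin, seed = seed,
                     ml = ml, allele_counts = allele_counts)
  attr(mcmc, "transect_name") <- t$name
  region <- credible_region(mcmc)
  structure(list(cells = cells, model_table = model_table, spec = spec,
                 ml = ml, mcmc = mcmc, region = region, locus = locus,
                 transect = t$name, seed = seed),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  r <- x$region
  cat("cline_fit: locus ", x$locus, " along '", x$transect, "' (",
      nrow(x$cells), " cells)\n", sep = "")
  cat("  model: scaling = ", x$spec$scaling, ", tails = ", x$spec$tails,
      "; orientation ", x$mcmc$orientation, "\n", sep = "")
  cat(sprintf("  centre: %.0f km (95%% CI %.0f-%.0f)\n",
              r$centre_median, r$centre_ci[1], r$centre_ci[2]))
  cat(sprintf("  width:  %.0f km (95%% CI %.0f-%.0f)\n",
              r$width_median, r$width_ci[1], r$width_ci[2]))
  invisible(x)
}

#' Write a cline fit report as JSON and its envelope as CSV
#'
#' @param fit a `cline_fit`.
#' @param json_path,envelope_path output paths (either may be `NULL`
#'   to skip).
#' @export
write_cline_fit <- function(fit, json_path = NULL, envelope_path = NULL) {
  if (!is.null(json_path)) {
    act <- fit$mcmc$active
    qs <- apply(fit$mcmc$draws[, act, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975))
    report <- list(
      locus = fit$locus, transect = fit$transect,
      model = list(scaling = fit$spec$scaling, tails = fit$spec$tails,
                   k = fit$spec$k),
      orientation = fit$mcmc$orientation,
      ml_params = unclass(fit$ml$params), logL = fit$ml$logL,
      aicc_table = if (!is.null(fit$model_table))
        fit$model_table[, c("scaling", "tails", "k", "logL", "aicc")],
      posterior_quantiles = as.data.frame(t(qs)),
      rhat = as.list(fit$mcmc$rhat[act]),
      acceptance = colMeans(fit$mcmc$acceptance[, act, drop = FALSE]),
      centre_ci = fit$region$centre_ci, width_ci = fit$region$width_ci,
      seed = fit$seed)
    report <- Filter(Negate(is.null), report)
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  if (!is.null(envelope_path))
    utils::write.csv(fit$region$envelope, envelope_path, row.names = FALSE)
  invisible(fit)
}
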