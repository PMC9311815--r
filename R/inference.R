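#' @name inference_models
#' @title Regression stage: beta, AR1 mixed and log-linear models
#' @description
#' Implements the statistical chain applied to the movement outcomes: a
#' chi-squared association screen between categorical covariates; beta
#' regression (logit link, constant precision) for the fraction of time
#' away; a Box-Cox transformed linear mixed model with a per-animal random
#' intercept and AR1 day-to-day error correlation for daily distance; an
#' ordinary log10-scale linear model for home-range area (>90 ha outliers
#' excluded); type-II likelihood-ratio tests; manual backward elimination;
#' a >20% coefficient-change confounding check; Tukey-adjusted pairwise
#' contrasts of marginal means; and back-transformed rainfall prediction
#' curves.
NULL

## ---- model-fit container ----------------------------------------------------

new_modelfit <- function(kind, coefficients, se, vcov, terms, response,
                         transform, scale, loglik, npar, df_residual,
                         data, refit, assign_map, extra = list()) {
  structure(c(list(kind = kind, coefficients = coefficients, se = se,
                   vcov = vcov, terms = terms, response = response,
                   transform = transform, scale = scale, loglik = loglik,
                   npar = npar, df_residual = df_residual, data = data,
                   refit = refit, assign_map = assign_map), extra),
            class = "cat_modelfit")
}

#' @export
print.cat_modelfit <- function(x, ...) {
  cat(sprintf("<cat_modelfit:%s> response %s; terms: %s\n", x$kind,
              x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  print(data.frame(estimate = x$coefficients, se = x$se))
  cat(sprintf("logLik %.3f (%d parameters)\n", x$loglik, x$npar))
  invisible(x)
}

#' Coefficient table of a model fit
#'
#' @param fit A `cat_modelfit`.
#' @return data.frame `variable, level, estimate, se, stat, p` in the shape
#'   used by the report writer.
#' @export
coef_table <- function(fit) {
  est <- fit$coefficients; se <- fit$se
  stat <- est / se
  df <- fit$df_residual
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  cn <- names(est)
  variable <- character(length(cn)); level <- character(length(cn))
  for (i in seq_along(cn)) {
    hit <- ""
    for (tm in fit$terms) if (startsWith(cn[i], tm) && nchar(tm) > nchar(hit)) hit <- tm
    variable[i] <- if (cn[i] == "(Intercept)") "(Intercept)" else if (nzchar(hit)) hit else cn[i]
    level[i] <- if (nzchar(hit)) substring(cn[i], nchar(hit) + 1L) else ""
  }
  data.frame(variable = variable, level = level, estimate = est, se = se,
             stat = stat, p = p, row.names = NULL)
}

# model matrix + map from term labels to coefficient columns; unused factor
# levels are dropped and aliased columns pruned (QR pivoting) so small
# cohorts with empty cells still fit
build_mm <- function(data, terms) {
  dd <- droplevels(data)
  # single-level factors carry no information and break model.matrix
  ok <- vapply(terms, function(tm) {
    v <- dd[[tm]]
    is.numeric(v) || nlevels(as.factor(v)) >= 2L
  }, logical(1))
  live <- terms[ok]
  f <- if (length(live)) reformulate(live) else ~1
  X <- model.matrix(f, dd)
  asg <- attr(X, "assign")
  if (ncol(X) > 1L) {
    q <- qr(X)
    if (q$rank < ncol(X)) {
      keep <- sort(q$pivot[seq_len(q$rank)])
      X <- X[, keep, drop = FALSE]
      asg <- asg[keep]
    }
  }
  labs <- attr(stats::terms(f), "term.labels")
  map <- lapply(seq_along(labs), function(i) colnames(X)[asg == i])
  names(map) <- labs
  for (tm in terms[!ok]) map[[tm]] <- character(0)
  list(X = X, map = map)
}

## ---- association screen -----------------------------------------------------

#' Chi-squared association screen between categorical covariates
#'
#' Tests every pair of categorical covariates with Pearson's chi-squared
#' test; strongly associated pairs (p below `alpha`) are flagged and, per
#' pair, the variable flagged against more partners (tie broken towards the
#' later column) is proposed for exclusion. When any expected cell count
#' falls below 1 the p-value is computed by seeded Monte Carlo simulation.
#'
#' @param covariates data.frame of factors (only factor/character columns
#'   are screened).
#' @param alpha Flagging level (default 0.05).
#' @param sim_B Monte-Carlo replicates when simulation is needed.
#' @param sim_seed Seed for the simulated p-values.
#' @return List with `pairs` (data.frame `var1, var2, p, simulated,
#'   flagged`) and `exclude` (character vector).
#' @export
association_screen <- function(covariates, alpha = 0.05, sim_B = 2000,
                               sim_seed = 1L) {
  cols <- names(covariates)[vapply(covariates, function(c)
    is.factor(c) || is.character(c), logical(1))]
  if (length(cols) < 2L)
    return(list(pairs = data.frame(var1 = character(), var2 = character(),
                                   p = numeric(), simulated = logical(),
                                   flagged = logical()),
                exclude = character()))
  cmb <- utils::combn(cols, 2L)
  res <- data.frame(var1 = cmb[1L, ], var2 = cmb[2L, ], p = NA_real_,
                    simulated = FALSE, flagged = FALSE)
  for (i in seq_len(nrow(res))) {
    tab <- table(covariates[[res$var1[i]]], covariates[[res$var2[i]]])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) next   # degenerate: untestable
    exp_min <- min(outer(rowSums(tab), colSums(tab)) / sum(tab))
    if (exp_min < 1) {
      res$simulated[i] <- TRUE
      p <- withr_seed(sim_seed, suppressWarnings(
        chisq.test(tab, simulate.p.value = TRUE, B = sim_B)$p.value))
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    res$p[i] <- p
  }
  res$flagged <- !is.na(res$p) & res$p < alpha
  counts <- setNames(numeric(length(cols)), cols)
  for (i in which(res$flagged)) {
    counts[res$var1[i]] <- counts[res$var1[i]] + 1
    counts[res$var2[i]] <- counts[res$var2[i]] + 1
  }
  exclude <- character()
  for (i in which(res$flagged)) {
    v1 <- res$var1[i]; v2 <- res$var2[i]
    pick <- if (counts[v1] > counts[v2]) v1
            else if (counts[v2] > counts[v1]) v2
            else cols[max(match(v1, cols), match(v2, cols))]  # tie: later column
    exclude <- union(exclude, pick)
  }
  list(pairs = res, exclude = exclude)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## ---- beta regression --------------------------------------------------------

#' Beta regression with logit mean link and constant precision
#'
#' Maximum likelihood for responses strictly in (0,1):
#' `y ~ Beta(mu*phi, (1-mu)*phi)` with `logit(mu) = X beta` and a constant
#' precision `phi` (identity link). Standard errors come from the inverse
#' observed information. The pseudo-R-squared is the squared correlation
#' between the fitted linear predictor and the logit of the response.
#'
#' @param data Model data.frame.
#' @param response Name of the response column (values in (0,1)).
#' @param terms Character vector of model terms (may be empty for an
#'   intercept-only model).
#' @return A `cat_modelfit` of kind `"beta"` with `scale$precision_phi` and
#'   `extra` element `pseudo_r2`.
#' @export
fit_beta_regression <- function(data, response, terms = character()) {
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0 | y >= 1))
    stop("precondition error: beta-regression response must lie strictly in ",
         "(0,1); apply the boundary adjustment (see percent_time_away)")
  mm <- build_mm(data, terms)
  X <- mm$X
  p <- ncol(X)
  negll <- function(par) {
    eta <- drop(X %*% par[seq_len(p)])
    mu <- stats::plogis(eta)
    phi <- exp(par[p + 1L])
    ll <- sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  start_beta <- tryCatch(lm.fit(X, stats::qlogis(y))$coefficients,
                         error = function(e) rep(0, p))
  start_beta[!is.finite(start_beta)] <- 0
  mu0 <- stats::plogis(drop(X %*% start_beta))
  v0 <- max(stats::var(y - mu0), 1e-6)
  phi0 <- max(mean(mu0 * (1 - mu0)) / v0 - 1, 1)
  opt <- optim(c(start_beta, log(phi0)), negll, method = "BFGS",
               hessian = TRUE, control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("fit error: beta-regression optimizer did not converge (code ",
         opt$convergence, "); value ", signif(opt$value, 6))
  H <- opt$hessian
  V <- tryCatch(solve(H), error = function(e) {
    warning("singular information matrix; using pseudo-inverse")
    sv <- svd(H); sv$v %*% diag(ifelse(sv$d > 1e-10, 1 / sv$d, 0)) %*% t(sv$u)
  })
  beta <- setNames(opt$par[seq_len(p)], colnames(X))
  eta <- drop(X %*% beta)
  pr2 <- if (stats::sd(eta) > 0) cor(eta, stats::qlogis(y))^2 else 0
  refit <- function(new_terms) fit_beta_regression(data, response, new_terms)
  new_modelfit("beta", beta, sqrt(pmax(diag(V)[seq_len(p)], 0)),
               V[seq_len(p), seq_len(p), drop = FALSE], terms, response,
               transform = list(link = "logit"),
               scale = list(precision_phi = unname(exp(opt$par[p + 1L]))),
               loglik = -opt$value, npar = p + 1L, df_residual = Inf,
               data = data, refit = refit, assign_map = mm$map,
               extra = list(pseudo_r2 = pr2))
}

## ---- Box-Cox ----------------------------------------------------------------

#' Box-Cox lambda by profile likelihood
#'
#' Profiles the Box-Cox log-likelihood of a fixed-effects linear model over
#' an equidistant lambda grid (default -2..2 by 0.01), using the normalised
#' transform `(y^l - 1)/l` (log at `l = 0`) with its Jacobian term.
#'
#' @param data Model data.frame (response strictly positive).
#' @param response Response column name.
#' @param terms Model terms for the profiling linear model.
#' @param grid Lambda grid.
#' @return The maximising lambda (warns at the grid endpoints).
#' @export
boxcox_lambda <- function(data, response, terms = character(),
                          grid = seq(-2, 2, by = 0.01)) {
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0))
    stop("validation error: Box-Cox requires strictly positive responses")
  X <- build_mm(data, terms)$X
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(grid, function(l) {
    z <- if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
    rss <- sum(lm.fit(X, z)$residuals^2)
    -n / 2 * log(rss / n) + (l - 1) * slog
  }, numeric(1))
  lam <- grid[which.max(ll)]
  if (lam %in% range(grid))
    warning("boundary warning: Box-Cox lambda at grid endpoint (", lam, ")")
  lam
}

# response transform used by the distance model
bc_transform <- function(y, lambda, mode = c("power", "normalized")) {
  mode <- match.arg(mode)
  if (mode == "power") y^lambda
  else if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

bc_inverse <- function(z, lambda, mode = c("power", "normalized")) {
  mode <- match.arg(mode)
  if (mode == "power") {
    if (lambda <= 0) stop("back-transform domain error: lambda <= 0")
    if (any(z < 0)) stop("back-transform domain error: negative predictor")
    z^(1 / lambda)
  } else {
    if (abs(lambda) < 1e-12) exp(z) else {
      base <- lambda * z + 1
      if (any(base < 0)) stop("back-transform domain error")
      base^(1 / lambda)
    }
  }
}

## ---- AR1 random-intercept mixed model ---------------------------------------

#' Linear mixed model with per-animal intercept and AR1 errors
#'
#' Fits, by maximum likelihood, `y* = X beta + b_cat + e` where `y* =
#' distance^lambda` (simple-power Box-Cox; the normalised variant by
#' `boxcox_mode = "normalized"`), `b_cat ~ N(0, tau2)` and within-animal
#' errors follow an AR1 process over calendar-day offsets: `cor(e_j, e_k) =
#' rho^|day_j - day_k|` (missing days decay the correlation). `sigma2` and
#' `beta` are profiled; the optimiser works on the variance ratio
#' `tau2/sigma2 >= 0` and `rho` in (-0.98, 0.98), so the degenerate
#' `tau2 = 0` boundary is reachable exactly.
#'
#' @param data Daily data.frame (one row per animal-day).
#' @param response Response column (positive distances, metres).
#' @param terms Fixed-effect terms.
#' @param lambda Box-Cox exponent (e.g. from [boxcox_lambda()]).
#' @param cat_col,day_col Grouping and date columns.
#' @param boxcox_mode `"power"` (default, `y^lambda`) or `"normalized"`.
#' @param fix Optional named list fixing variance parameters, e.g.
#'   `list(ratio = 0, rho = 0)` for the degenerate (OLS) limit.
#' @return A `cat_modelfit` of kind `"lmm_ar1"` with `scale` components
#'   `tau2`, `sigma2`, `ar1_rho`.
#' @export
fit_distance_lmm <- function(data, response, terms, lambda,
                             cat_col = "cat_id", day_col = "date",
                             boxcox_mode = c("power", "normalized"),
                             fix = NULL) {
  boxcox_mode <- match.arg(boxcox_mode)
  y0 <- data[[response]]
  if (any(!is.finite(y0)) || any(y0 <= 0))
    stop("validation error: distances must be positive")
  y <- bc_transform(y0, lambda, boxcox_mode)
  mm <- build_mm(data, terms)
  X <- mm$X
  p <- ncol(X)
  g <- as.character(data[[cat_col]])
  dayn <- as.numeric(data[[day_col]])
  idx <- split(seq_along(y), g)
  if (length(idx) < 2L) stop("need >= 2 animals")
  N <- length(y)

  profile <- function(ratio, rho) {
    XtWX <- matrix(0, p, p); XtWy <- numeric(p); yWy <- 0; logdet <- 0
    for (ii in idx) {
      ni <- length(ii)
      dd <- abs(outer(dayn[ii], dayn[ii], "-"))
      V <- ratio + rho^dd          # ratio*J + AR1 correlation
      diag(V) <- ratio + 1
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Xi <- backsolve(ch, X[ii, , drop = FALSE], transpose = TRUE)
      yi <- backsolve(ch, y[ii], transpose = TRUE)
      XtWX <- XtWX + crossprod(Xi)
      XtWy <- XtWy + crossprod(Xi, yi)
      yWy <- yWy + sum(yi^2)
    }
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    rss <- max(yWy - sum(XtWy * beta), 1e-12)
    sigma2 <- rss / N
    nll <- 0.5 * (N * log(2 * pi * sigma2) + logdet + N)
    list(nll = nll, beta = drop(beta), sigma2 = sigma2, XtWX = XtWX)
  }

  if (!is.null(fix)) {
    ratio <- if (!is.null(fix$ratio)) fix$ratio else 0
    rho <- if (!is.null(fix$rho)) fix$rho else 0
    pr <- profile(ratio, rho)
  } else {
    obj <- function(par) {
      pr <- profile(par[1L], par[2L])
      if (is.null(pr)) 1e10 else pr$nll
    }
    opt <- optim(c(0.5, 0), obj, method = "L-BFGS-B",
                 lower = c(0, -0.98), upper = c(100, 0.98),
                 control = list(factr = 1e5))
    ratio <- opt$par[1L]; rho <- opt$par[2L]
    pr <- profile(ratio, rho)
  }
  if (is.null(pr)) stop("fit error: variance structure not positive definite")
  if (is.null(fix) && ratio < 1e-8)
    message("note: random-intercept variance at the zero boundary")
  beta <- setNames(pr$beta, colnames(X))
  V <- pr$sigma2 * solve(pr$XtWX)
  refit <- function(new_terms)
    fit_distance_lmm(data, response, new_terms, lambda, cat_col, day_col,
                     boxcox_mode, fix)
  new_modelfit("lmm_ar1", beta, sqrt(pmax(diag(V), 0)), V, terms, response,
               transform = list(boxcox = boxcox_mode, lambda = lambda),
               scale = list(tau2 = ratio * pr$sigma2, sigma2 = pr$sigma2,
                            ar1_rho = rho),
               loglik = -pr$nll, npar = p + 3L, df_residual = N - p,
               data = data, refit = refit, assign_map = mm$map,
               extra = list(cat_col = cat_col, day_col = day_col))
}

## ---- home-range linear model ------------------------------------------------

#' Log-scale linear model for home-range area
#'
#' Excludes areas above `outlier_ha` (count reported), then ordinary least
#' squares on `log10(area)` (natural log via `log_base = exp(1)`). A
#' Shapiro-Wilk statistic on the residuals is reported for inspection and
#' never used to reject automatically.
#'
#' @param data data.frame with the area column and covariates.
#' @param response Area column name (hectares, positive).
#' @param terms Model terms.
#' @param outlier_ha Exclusion threshold (default 90 ha).
#' @param log_base Log base (default 10).
#' @return A `cat_modelfit` of kind `"lm"` with extras `n_excluded`,
#'   `shapiro_w`, `r_squared`.
#' @export
fit_homerange_lm <- function(data, response, terms = character(),
                             outlier_ha = 90, log_base = 10) {
  a <- data[[response]]
  if (any(!is.finite(a)) || any(a <= 0))
    stop("validation error: areas must be positive")
  keep <- a <= outlier_ha
  n_excl <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  mm <- build_mm(d, terms)
  X <- mm$X
  z <- log(d[[response]], base = log_base)
  if (nrow(X) <= ncol(X)) stop("fit error: fewer rows than parameters")
  fit <- lm.fit(X, z)
  res <- fit$residuals
  n <- length(z); p <- ncol(X)
  sigma2_ml <- sum(res^2) / n
  ll <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  V <- sum(res^2) / (n - p) * solve(crossprod(X))
  sw <- if (n >= 3 && n <= 5000 && stats::sd(res) > 0)
    unname(shapiro.test(res)$statistic) else NA_real_
  r2 <- if (stats::var(z) > 0) 1 - sum(res^2) / sum((z - mean(z))^2) else NA_real_
  refit <- function(new_terms)
    fit_homerange_lm(data, response, new_terms, outlier_ha, log_base)
  new_modelfit("lm", setNames(fit$coefficients, colnames(X)),
               sqrt(pmax(diag(V), 0)), V, terms, response,
               transform = list(log_base = log_base),
               scale = list(sigma2 = sigma2_ml), loglik = ll, npar = p + 1L,
               df_residual = n - p, data = d, refit = refit,
               assign_map = mm$map,
               extra = list(n_excluded = n_excl, shapiro_w = sw,
                            r_squared = r2))
}

## ---- type-II tests, elimination, confounding --------------------------------

#' Type-II analysis of variance by likelihood ratio
#'
#' For each term, compares the fitted model against the model omitting that
#' term while retaining all others; test statistic is `2 * (llik_full -
#' llik_reduced)` on as many degrees of freedom as parameters removed. The
#' result is invariant to the order of terms in the formula.
#'
#' @param fit A `cat_modelfit` (its stored `refit` closure is reused).
#' @return data.frame `term, df, statistic, p`, classed `cat_anova`.
#' @export
anova_type2 <- function(fit) {
  terms <- fit$terms
  out <- data.frame(term = terms, df = NA_integer_, statistic = NA_real_,
                    p = NA_real_)
  for (i in seq_along(terms)) {
    red <- tryCatch(fit$refit(setdiff(terms, terms[i])),
                    error = function(e) NULL)
    if (is.null(red)) next  # term marked untestable
    stat <- max(0, 2 * (fit$loglik - red$loglik))
    df <- fit$npar - red$npar
    if (df < 1L) next  # term contributed no parameters: untestable
    out$df[i] <- df
    out$statistic[i] <- stat
    out$p[i] <- pchisq(stat, df, lower.tail = FALSE)
  }
  class(out) <- c("cat_anova", "data.frame")
  out
}

#' Manual backward elimination by type-II p-values
#'
#' Iteratively refits and removes the term with the largest type-II p-value
#' above `alpha`, stopping when every remaining term tests at or below
#' `alpha`.
#'
#' @param data Model data.frame.
#' @param full_terms Terms of the full model.
#' @param alpha Retention threshold (e.g. 0.05, or 0.10 for the home-range
#'   model).
#' @param fitter Function `(data, terms) -> cat_modelfit`, e.g. from
#'   [make_fitter()].
#' @return List `fit` (final model) and `trace` (data.frame of removals:
#'   `step, removed, p`).
#' @export
backward_eliminate <- function(data, full_terms, alpha, fitter) {
  terms <- full_terms
  trace <- data.frame(step = integer(), removed = character(), p = numeric())
  fit <- fitter(data, terms)
  step <- 0L
  while (length(terms) > 0L) {
    an <- anova_type2(fit)
    testable <- which(!is.na(an$p))
    if (!length(testable)) break
    worst <- testable[which.max(an$p[testable])]
    if (an$p[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = an$term[worst],
                                     p = an$p[worst]))
    terms <- setdiff(terms, an$term[worst])
    fit <- fitter(data, terms)
  }
  list(fit = fit, trace = trace)
}

#' Confounding check: >20% coefficient change
#'
#' For every ordered pair of terms (t, u), compares the coefficients of `t`
#' between the model containing all of `base_terms` (reference) and the
#' model omitting `u`; pairs whose largest relative change exceeds
#' `threshold` are flagged. Coefficients with reference magnitude below
#' `eps` are skipped with a note.
#'
#' @param data Model data.frame.
#' @param base_terms Terms of the reference model.
#' @param fitter Function `(data, terms) -> cat_modelfit`.
#' @param threshold Relative-change threshold (default 0.20).
#' @param eps Minimum reference magnitude (default 1e-8).
#' @return data.frame `term, against, max_rel_change, flagged, note`.
#' @export
confounding_check <- function(data, base_terms, fitter, threshold = 0.20,
                              eps = 1e-8) {
  if (length(base_terms) < 2L)
    return(data.frame(term = character(), against = character(),
                      max_rel_change = numeric(), flagged = logical(),
                      note = character()))
  full <- fitter(data, base_terms)
  out <- NULL
  for (u in base_terms) {
    red <- fitter(data, setdiff(base_terms, u))
    for (tm in setdiff(base_terms, u)) {
      cn <- intersect(full$assign_map[[tm]], names(red$coefficients))
      ref <- full$coefficients[cn]
      alt <- red$coefficients[cn]
      usable <- abs(ref) >= eps
      note <- if (any(!usable)) "near-zero reference coefficient(s) skipped" else ""
      mrc <- if (any(usable)) max(abs(alt[usable] - ref[usable]) / abs(ref[usable]))
             else NA_real_
      out <- rbind(out, data.frame(term = tm, against = u,
                                   max_rel_change = mrc,
                                   flagged = isTRUE(mrc > threshold),
                                   note = note))
    }
  }
  rownames(out) <- NULL
  out
}

## ---- marginal means, contrasts, predictions ---------------------------------

# terms that actually contributed coefficients (single-level factors are
# dropped from the design by build_mm but remain in fit$terms)
live_terms <- function(fit) {
  if (is.null(fit$assign_map)) return(fit$terms)
  lt <- names(fit$assign_map)[lengths(fit$assign_map) > 0L]
  intersect(fit$terms, lt)
}

# reference-grid model matrix rows: one per level of `factor`, other factors
# at their reference level, numeric covariates at their data mean
reference_grid <- function(fit, factor) {
  d <- droplevels(fit$data)
  lv <- levels(as.factor(d[[factor]]))
  grid <- d[rep(1L, length(lv)), , drop = FALSE]
  for (v in names(d)) {
    if (is.numeric(d[[v]])) grid[[v]] <- mean(d[[v]], na.rm = TRUE)
    else if (is.factor(d[[v]])) grid[[v]] <- factor(levels(d[[v]])[1L],
                                                    levels = levels(d[[v]]))
  }
  grid[[factor]] <- factor(lv, levels = levels(as.factor(d[[factor]])))
  X <- model.matrix(reformulate(live_terms(fit)), grid)
  X <- X[, names(fit$coefficients), drop = FALSE]
  rownames(X) <- lv
  X
}

#' Tukey-adjusted pairwise comparisons of marginal means
#'
#' Estimated marginal means are taken on a reference grid (other factors at
#' their reference level, numeric covariates at their mean); all pairwise
#' differences are tested with standard errors from the coefficient
#' covariance and Tukey (studentized-range) adjusted p-values. A two-level
#' factor reduces to the coefficient's own test (noted in the result).
#'
#' @param fit A `cat_modelfit` containing `factor` among its terms.
#' @param factor Name of the factor to compare.
#' @return List `emmeans` (level, emm, se) and `contrasts` (data.frame
#'   `level1, level2, estimate, se, statistic, p_tukey, note`).
#' @export
posthoc_pairwise <- function(fit, factor) {
  if (!factor %in% fit$terms) stop(factor, " is not a term of the model")
  X <- reference_grid(fit, factor)
  b <- fit$coefficients; V <- fit$vcov
  emm <- drop(X %*% b)
  se_emm <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  lv <- rownames(X)
  k <- length(lv)
  prs <- utils::combn(k, 2L)
  note <- if (k == 2L) "two-level factor: equals the coefficient test" else ""
  df <- fit$df_residual
  out <- NULL
  for (j in seq_len(ncol(prs))) {
    i1 <- prs[1L, j]; i2 <- prs[2L, j]
    L <- X[i1, ] - X[i2, ]
    est <- sum(L * b)
    se <- sqrt(max(drop(t(L) %*% V %*% L), 0))
    tt <- est / se
    p <- if (k == 2L) {
      if (is.finite(df)) 2 * stats::pt(-abs(tt), df) else 2 * pnorm(-abs(tt))
    } else {
      ptukey(sqrt(2) * abs(tt), nmeans = k,
             df = if (is.finite(df)) df else 1e6, lower.tail = FALSE)
    }
    out <- rbind(out, data.frame(level1 = lv[i1], level2 = lv[i2],
                                 estimate = est, se = se, statistic = tt,
                                 p_tukey = p, note = note))
  }
  list(emmeans = data.frame(level = lv, emm = emm, se = se_emm,
                            row.names = NULL),
       contrasts = out)
}

#' Predicted daily distance at given rainfall levels
#'
#' Evaluates the fitted AR1 mixed model at each rainfall amount with factors
#' at their reference level (or averaged over the sample with
#' `mode = "mean"`) and numeric covariates at their mean, builds a 95%
#' Wald interval on the transformed scale, and back-transforms estimate and
#' interval through the inverse Box-Cox power.
#'
#' @param fit A `cat_modelfit` of kind `"lmm_ar1"` whose terms include the
#'   rainfall column.
#' @param rainfall_levels Numeric vector of rainfall amounts (mm).
#' @param rain_col Name of the rainfall term (default `"rainfall_mm"`).
#' @param mode `"reference"` (default) or `"mean"` marginalisation for
#'   factors.
#' @return data.frame `rainfall_mm, mean_m, lo95_m, hi95_m`.
#' @export
predict_rainfall_curve <- function(fit, rainfall_levels,
                                   rain_col = "rainfall_mm",
                                   mode = c("reference", "mean")) {
  mode <- match.arg(mode)
  if (!rain_col %in% fit$terms) stop("rainfall term not in the model")
  d <- droplevels(fit$data)
  out <- data.frame(rainfall_mm = rainfall_levels, mean_m = NA_real_,
                    lo95_m = NA_real_, hi95_m = NA_real_)
  lambda <- fit$transform$lambda
  bmode <- fit$transform$boxcox
  for (i in seq_along(rainfall_levels)) {
    if (mode == "reference") {
      grid <- d[1L, , drop = FALSE]
      for (v in names(d)) {
        if (is.numeric(d[[v]])) grid[[v]] <- mean(d[[v]], na.rm = TRUE)
        else if (is.factor(d[[v]]))
          grid[[v]] <- factor(levels(d[[v]])[1L], levels = levels(d[[v]]))
      }
      grid[[rain_col]] <- rainfall_levels[i]
      X <- model.matrix(reformulate(live_terms(fit)), grid)
      L <- drop(X[1L, names(fit$coefficients)])
    } else {
      dd <- d
      dd[[rain_col]] <- rainfall_levels[i]
      X <- model.matrix(reformulate(live_terms(fit)), dd)
      L <- colMeans(X[, names(fit$coefficients), drop = FALSE])
    }
    est <- sum(L * fit$coefficients)
    se <- sqrt(max(drop(t(L) %*% fit$vcov %*% L), 0))
    ci <- c(est - 1.96 * se, est + 1.96 * se)
    out$mean_m[i] <- bc_inverse(est, lambda, bmode)
    out$lo95_m[i] <- bc_inverse(ci[1L], lambda, bmode)
    out$hi95_m[i] <- bc_inverse(ci[2L], lambda, bmode)
  }
  out
}

## ---- fitter factory ---------------------------------------------------------

#' Build a refitting closure for elimination and confounding tools
#'
#' @param kind `"beta"`, `"lmm_ar1"` or `"lm"`.
#' @param response Response column name.
#' @param ... Passed to the underlying fitter (`lambda`, `outlier_ha`, ...).
#' @return Function `(data, terms) -> cat_modelfit`.
#' @export
make_fitter <- function(kind = c("beta", "lmm_ar1", "lm"), response, ...) {
  kind <- match.arg(kind)
  dots <- list(...)
  switch(kind,
    beta = function(data, terms)
      fit_beta_regression(data, response, terms),
    lmm_ar1 = function(data, terms)
      do.call(fit_distance_lmm,
              c(list(data = data, response = response, terms = terms), dots)),
    lm = function(data, terms)
      do.call(fit_homerange_lm,
              c(list(data = data, response = response, terms = terms), dots)))
}
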