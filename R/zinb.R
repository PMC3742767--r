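# Zero-inflated negative binomial habitat models.
#
# Mixture: P(y=0) = pi + (1-pi) * NB(0); P(y>0) = (1-pi) * NB(y), with
# mu = exp(X beta + log area) (exposure offset, coefficient fixed at 1),
# NB2 variance mu + alpha mu^2, and pi = plogis(Z gamma) over detection-bias
# covariates. Fitting is quasi-Newton (BFGS) with analytic gradients from
# negative-binomial starting values for the count part and a logistic fit of
# the zero indicator for the inflation part.

#' Specify a species habitat model
#'
#' @param species species code the model is for.
#' @param count data.frame with columns `var`, `form` (`"linear"` or
#'   `"quadratic"`); a quadratic term always includes its linear term.
#' @param infl character vector of detection-bias covariates for the
#'   zero-inflation part (empty allowed; intercept always included when the
#'   family is `"zinb"`).
#' @param controls categorical control terms, entered in the count part and
#'   never dropped by stepwise selection.
#' @param interaction `NULL`, or the name of one oceanographic covariate
#'   (`"sst"`, `"sss"`, `"ssf"`) interacted with year (categorical).
#' @param family `"zinb"` or `"nb"` (plain negative binomial, no inflation
#'   part).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(species, count, infl = character(),
                       controls = c("month", "year"), interaction = NULL,
                       family = c("zinb", "nb")) {
  family <- match.arg(family)
  count <- as.data.frame(count)
  stopifnot(all(c("var", "form") %in% names(count)),
            all(count$form %in% c("linear", "quadratic")))
  if (anyDuplicated(count$var)) stop("duplicate count-part terms")
  if (!is.null(interaction) && !interaction %in% c("sst", "sss", "ssf"))
    stop("interaction covariate must be one of sst, sss, ssf")
  structure(list(species = species, count = count, infl = infl,
                 controls = controls, interaction = interaction,
                 family = family),
            class = "model_spec")
}

# training reference: covariate centers and factor levels, so prediction on
# new data uses the training frame
spec_ref <- function(spec, data) {
  vars <- unique(c(spec$count$var, spec$infl, spec$interaction))
  centers <- vapply(vars, function(v) mean(data[[v]]), 0)
  ranges <- lapply(vars, function(v) range(data[[v]]))
  names(ranges) <- vars
  ref <- list(centers = centers, ranges = ranges)
  for (ctl in spec$controls) ref[[ctl]] <- sort(unique(data[[ctl]]))
  if (!is.null(spec$interaction)) ref$year <- sort(unique(data$year))
  ref
}

centered <- function(ref, v, data) data[[v]] - ref$centers[[v]]

dummy_cols <- function(x, levels, prefix) {
  lev <- levels[-1]
  if (length(lev) == 0L) return(NULL)
  m <- vapply(lev, function(l) as.numeric(x == l), numeric(length(x)))
  colnames(m) <- paste0(prefix, lev)
  m
}

design_count <- function(spec, data, ref) {
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (i in seq_len(nrow(spec$count))) {
    v <- spec$count$var[i]
    z <- centered(ref, v, data)
    X <- cbind(X, z)
    colnames(X)[ncol(X)] <- v
    if (spec$count$form[i] == "quadratic") {
      X <- cbind(X, z^2)
      colnames(X)[ncol(X)] <- paste0("I(", v, "^2)")
    }
  }
  for (ctl in spec$controls) {
    d <- dummy_cols(data[[ctl]], ref[[ctl]], paste0(ctl, "_"))
    if (!is.null(d)) X <- cbind(X, d)
  }
  if (!is.null(spec$interaction)) {
    z <- centered(ref, spec$interaction, data)
    d <- dummy_cols(data$year, ref$year, "year_")
    if (!is.null(d)) {
      inter <- d * z
      colnames(inter) <- paste0(spec$interaction, ":", colnames(d))
      X <- cbind(X, inter)
    }
  }
  X
}

design_infl <- function(spec, data, ref) {
  Z <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (v in spec$infl) {
    Z <- cbind(Z, centered(ref, v, data))
    colnames(Z)[ncol(Z)] <- v
  }
  Z
}

#' Zero-inflated negative binomial log-likelihood
#'
#' Sum over observations of the log mixture density
#' `log(pi + (1-pi) NB(0))` for zeros and `log(1-pi) + log NB(y)` otherwise,
#' with `mu = exp(X beta + offset)`, `pi = plogis(Z gamma)` and NB2 size
#' `1/alpha`. Computed in log space for stability. Returns `-Inf` for
#' `alpha <= 0` (rejected by the optimizer).
#'
#' @param y non-negative integer counts.
#' @param X count-part design matrix.
#' @param Z inflation-part design matrix.
#' @param beta,gamma coefficient vectors.
#' @param alpha NB2 dispersion (> 0).
#' @param offset exposure offset, typically `log(area)`.
#' @param per_obs if `TRUE` return the per-observation log densities.
#' @return scalar log-likelihood (or vector when `per_obs`).
#' @export
zinb_loglik <- function(y, X, Z, beta, gamma, alpha, offset = 0,
                        per_obs = FALSE) {
  if (!all(is.finite(c(beta, gamma, alpha))) || alpha <= 0)
    return(if (per_obs) rep(-Inf, length(y)) else -Inf)
  r <- 1 / alpha
  eta <- as.numeric(X %*% beta) + offset
  zeta <- as.numeric(Z %*% gamma)
  mu <- exp(eta)
  log_pi <- stats::plogis(zeta, log.p = TRUE)
  log_1mpi <- stats::plogis(-zeta, log.p = TRUE)
  lp0 <- r * (log(r) - log(r + mu))
  ll <- numeric(length(y))
  z0 <- y == 0
  if (any(z0)) {
    a <- log_pi[z0]; b <- log_1mpi[z0] + lp0[z0]
    m <- pmax(a, b)
    ll[z0] <- m + log(exp(a - m) + exp(b - m))
  }
  if (any(!z0)) {
    ll[!z0] <- log_1mpi[!z0] +
      stats::dnbinom(y[!z0], size = r, mu = mu[!z0], log = TRUE)
  }
  if (per_obs) ll else sum(ll)
}

# analytic gradient of the ZINB log-likelihood wrt (beta, gamma, log(alpha))
zinb_grad <- function(y, X, Z, beta, gamma, log_alpha, offset = 0) {
  alpha <- exp(log_alpha)
  r <- 1 / alpha
  eta <- as.numeric(X %*% beta) + offset
  zeta <- as.numeric(Z %*% gamma)
  mu <- exp(eta)
  pi <- stats::plogis(zeta)
  lp0 <- r * (log(r) - log(r + mu))
  p0 <- exp(lp0)
  z0 <- y == 0
  u <- v <- dla <- numeric(length(y))
  # y > 0
  if (any(!z0)) {
    i <- !z0
    u[i] <- (y[i] - mu[i]) * r / (r + mu[i])
    v[i] <- -pi[i]
    dr <- digamma(y[i] + r) - digamma(r) + log(r) + 1 -
      log(r + mu[i]) - (r + y[i]) / (r + mu[i])
    dla[i] <- -r * dr
  }
  # y == 0: f = pi + (1-pi) p0
  if (any(z0)) {
    i <- z0
    f <- pi[i] + (1 - pi[i]) * p0[i]
    u[i] <- -(1 - pi[i]) * p0[i] * r * mu[i] / ((r + mu[i]) * f)
    v[i] <- pi[i] * (1 - pi[i]) * (1 - p0[i]) / f
    dlp0_dr <- log(r) + 1 - log(r + mu[i]) - r / (r + mu[i])
    dla[i] <- -r * (1 - pi[i]) * p0[i] * dlp0_dr / f
  }
  c(as.numeric(crossprod(X, u)), as.numeric(crossprod(Z, v)), sum(dla))
}

#' Fit a species habitat model
#'
#' Fits the spec's model to the bin table: a zero-inflated negative binomial
#' by quasi-Newton maximization with analytic gradients (starting from a
#' negative-binomial fit of the count part and a logistic fit of the zero
#' indicator), or a plain negative binomial / Poisson via [MASS::glm.nb()] /
#' [stats::glm()] when the family says so. The exposure offset `log(area)`
#' enters with coefficient fixed at 1. Non-convergence and apparent
#' separation in the inflation part are flagged, never silent.
#'
#' @param spec a [model_spec()].
#' @param data bin table with count column named as `spec$species`,
#'   covariates, and `area_km2 > 0`.
#' @param family override the spec family; `"poisson"` also allowed (for the
#'   dispersion likelihood-ratio test).
#' @param restarts perturbed restarts when the ZINB optimizer fails.
#' @param start optional starting vector `c(beta, gamma, log(alpha))`
#'   overriding the default NB/logistic starting values (ZINB only).
#' @return object of class `habitat_fit`: coefficients, `vcov`, `alpha`,
#'   `loglik`, per-observation log densities `obs_ll`, Wald `summary` table,
#'   `converged` flag.
#' @export
fit_habitat_model <- function(spec, data, family = NULL, restarts = 3L,
                              start = NULL) {
  family <- if (is.null(family)) spec$family else family
  y <- data[[spec$species]]
  stopifnot(all(y >= 0), all(y == round(y)), all(data$area_km2 > 0))
  ref <- spec_ref(spec, data)
  X <- design_count(spec, data, ref)
  off <- log(data$area_km2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("count-part design is rank deficient")

  if (family == "poisson") {
    g <- stats::glm.fit(X, y, offset = off, family = stats::poisson())
    beta <- g$coefficients
    obs_ll <- stats::dpois(y, exp(as.numeric(X %*% beta) + off), log = TRUE)
    return(new_fit("poisson", spec, ref, beta, NULL, NA, NULL, sum(obs_ll),
                   obs_ll, y, off, TRUE, X, NULL,
                   vcov_glmfit(g, X)))
  }
  if (family == "nb") {
    df <- data.frame(.y = y)
    nb <- suppressWarnings(
      MASS::glm.nb(.y ~ X - 1 + offset(off), data = df,
                   control = stats::glm.control(maxit = 100)))
    beta <- stats::coef(nb)
    names(beta) <- colnames(X)
    mu <- exp(as.numeric(X %*% beta) + off)
    obs_ll <- stats::dnbinom(y, size = nb$theta, mu = mu, log = TRUE)
    V <- stats::vcov(nb)
    dimnames(V) <- list(colnames(X), colnames(X))
    return(new_fit("nb", spec, ref, beta, NULL, 1 / nb$theta, NULL,
                   sum(obs_ll), obs_ll, y, off, nb$converged, X, NULL, V))
  }

  # ZINB
  Z <- design_infl(spec, data, ref)
  # starting values
  beta0 <- tryCatch({
    df <- data.frame(.y = y)
    nb <- suppressWarnings(
      MASS::glm.nb(.y ~ X - 1 + offset(off), data = df,
                   control = stats::glm.control(maxit = 100)))
    list(beta = stats::coef(nb), alpha = 1 / nb$theta)
  }, error = function(e) {
    g <- stats::glm.fit(X, y, offset = off, family = stats::poisson())
    list(beta = g$coefficients, alpha = 1)
  })
  gz <- suppressWarnings(
    stats::glm.fit(Z, as.numeric(y == 0), family = stats::binomial()))
  gamma0 <- gz$coefficients
  gamma0[1] <- gamma0[1] - 0.5  # zero indicator overstates structural zeros
  gamma0[!is.finite(gamma0)] <- 0

  p <- ncol(X); q <- ncol(Z)
  nll <- function(th) {
    -zinb_loglik(y, X, Z, th[1:p], th[(p + 1):(p + q)], exp(th[p + q + 1]), off)
  }
  ngr <- function(th) {
    -zinb_grad(y, X, Z, th[1:p], th[(p + 1):(p + q)], th[p + q + 1], off)
  }
  th0 <- if (is.null(start)) c(beta0$beta, gamma0, log(max(beta0$alpha, 1e-3)))
         else start
  best <- NULL
  for (k in 0:restarts) {
    start <- if (k == 0) th0 else th0 + stats::rnorm(length(th0), sd = 0.2)
    opt <- tryCatch(
      stats::optim(start, nll, ngr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0) break
  }
  if (is.null(best)) stop("ZINB optimization failed from all starts")
  # polish from the incumbent: clears reltol/maxit stalls cheaply
  polish <- tryCatch(
    stats::optim(best$par, nll, ngr, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  th <- best$par
  beta <- th[1:p]; names(beta) <- colnames(X)
  gamma <- th[(p + 1):(p + q)]; names(gamma) <- colnames(Z)
  alpha <- unname(exp(th[p + q + 1]))
  grad <- ngr(th)
  grad_norm <- sqrt(sum(grad^2))
  separated <- any(abs(gamma) > 15)
  # Hessian as central differences of the analytic gradient with
  # per-parameter relative steps (coefficients span many orders of magnitude)
  H <- tryCatch({
    np <- length(th)
    Hm <- matrix(0, np, np)
    for (j in seq_len(np)) {
      h <- 1e-5 * max(abs(th[j]), 1e-3)
      e <- rep(0, np); e[j] <- h
      Hm[, j] <- (ngr(th + e) - ngr(th - e)) / (2 * h)
    }
    (Hm + t(Hm)) / 2
  }, error = function(e) NULL)
  V <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && any(!is.finite(V))) V <- NULL
  }
  nm <- c(colnames(X), paste0("zero_", colnames(Z)), "log_alpha")
  if (!is.null(V)) dimnames(V) <- list(nm, nm)
  # scale-invariant convergence check: Newton decrement g' H^-1 g is the
  # log-likelihood improvement still available at the stopping point
  decrement <- if (!is.null(V)) {
    tryCatch(abs(sum(grad * as.numeric(V %*% grad))), error = function(e) NA)
  } else NA
  converged <- best$convergence == 0 &&
    (if (is.finite(decrement)) decrement < 1e-3
     else grad_norm < 1e-2 * max(1, length(y) / 100))
  obs_ll <- zinb_loglik(y, X, Z, beta, gamma, alpha, off, per_obs = TRUE)
  fit <- new_fit("zinb", spec, ref, beta, gamma, alpha, NULL, sum(obs_ll),
                 obs_ll, y, off, converged, X, Z, V)
  fit$separated <- separated
  fit$grad_norm <- grad_norm
  fit
}

vcov_glmfit <- function(g, X) {
  w <- g$weights
  V <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  if (!is.null(V)) dimnames(V) <- list(colnames(X), colnames(X))
  V
}

new_fit <- function(family, spec, ref, beta, gamma, alpha, theta, loglik,
                    obs_ll, y, offset, converged, X, Z, vcov) {
  structure(list(family = family, spec = spec, ref = ref, beta = beta,
                 gamma = gamma, alpha = alpha, loglik = loglik,
                 obs_ll = obs_ll, y = y, offset = offset, n = length(y),
                 converged = converged, vcov = vcov,
                 x_names = colnames(X), z_names = colnames(Z)),
            class = "habitat_fit")
}

#' @export
print.habitat_fit <- function(x, ...) {
  cat(sprintf("%s fit for %s: n=%d, logLik=%.2f, alpha=%s, converged=%s\n",
              toupper(x$family), x$spec$species, x$n, x$loglik,
              ifelse(is.na(x$alpha), "-", sprintf("%.3f", x$alpha)),
              x$converged))
  invisible(x)
}

#' Wald summary table of a fit
#'
#' @param fit a `habitat_fit`.
#' @return data.frame with `part` (count/zero/dispersion), `term`,
#'   `estimate`, `se`, `z`, `p`.
#' @export
fit_summary <- function(fit) {
  est <- c(fit$beta,
           if (!is.null(fit$gamma)) fit$gamma,
           if (fit$family == "zinb") log(fit$alpha))
  nm <- c(names(fit$beta),
          if (!is.null(fit$gamma)) paste0("zero_", names(fit$gamma)),
          if (fit$family == "zinb") "log_alpha")
  part <- c(rep("count", length(fit$beta)),
            if (!is.null(fit$gamma)) rep("zero", length(fit$gamma)),
            if (fit$family == "zinb") "dispersion")
  se <- rep(NA_real_, length(est))
  if (!is.null(fit$vcov)) {
    d <- diag(fit$vcov)
    d[d < 0] <- NA
    se[seq_along(d)] <- sqrt(d)
  }
  z <- est / se
  data.frame(part = part, term = nm, estimate = unname(est), se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)))
}

#' Predict expected counts from a fitted habitat model
#'
#' Expectation of the fitted mixture `(1 - pi) * exp(x' beta + log(area))`
#' (plain `exp(x' beta + log(area))` for NB/Poisson fits), on new data using
#' the training covariate centers and factor levels.
#'
#' @param object a `habitat_fit`.
#' @param newdata data.frame with the model covariates and `area_km2`.
#' @param ... unused.
#' @return numeric vector of expected counts.
#' @export
predict.habitat_fit <- function(object, newdata, ...) {
  X <- design_count(object$spec, newdata, object$ref)
  X <- X[, object$x_names, drop = FALSE]
  mu <- exp(as.numeric(X %*% object$beta) + log(newdata$area_km2))
  if (object$family != "zinb") return(mu)
  Z <- design_infl(object$spec, newdata, object$ref)
  pi <- stats::plogis(as.numeric(Z %*% object$gamma))
  (1 - pi) * mu
}

#' Likelihood-ratio test for overdispersion (NB over Poisson)
#'
#' `2 (LL_NB - LL_Poisson)` compared to the boundary-corrected half-chi-square
#' mixture with 1 df (the dispersion parameter sits on the boundary of its
#' space under the null); a statistic of 0 gives p = 0.5.
#'
#' @param nb_fit,poisson_fit `habitat_fit`s on identical observations.
#' @return list (class `model_test`) with `name`, `statistic`, `df`, `p`,
#'   `preferred`.
#' @export
lr_test_alpha <- function(nb_fit, poisson_fit) {
  check_same_data(nb_fit, poisson_fit)
  stat <- max(0, 2 * (nb_fit$loglik - poisson_fit$loglik))
  p <- if (stat == 0) 0.5 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  structure(list(name = "LR-alpha", statistic = stat, df = 1, p = p,
                 preferred = if (p < 0.05) "negbin" else "poisson"),
            class = "model_test")
}

#' Vuong closeness test (zero-inflated NB vs plain NB)
#'
#' `V = sqrt(n) * mean(m) / sd(m)` with `m_i` the per-observation log density
#' ratio of the two fits; positive values favor the first (zero-inflated)
#' model; the one-sided p-value is reported. Identical per-observation
#' densities give a degenerate result (statistic 0, p = 0.5).
#'
#' @param zinb_fit,nb_fit `habitat_fit`s on identical observations.
#' @return `model_test` with `statistic`, `n`, `p`, `preferred`, `degenerate`.
#' @export
vuong_test <- function(zinb_fit, nb_fit) {
  check_same_data(zinb_fit, nb_fit)
  m <- zinb_fit$obs_ll - nb_fit$obs_ll
  n <- length(m)
  s <- stats::sd(m)
  degenerate <- !is.finite(s) || s < 1e-12
  V <- if (degenerate) 0 else sqrt(n) * mean(m) / s
  p <- if (degenerate) 0.5 else stats::pnorm(V, lower.tail = FALSE)
  structure(list(name = "Vuong", statistic = V, n = n, p = p,
                 preferred = if (!degenerate && p < 0.05) "zinb" else "negbin",
                 degenerate = degenerate),
            class = "model_test")
}

check_same_data <- function(f1, f2) {
  if (f1$n != f2$n || !isTRUE(all.equal(f1$y, f2$y)))
    stop("fits must be on identical observations")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each covariate on the others;
#' a perfectly collinear covariate reports `Inf` and fails the screen.
#'
#' @param covariates data.frame or matrix of numeric covariates (>= 3
#'   columns, more rows than columns).
#' @param threshold pass/fail cut (default 10).
#' @return data.frame `variable`, `vif`, `pass`.
#' @export
vif_screen <- function(covariates, threshold = 10) {
  M <- as.matrix(covariates)
  if (ncol(M) < 3L) stop("need >= 3 covariates")
  if (nrow(M) <= ncol(M)) stop("need more observations than covariates")
  vif <- vapply(seq_len(ncol(M)), function(j) {
    fit <- stats::lm.fit(cbind(1, M[, -j, drop = FALSE]), M[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((M[, j] - mean(M[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  data.frame(variable = colnames(M), vif = vif, pass = vif < threshold)
}

# terms of the count part that may currently be dropped, with the design
# column whose p-value governs the decision
droppable_terms <- function(spec) {
  out <- list()
  for (i in seq_len(nrow(spec$count))) {
    v <- spec$count$var[i]
    if (spec$count$form[i] == "quadratic") {
      out[[length(out) + 1L]] <- list(var = v, col = paste0("I(", v, "^2)"),
                                      action = "to_linear")
    } else {
      out[[length(out) + 1L]] <- list(var = v, col = v, action = "remove")
    }
  }
  out
}

apply_drop <- function(spec, drop) {
  i <- which(spec$count$var == drop$var)
  if (drop$action == "to_linear") {
    spec$count$form[i] <- "linear"
  } else {
    spec$count <- spec$count[-i, , drop = FALSE]
  }
  spec
}

#' Backward stepwise simplification of the count part
#'
#' Negative-binomial backward elimination at the given significance level:
#' repeatedly refit and drop the term with the largest Wald p-value above
#' `level`, reducing quadratics to linears before removing the linear term,
#' and never touching the categorical month/year controls. Near-ties in p are
#' broken by dropping the term whose removal loses the least log-likelihood.
#'
#' @param spec full [model_spec()].
#' @param data bin table.
#' @param level significance level for retention (default 0.05).
#' @return list with `spec` (the reduced spec) and `path` (data.frame of
#'   drops). Warns if no covariate terms survive.
#' @export
backward_stepwise <- function(spec, data, level = 0.05) {
  path <- list()
  repeat {
    if (nrow(spec$count) == 0L) {
      warning("no covariate terms survive; returning intercept + controls")
      break
    }
    fit <- fit_habitat_model(spec, data, family = "nb")
    sm <- fit_summary(fit)
    cand <- droppable_terms(spec)
    pvals <- vapply(cand, function(d) {
      p <- sm$p[sm$term == d$col]
      if (length(p) == 0L || is.na(p)) 1 else p
    }, 0)
    over <- which(pvals > level)
    if (length(over) == 0L) break
    worst <- over[pvals[over] > max(pvals[over]) - 1e-12]
    if (length(worst) > 1L) {
      # tie: drop the term whose removal loses the least log-likelihood
      losses <- vapply(worst, function(w) {
        f2 <- fit_habitat_model(apply_drop(spec, cand[[w]]), data, family = "nb")
        fit$loglik - f2$loglik
      }, 0)
      worst <- worst[which.min(losses)]
    }
    d <- cand[[worst]]
    path[[length(path) + 1L]] <- data.frame(term = d$col, action = d$action,
                                            p = pvals[worst])
    spec <- apply_drop(spec, d)
  }
  list(spec = spec, path = if (length(path)) do.call(rbind, path)
       else data.frame(term = character(), action = character(), p = numeric()))
}

#' Backward selection of detection-bias inflation terms
#'
#' Fits the zero-inflated model and repeatedly drops the inflation-part
#' covariate with the largest Wald p-value above `level` (the inflation
#' intercept always stays).
#'
#' @param spec [model_spec()] with candidate `infl` terms.
#' @param data bin table.
#' @param level retention level.
#' @return reduced `model_spec`.
#' @export
select_detection_terms <- function(spec, data, level = 0.05) {
  repeat {
    if (length(spec$infl) == 0L) break
    fit <- fit_habitat_model(spec, data)
    sm <- fit_summary(fit)
    p <- vapply(spec$infl, function(v) {
      pv <- sm$p[sm$term == paste0("zero_", v)]
      if (length(pv) == 0L || is.na(pv)) 1 else pv
    }, 0)
    if (max(p) <= level) break
    spec$infl <- setdiff(spec$infl, names(which.max(p)))
  }
  spec
}

#' Select a year x oceanography interaction by likelihood ratio
#'
#' For each oceanographic covariate (SST, SSS, SSF) present in the reduced
#' spec, compares the model with a year-by-covariate interaction against the
#' base model by a likelihood-ratio test; keeps the interaction with the
#' largest significant statistic, or none. Year levels with fewer than 2
#' observations skip that interaction with a warning.
#'
#' @param spec reduced [model_spec()].
#' @param data bin table.
#' @param level significance level (default 0.05).
#' @return list with `spec` (interaction set or unchanged) and `tests`
#'   (data.frame of LR statistics).
#' @export
select_interaction <- function(spec, data, level = 0.05) {
  ocean <- intersect(spec$count$var, c("sst", "sss", "ssf"))
  if (length(ocean) == 0L)
    return(list(spec = spec, tests = data.frame()))
  yr_tab <- table(data$year)
  if (any(yr_tab < 2L)) {
    warning("year level(s) with < 2 observations; interactions skipped")
    return(list(spec = spec, tests = data.frame()))
  }
  base <- fit_habitat_model(spec, data)
  tests <- lapply(ocean, function(v) {
    sp2 <- spec; sp2$interaction <- v
    fit2 <- tryCatch(fit_habitat_model(sp2, data), error = function(e) NULL)
    if (is.null(fit2)) return(NULL)
    stat <- max(0, 2 * (fit2$loglik - base$loglik))
    df <- length(fit2$beta) - length(base$beta)
    data.frame(variable = v, statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  })
  tests <- do.call(rbind, tests)
  if (is.null(tests) || nrow(tests) == 0L)
    return(list(spec = spec, tests = data.frame()))
  sig <- tests[tests$p < level, , drop = FALSE]
  if (nrow(sig) > 0L) spec$interaction <- sig$variable[which.max(sig$statistic)]
  list(spec = spec, tests = tests)
}

#' n-fold cross-validation of a habitat model
#'
#' Randomly splits the bins into mutually exclusive folds, predicts each
#' observation exactly once from a fit excluding its fold, and regresses
#' observed counts on the out-of-fold predictions; the regression F statistic
#' (1, n-2) and its p-value summarize predictive fit. Folds whose fit fails
#' are skipped and reported.
#'
#' @param spec a [model_spec()].
#' @param data bin table.
#' @param folds number of folds (>= 2, <= n).
#' @param seed seed for the fold assignment (recorded in the result).
#' @return `model_test` with `statistic` (F), `df`, `p`, plus `predicted`,
#'   `folds_failed`, `seed`.
#' @export
cross_validate <- function(spec, data, folds = 10, seed = 1L) {
  n <- nrow(data)
  stopifnot(folds >= 2, n >= folds)
  set.seed(seed)
  assign <- sample(rep(seq_len(folds), length.out = n))
  pred <- rep(NA_real_, n)
  failed <- integer()
  for (f in seq_len(folds)) {
    test <- assign == f
    fit <- tryCatch(fit_habitat_model(spec, data[!test, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- c(failed, f); next }
    pred[test] <- predict(fit, data[test, , drop = FALSE])
  }
  ok <- !is.na(pred)
  y <- data[[spec$species]][ok]
  lm_fit <- stats::lm(y ~ pred[ok])
  fs <- summary(lm_fit)$fstatistic
  structure(list(name = "CV-F", statistic = unname(fs[1]),
                 df = unname(fs[2:3]),
                 p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
                 predicted = pred, folds_failed = failed, seed = seed),
            class = "model_test")
}

#' @export
print.model_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g%s\n", x$name, x$statistic,
              x$p,
              if (!is.null(x$preferred)) paste0(" (prefers ", x$preferred, ")")
              else ""))
  invisible(x)
}
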