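# Zero-inflated beta regression with a subject-level random intercept.
#
# Model for a per-sample proportion y in [0, 1):
#   y = 0            with probability pi0
#   y ~ Beta(mu*phi, (1-mu)*phi)  otherwise,
# with logit(mu) = X beta + b_subject, b_subject ~ N(0, sigma_u^2),
# logit(pi0) = Z gamma (intercept-only by default), log link on phi.
# The marginal likelihood integrates b out per subject by adaptive
# Gauss-Hermite quadrature.

#' Zero-inflated beta mixed model
#'
#' Fits a zero-inflated beta regression with a per-subject random intercept
#' in the mean submodel, the standard model for longitudinal microbiome
#' relative abundances: a point mass at zero (taxon not observed) mixed with
#' a beta distribution for positive proportions, with repeated samples from
#' the same subject sharing a latent offset.
#'
#' The marginal likelihood integrates the random intercept out subject by
#' subject with adaptive Gauss-Hermite quadrature: the integrand is re-centred
#' at its conditional mode (found by Newton iteration) and scaled by its
#' curvature before applying the quadrature rule, so moderate orders are
#' accurate even for large random-effect variances. Wald standard errors come
#' from the numerically differentiated observed information.
#'
#' Proportions equal to 1 (possible after aggregation) are squeezed by
#' \code{y (N-1)/N + 0.5/N}; the beta density has open support at 1 and the
#' zero-inflation component covers only the 0 boundary. If every response is
#' zero the mean submodel is unidentified: the fit is returned with
#' \code{pi0 = 1} and \code{identified = FALSE}.
#'
#' @param formula model formula for the mean submodel, e.g.
#'   \code{abund ~ dementia_class + frailty}. The response is a proportion in
#'   \code{[0, 1]}.
#' @param data data frame holding response, covariates and the subject column.
#' @param subject name of the grouping column (character scalar) identifying
#'   repeated measures.
#' @param zi_formula right-hand-side formula for the zero-inflation
#'   probability on the logit scale; default intercept-only (\code{~1}).
#' @param nAGQ order of the Gauss-Hermite rule (default 15).
#' @param control list of optimizer settings passed to \code{\link{nlminb}}.
#' @return an object of class \code{"zib_glmm"} with components \code{beta},
#'   \code{se}, \code{wald_z}, \code{p_values}, \code{phi}, \code{pi0_params},
#'   \code{sigma_u}, \code{loglik}, \code{converged}, \code{identified},
#'   \code{n_obs}, \code{n_subjects}, \code{vcov}, and the model frame pieces.
#' @examples
#' set.seed(1)
#' d <- data.frame(subj = rep(1:20, each = 3), x = rnorm(60))
#' mu <- plogis(-2 + 0.5 * d$x + rnorm(20, 0, 0.5)[d$subj])
#' d$y <- rbeta(60, mu * 30, (1 - mu) * 30)
#' d$y[sample(60, 8)] <- 0
#' fit <- zib_glmm(y ~ x, d, subject = "subj")
#' coef(fit)
#' @export
zib_glmm <- function(formula, data, subject, zi_formula = ~1, nAGQ = 15,
                     control = list()) {
  stopifnot(is.character(subject), length(subject) == 1L)
  if (!subject %in% names(data))
    stop("subject column '", subject, "' not found in data")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  Z <- stats::model.matrix(zi_formula, data)
  subj <- factor(data[[subject]])
  n <- length(y)
  if (any(y < 0 | y > 1)) stop("response must lie in [0, 1]")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; drop redundant covariates")
  n_subj <- nlevels(subj)
  if (n_subj < 2L) stop("need at least 2 subjects")

  # squeeze exact ones only; zeros are the zero-inflation component's job
  hi <- y >= 1 - 1e-9
  if (any(hi)) y[hi] <- y[hi] * (n - 1) / n + 0.5 / n

  if (all(y == 0)) {
    fit <- structure(list(
      beta = stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
      se = rep(NA_real_, ncol(X)), wald_z = rep(NA_real_, ncol(X)),
      p_values = rep(NA_real_, ncol(X)), phi = NA_real_,
      pi0_params = stats::setNames(c(Inf, rep(0, ncol(Z) - 1L)), colnames(Z)),
      sigma_u = NA_real_, loglik = 0, converged = TRUE, identified = FALSE,
      n_obs = n, n_subjects = n_subj, vcov = NULL,
      formula = formula, zi_formula = zi_formula, nAGQ = nAGQ,
      X = X, Z = Z, y = y, subject = subj), class = "zib_glmm")
    return(fit)
  }

  p <- ncol(X); q <- ncol(Z)
  gh <- pracma::gaussHermite(nAGQ)

  # initialization: logit least squares on the nonzero part
  pos <- y > 0
  ystar <- stats::qlogis(pmin(pmax(y[pos], 1e-6), 1 - 1e-6))
  beta0 <- tryCatch(stats::lsfit(X[pos, , drop = FALSE], ystar,
                                 intercept = FALSE)$coefficients,
                    error = function(e) rep(0, p))
  beta0[!is.finite(beta0)] <- 0
  z0 <- mean(!pos)
  gamma0 <- c(stats::qlogis(pmin(pmax(z0, 1e-3), 1 - 1e-3)), rep(0, q - 1L))
  theta0 <- c(beta0, gamma0, log(10), log(0.5))

  cache <- new.env(parent = emptyenv())
  core_at <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    v <- zib_ll_core(beta = theta[seq_len(p)], gamma = theta[p + seq_len(q)],
                     phi = exp(theta[p + q + 1L]),
                     sigma_u = exp(theta[p + q + 2L]),
                     y = y, X = X, Z = Z, subject = subj, gh = gh,
                     grad = TRUE)
    cache$key <- key; cache$val <- v
    v
  }
  negll <- function(theta) {
    ll <- core_at(theta)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  neggr <- function(theta) {
    g <- core_at(theta)$grad
    if (any(!is.finite(g))) rep(0, length(theta)) else -g
  }

  ctrl <- utils::modifyList(list(iter.max = 500, eval.max = 1000,
                                 rel.tol = 1e-10), control)
  opt <- stats::nlminb(theta0, negll, gradient = neggr, control = ctrl,
                       lower = c(rep(-Inf, p + q), -10, -7),
                       upper = c(rep(Inf, p + q), 12, 5))
  ll0 <- -negll(theta0)
  # nlminb can report false convergence when the quadrature order is low
  # (objective and Fisher-identity gradient differ at O(quadrature error));
  # accept the optimum if the scaled gradient norm is small
  gfin <- max(abs(neggr(opt$par)))
  converged <- (opt$convergence == 0 || gfin < 1e-3 * (1 + abs(opt$objective))) &&
    -opt$objective >= ll0 - 1e-6

  # observed information by central differences of the analytic gradient
  H <- tryCatch({
    np <- length(opt$par)
    Hm <- matrix(NA_real_, np, np)
    eps <- pmax(1e-5, 1e-5 * abs(opt$par))
    for (i in seq_len(np)) {
      tp <- opt$par; tp[i] <- tp[i] + eps[i]
      tm <- opt$par; tm[i] <- tm[i] - eps[i]
      Hm[, i] <- (neggr(tp) - neggr(tm)) / (2 * eps[i])
    }
    (Hm + t(Hm)) / 2
  }, error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se_all <- if (!is.null(V) && all(diag(V)[seq_len(p)] > 0))
    sqrt(diag(V)) else rep(NA_real_, length(opt$par))

  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  se <- se_all[seq_len(p)]
  z <- beta / se
  structure(list(
    beta = beta, se = se, wald_z = z,
    p_values = 2 * stats::pnorm(-abs(z)),
    phi = exp(opt$par[p + q + 1L]),
    pi0_params = stats::setNames(opt$par[p + seq_len(q)], colnames(Z)),
    sigma_u = exp(opt$par[p + q + 2L]),
    loglik = -opt$objective, loglik_init = ll0,
    converged = converged, identified = TRUE,
    n_obs = n, n_subjects = n_subj, vcov = V,
    formula = formula, zi_formula = zi_formula, nAGQ = nAGQ,
    X = X, Z = Z, y = y, subject = subj), class = "zib_glmm")
}

#' Marginal log-likelihood of the zero-inflated beta mixed model
#'
#' Evaluates the marginal log-likelihood at given parameter values, integrating
#' the subject random intercept out by adaptive Gauss-Hermite quadrature. This
#' is the objective \code{\link{zib_glmm}} maximizes; it is exported so the
#' quadrature can be validated against brute-force numerical integration and
#' so profile computations are possible.
#'
#' @param beta mean-submodel coefficients (logit link).
#' @param gamma zero-inflation coefficients (logit link); a scalar gives an
#'   intercept-only model.
#' @param phi beta precision (> 0).
#' @param sigma_u random-intercept standard deviation (>= 0).
#' @param y response proportions in [0, 1).
#' @param X mean-submodel design matrix.
#' @param Z zero-inflation design matrix; default intercept-only.
#' @param subject factor of subject ids, length \code{nrow(X)}.
#' @param gh optional precomputed \code{pracma::gaussHermite} rule.
#' @param nAGQ quadrature order used when \code{gh} is NULL.
#' @return scalar log-likelihood.
#' @export
zib_marginal_loglik <- function(beta, gamma, phi, sigma_u, y, X,
                                Z = matrix(1, length(y), 1L), subject,
                                gh = NULL, nAGQ = 15) {
  if (is.null(gh)) gh <- pracma::gaussHermite(nAGQ)
  zib_ll_core(beta, gamma, phi, sigma_u, y, X, Z, subject, gh,
              grad = FALSE)$ll
}

# Likelihood core. Returns the marginal log-likelihood and, optionally, its
# gradient with respect to (beta, gamma, log phi, log sigma_u). The gradient
# uses Fisher's identity: d/dtheta log L_i equals the posterior expectation
# of d/dtheta log f(y_i, b | theta), evaluated with the same adaptive
# quadrature nodes reweighted to posterior weights. The zero-inflation
# submodel does not involve b, so its gradient block is exact.
zib_ll_core <- function(beta, gamma, phi, sigma_u, y, X, Z, subject, gh,
                        grad = FALSE) {
  subject <- factor(subject)
  eta0 <- drop(X %*% beta)
  zeta <- drop(Z %*% gamma)
  pi0 <- stats::plogis(zeta)
  pos <- y > 0
  # zero observations do not involve b: their loglik factors out
  ll_zero <- sum(stats::plogis(zeta[!pos], log.p = TRUE))
  g_gamma <- if (grad)
    drop(crossprod(Z[!pos, , drop = FALSE], 1 - pi0[!pos])) -
      drop(crossprod(Z[pos, , drop = FALSE], pi0[pos]))
  else NULL
  if (!any(pos)) {
    out <- list(ll = ll_zero)
    if (grad) out$grad <- c(rep(0, ncol(X)), g_gamma, 0, 0)
    return(out)
  }
  lp1 <- stats::plogis(zeta[pos], log.p = TRUE, lower.tail = FALSE)
  yp <- y[pos]; eta0p <- eta0[pos]
  Xp <- X[pos, , drop = FALSE]
  sp <- droplevels(subject[pos])
  idx <- as.integer(sp); ns <- nlevels(sp)
  ly <- log(yp); l1y <- log1p(-yp)
  K <- length(gh$x)

  # conditional log f(y|b) for positive obs, vectorized over obs
  obs_ll <- function(b_per_obs) {
    mu <- stats::plogis(eta0p + b_per_obs)
    a <- mu * phi; bb <- (1 - mu) * phi
    lp1 + (a - 1) * ly + (bb - 1) * l1y - lbeta(a, bb)
  }
  # d/d eta and d/d phi of the conditional beta log density
  obs_d <- function(b_per_obs) {
    mu <- stats::plogis(eta0p + b_per_obs)
    a <- mu * phi; bb <- (1 - mu) * phi
    Tq <- ly - l1y - digamma(a) + digamma(bb)
    list(deta = phi * mu * (1 - mu) * Tq,
         dphi = mu * ly + (1 - mu) * l1y - mu * digamma(a) -
           (1 - mu) * digamma(bb) + digamma(phi))
  }

  if (sigma_u < 1e-8) {
    b0 <- rep(0, length(yp))
    ll <- ll_zero + sum(obs_ll(b0))
    out <- list(ll = ll)
    if (grad) {
      d <- obs_d(b0)
      out$grad <- c(drop(crossprod(Xp, d$deta)), g_gamma,
                    phi * sum(d$dphi), 0)
    }
    return(out)
  }

  # per-subject joint log density g_i(b) = sum_j log f + log N(b; 0, sigma^2)
  g_parts <- function(b) { # b: vector length ns, returns derivative pieces
    mu <- stats::plogis(eta0p + b[idx])
    a <- mu * phi; bb <- (1 - mu) * phi
    Tq <- ly - l1y - digamma(a) + digamma(bb)
    d1o <- phi * mu * (1 - mu) * Tq
    mup <- mu * (1 - mu)
    d2o <- phi * mup * ((1 - 2 * mu) * Tq -
                         phi * mup * (trigamma(a) + trigamma(bb)))
    list(d1 = rowsum(d1o, idx)[, 1] - b / sigma_u^2,
         d2 = rowsum(d2o, idx)[, 1] - 1 / sigma_u^2)
  }
  # Newton for per-subject modes (d2 < 0 away from degenerate fits)
  bhat <- rep(0, ns)
  for (it in 1:25) {
    gp <- g_parts(bhat)
    step <- gp$d1 / pmin(gp$d2, -1e-8)
    step <- sign(step) * pmin(abs(step), 2) # damp
    bhat <- bhat - step
    if (max(abs(step)) < 1e-9) break
  }
  h <- -g_parts(bhat)$d2
  h <- pmax(h, 1e-8)
  sc <- sqrt(2 / h)

  # sum_k w_k exp(g(bhat + sc z_k) + z_k^2) * sc, in log space per subject
  lse <- matrix(-Inf, ns, K)
  for (k in seq_len(K)) {
    bk <- bhat + sc * gh$x[k]
    gv <- rowsum(obs_ll(bk[idx]), idx)[, 1] +
      stats::dnorm(bk, 0, sigma_u, log = TRUE)
    lse[, k] <- log(gh$w[k]) + gv + gh$x[k]^2
  }
  m <- apply(lse, 1, max)
  ll_pos_i <- m + log(rowSums(exp(lse - m))) + log(sc)
  ll <- ll_zero + sum(ll_pos_i)
  out <- list(ll = ll)
  if (grad) {
    # posterior node weights W[i, k], rows sum to 1
    W <- exp(lse - (ll_pos_i - log(sc)))
    g_beta <- numeric(ncol(X)); g_lphi <- 0; g_lsig <- 0
    for (k in seq_len(K)) {
      bk <- bhat + sc * gh$x[k]
      wk_obs <- W[idx, k]
      d <- obs_d(bk[idx])
      g_beta <- g_beta + drop(crossprod(Xp, d$deta * wk_obs))
      g_lphi <- g_lphi + sum(d$dphi * wk_obs)
      g_lsig <- g_lsig + sum(W[, k] * (bk^2 / sigma_u^2 - 1))
    }
    out$grad <- c(g_beta, g_gamma, phi * g_lphi, g_lsig)
  }
  out
}

#' @export
print.zib_glmm <- function(x, ...) {
  cat("Zero-inflated beta mixed model (adaptive Gauss-Hermite, order",
      x$nAGQ, ")\n")
  cat("  obs:", x$n_obs, " subjects:", x$n_subjects, "\n")
  if (!x$identified) {
    cat("  all responses zero: pi0 at boundary 1, mean model unidentified\n")
    return(invisible(x))
  }
  cat("  logLik:", format(x$loglik, digits = 6),
      " converged:", x$converged, "\n")
  cat("  sigma_u:", format(x$sigma_u, digits = 4),
      " phi:", format(x$phi, digits = 4),
      " pi0(intercept):", format(stats::plogis(x$pi0_params[1]), digits = 4),
      "\n\nCoefficients (mean submodel, logit link):\n")
  print(cbind(Estimate = x$beta, `Std.Err` = x$se, z = x$wald_z,
              `Pr(>|z|)` = x$p_values))
  invisible(x)
}

#' @export
summary.zib_glmm <- function(object, ...) {
  object
}

#' @export
coef.zib_glmm <- function(object, ...) object$beta

#' @export
vcov.zib_glmm <- function(object, ...) {
  if (is.null(object$vcov)) return(NULL)
  p <- length(object$beta)
  v <- object$vcov[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(v) <- list(names(object$beta), names(object$beta))
  v
}

#' @export
logLik.zib_glmm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta) + length(object$pi0_params) + 2L,
            nobs = object$n_obs, class = "logLik")
}

#' Predicted mean proportions from a zib_glmm fit
#'
#' Population-level predictions (random intercept at zero). \code{type
#' = "response"} returns the unconditional mean \code{(1 - pi0) * mu}.
#'
#' @param object a \code{zib_glmm} fit.
#' @param newdata optional data frame; defaults to the fitting data.
#' @param type \code{"response"} (default), \code{"conditional"} (beta mean
#'   \code{mu} only) or \code{"link"} (linear predictor).
#' @param ... unused.
#' @export
predict.zib_glmm <- function(object, newdata = NULL,
                             type = c("response", "conditional", "link"),
                             ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X; Z <- object$Z
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    X <- stats::model.matrix(tt, newdata)
    Z <- stats::model.matrix(object$zi_formula, newdata)
  }
  eta <- drop(X %*% object$beta)
  if (type == "link") return(eta)
  mu <- stats::plogis(eta)
  if (type == "conditional") return(mu)
  pi0 <- stats::plogis(drop(Z %*% object$pi0_params))
  (1 - pi0) * mu
}

#' @export
residuals.zib_glmm <- function(object, ...) {
  object$y - predict(object)
}
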