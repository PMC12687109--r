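#' Construct zero-one inflated beta parameters
#'
#' The ZOIB mixture has a point mass at 0 with probability p0, a conditional
#' point mass at 1 with probability q1 given y > 0, and a beta density on
#' (0,1) with mean mu and precision phi otherwise. p0, q1 and mu are tied to
#' a shared design matrix through logit links; phi is a single positive
#' precision on the log scale.
#'
#' @param beta_zero,beta_one,beta_mu Numeric coefficient vectors for the
#'   logit models of P(y = 0), P(y = 1 | y > 0) and the beta mean.
#' @param log_phi Log precision (scalar).
#' @return An object of class `zoib_params`.
#' @export
zoib_params <- function(beta_zero, beta_one, beta_mu, log_phi) {
  stopifnot(length(log_phi) == 1L, is.finite(log_phi))
  structure(list(beta_zero = beta_zero, beta_one = beta_one,
                 beta_mu = beta_mu, log_phi = log_phi),
            class = "zoib_params")
}

#' Zero-one inflated beta log-likelihood
#'
#' f(0) = p0; f(1) = (1 - p0) q1; f(y in (0,1)) =
#' (1 - p0)(1 - q1) Beta(y; mu phi, (1 - mu) phi), with p0, q1, mu obtained
#' from the design matrix through logit links.
#'
#' @param params A [zoib_params()] object.
#' @param y Response in \[0, 1\].
#' @param X Design matrix (rows match `y`); a column of ones for the
#'   intercept must be included explicitly.
#' @return Scalar log-likelihood.
#' @export
zoib_loglik <- function(params, y, X) {
  X <- as.matrix(X)
  if (any(y < 0 | y > 1)) stop("invalid data: y outside [0, 1]", call. = FALSE)
  if (nrow(X) != length(y)) stop("X rows must match y", call. = FALSE)
  eta0 <- drop(X %*% params$beta_zero)
  eta1 <- drop(X %*% params$beta_one)
  etam <- drop(X %*% params$beta_mu)
  phi <- exp(params$log_phi)
  # log p, log(1-p) via plogis for numerical stability at extreme predictors
  lp0 <- stats::plogis(eta0, log.p = TRUE)
  l1mp0 <- stats::plogis(-eta0, log.p = TRUE)
  lq1 <- stats::plogis(eta1, log.p = TRUE)
  l1mq1 <- stats::plogis(-eta1, log.p = TRUE)
  mu <- stats::plogis(etam)
  ll <- numeric(length(y))
  at0 <- y == 0
  at1 <- y == 1
  mid <- !at0 & !at1
  ll[at0] <- lp0[at0]
  ll[at1] <- l1mp0[at1] + lq1[at1]
  ll[mid] <- l1mp0[mid] + l1mq1[mid] +
    stats::dbeta(y[mid], mu[mid] * phi, (1 - mu[mid]) * phi, log = TRUE)
  sum(ll)
}

#' Simulate from a zero-one inflated beta model
#'
#' @param params A [zoib_params()] object.
#' @param X Design matrix.
#' @param seed Integer seed (mandatory; the draw is reproducible).
#' @return Numeric vector in \[0, 1\], one draw per row of `X`.
#' @export
simulate_zoib <- function(params, X, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  X <- as.matrix(X)
  p0 <- stats::plogis(drop(X %*% params$beta_zero))
  q1 <- stats::plogis(drop(X %*% params$beta_one))
  mu <- stats::plogis(drop(X %*% params$beta_mu))
  phi <- exp(params$log_phi)
  n <- nrow(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u0 <- stats::runif(n)
  u1 <- stats::runif(n)
  b <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  ifelse(u0 < p0, 0, ifelse(u1 < q1, 1, b))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fit a zero-one inflated beta model by maximum likelihood
#'
#' The ZOIB likelihood factorises exactly into three independent pieces: a
#' Bernoulli model for y = 0, a Bernoulli model for y = 1 among y > 0, and a
#' beta likelihood on the interior observations. The two Bernoulli parts are
#' fitted as logistic regressions; the beta part is maximised by
#' quasi-Newton (BFGS) from a deterministic start (interior-mean intercept,
#' zero slopes, phi = 1). The combined estimate is the joint maximum
#' likelihood estimate. Degenerate layers (no zeros, all zeros, no ones, no
#' interior points) are flagged as boundary cases rather than raising.
#'
#' @param y Response in \[0, 1\].
#' @param X Design matrix including the intercept column.
#' @return List with `params` ([zoib_params()]), `se` (same shape; `NA` on
#'   boundary layers), `loglik`, `converged`, `boundary` (character vector
#'   naming degenerate layers), and `grad_norm` (final gradient norm of the
#'   beta layer; 0 when it has nothing to fit).
#' @export
fit_zoib <- function(y, X) {
  X <- as.matrix(X)
  if (any(y < 0 | y > 1)) stop("invalid data: y outside [0, 1]", call. = FALSE)
  k <- ncol(X)
  if (length(y) < 5 * (3 * k + 1))
    warning("few observations relative to parameter count; estimates may be ",
            "unstable", call. = FALSE)
  boundary <- character()

  fit_logit <- function(resp, Xs, layer) {
    if (all(resp) || !any(resp)) {
      boundary <<- c(boundary, layer)
      co <- c(if (all(resp)) Inf else -Inf, rep(0, ncol(Xs) - 1L))
      return(list(coef = co, se = rep(NA_real_, ncol(Xs)),
                  loglik = 0, ok = TRUE))
    }
    g <- stats::glm.fit(Xs, as.numeric(resp),
                        family = stats::binomial())
    se <- tryCatch({
      w <- g$weights
      sqrt(diag(solve(crossprod(Xs * sqrt(w)))))
    }, error = function(e) rep(NA_real_, ncol(Xs)))
    list(coef = g$coefficients, se = se, ok = g$converged)
  }

  z <- fit_logit(y == 0, X, "zero")
  pos <- y > 0
  o <- fit_logit(y[pos] == 1, X[pos, , drop = FALSE], "one")

  mid <- y > 0 & y < 1
  if (sum(mid) == 0L) {
    boundary <- c(boundary, "beta")
    bm <- rep(0, k); se_bm <- rep(NA_real_, k)
    log_phi <- 0; se_phi <- NA_real_
    ok_beta <- TRUE; gnorm <- 0
  } else {
    ym <- y[mid]
    Xm <- X[mid, , drop = FALSE]
    nll <- function(th) {
      mu <- stats::plogis(drop(Xm %*% th[1:k]))
      phi <- exp(th[k + 1L])
      -sum(stats::dbeta(ym, mu * phi, (1 - mu) * phi, log = TRUE))
    }
    start <- c(stats::qlogis(min(max(mean(ym), 1e-3), 1 - 1e-3)),
               rep(0, k - 1L), 0)
    opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-12))
    bm <- opt$par[1:k]
    log_phi <- opt$par[k + 1L]
    se_all <- tryCatch(sqrt(diag(solve(opt$hessian))),
                       error = function(e) rep(NA_real_, k + 1L))
    se_bm <- se_all[1:k]
    se_phi <- se_all[k + 1L]
    ok_beta <- opt$convergence == 0L
    eps <- 1e-5
    gnorm <- sqrt(sum(vapply(seq_len(k + 1L), function(j) {
      e <- numeric(k + 1L); e[j] <- eps
      (nll(opt$par + e) - nll(opt$par - e)) / (2 * eps)
    }, numeric(1))^2))
  }

  params <- zoib_params(z$coef, o$coef, bm, log_phi)
  yc <- y; Xc <- X
  ll <- zoib_loglik_safe(params, yc, Xc)
  list(
    params = params,
    se = list(beta_zero = z$se, beta_one = o$se, beta_mu = se_bm,
              log_phi = se_phi),
    loglik = ll,
    converged = isTRUE(z$ok) && isTRUE(o$ok) && ok_beta,
    boundary = boundary,
    grad_norm = gnorm
  )
}

# loglik tolerant of +-Inf coefficients from boundary layers
zoib_loglik_safe <- function(params, y, X) {
  p <- params
  clamp <- function(b) {
    b[!is.finite(b)] <- sign(b[!is.finite(b)]) * 35
    b
  }
  p$beta_zero <- clamp(p$beta_zero)
  p$beta_one <- clamp(p$beta_one)
  zoib_loglik(p, y, X)
}

#' Design matrix for the exposure regression
#'
#' Builds the design used to test whether smaller-ranged or more threatened
#' species face more unsuitable conditions: an intercept, log10 initial
#' range area, and Red List category indicators with LC as the reference
#' level (categories absent from the data contribute no column).
#'
#' @param species Tibble with `polygon_area_km2` and `redlist`.
#' @param ordinal If `TRUE`, encode the Red List category as a single
#'   ordinal score (LC=0 .. CR=4, DD treated as NA-dropped column `dd`)
#'   instead of indicators.
#' @return Numeric design matrix with named columns.
#' @export
zoib_design <- function(species, ordinal = FALSE) {
  n <- nrow(species)
  lr <- log10(pmax(species$polygon_area_km2, 1e-12))
  if (!ordinal) {
    rl <- factor(species$redlist, levels = redlist_levels())
    mm <- stats::model.matrix(~rl)[, -1, drop = FALSE]
    colnames(mm) <- sub("^rl", "redlist", colnames(mm))
    keep <- colSums(mm) > 0
    X <- cbind(intercept = rep(1, n), log10_range = lr, mm[, keep, drop = FALSE])
  } else {
    score <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, DD = NA)[species$redlist]
    dd <- as.numeric(species$redlist == "DD")
    score[is.na(score)] <- 0
    X <- cbind(intercept = rep(1, n), log10_range = lr,
               threat_score = score, dd = dd)
  }
  X
}
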