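#' Proportional-odds (cumulative logit) ordinal regression
#'
#' Maximum-likelihood fit of the proportional-odds model
#' `P(Y <= j | x) = logistic(c_j - x'beta)` for an ordered response with
#' `J >= 2` states, the model used to compare methyl-state distributions
#' across strains and conditions. Observations may carry non-negative real
#' weights, so relative-abundance stoichiometries can be used directly as
#' weights; integer counts are just a special case.
#'
#' The optimizer is a Newton-type ascent on a reparameterized vector
#' `(c_1, log gap_2, ..., log gap_(J-1), beta)` in which cutpoints are kept
#' strictly increasing by construction (`c_j = c_(j-1) + exp(g_j)`). The
#' Hessian is obtained by central finite differences of the analytic
#' gradient; steps are halved until the likelihood increases. Convergence
#' is declared at gradient norm below `tol` (default 1e-8) within
#' `max_iter` iterations; non-convergence (e.g. separation) is reported via
#' `converged = FALSE` and a warning, never silently.
#'
#' With two response states the model degenerates to ordinary logistic
#' regression of `P(Y = 2)` with intercept `-c_1`.
#'
#' @param state ordered response: integer codes `1..J`, a factor, or an
#'   ordered factor.
#' @param x covariates: numeric vector, matrix or data frame (no intercept
#'   column; the cutpoints absorb it).
#' @param weights optional non-negative observation weights (default 1).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `po_fit`: `cutpoints`, `coefficients`,
#'   `se` (Wald standard errors of the coefficients), `z`, `p_value`,
#'   `vcov` (natural parameterization, cutpoints then coefficients),
#'   `log_likelihood`, `converged`, `n_iter`, `states`.
#' @examples
#' set.seed(1)
#' x <- rnorm(300)
#' star <- x + rlogis(300)
#' y <- cut(star, c(-Inf, -1, 1, Inf), labels = FALSE)
#' fit <- proportional_odds_fit(y, x)
#' fit$coefficients
#' @export
proportional_odds_fit <- function(state, x, weights = NULL, tol = 1e-8,
                                  max_iter = 100L) {
  if (is.factor(state)) state <- as.integer(state)
  state <- as.integer(state)
  states <- sort(unique(state))
  if (!all(states == seq_along(states))) {
    state <- match(state, states)
    states <- seq_along(states)
  }
  J <- length(states)
  if (J < 2L) stop("response must have at least 2 distinct states")
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- length(state)
  stopifnot(nrow(X) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  keep <- weights > 0
  state <- state[keep]; X <- X[keep, , drop = FALSE]
  weights <- weights[keep]
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("design matrix (with intercept) is not full rank")
  }
  p <- ncol(X)
  K <- J - 1L  # number of cutpoints

  cut_from_theta <- function(theta) {
    if (K == 1L) return(theta[1L])
    cumsum(c(theta[1L], exp(theta[2:K])))
  }

  # weighted log-likelihood and analytic gradient in theta
  ll_grad <- function(theta) {
    cuts <- cut_from_theta(theta)
    beta <- theta[(K + 1L):(K + p)]
    eta <- drop(X %*% beta)
    zu <- ifelse(state == J, Inf, cuts[pmin(state, K)] - eta)
    zl <- ifelse(state == 1L, -Inf, cuts[pmax(state - 1L, 1L)] - eta)
    Li <- pmax(stats::plogis(zu) - stats::plogis(zl), 1e-300)
    ll <- sum(weights * log(Li))
    fu <- ifelse(is.finite(zu), stats::dlogis(zu), 0)
    fl <- ifelse(is.finite(zl), stats::dlogis(zl), 0)
    # gradient wrt natural cutpoints
    gc <- numeric(K)
    wu <- weights * fu / Li   # contribution to c_{state}
    wl <- weights * fl / Li   # contribution to c_{state-1}
    for (j in seq_len(K)) {
      gc[j] <- sum(wu[state == j]) - sum(wl[state == j + 1L])
    }
    gbeta <- -drop(crossprod(X, weights * (fu - fl) / Li))
    # chain rule to reparameterized theta
    gtheta <- numeric(K + p)
    gtheta[1L] <- sum(gc)
    if (K > 1L) {
      for (l in 2:K) {
        gtheta[l] <- exp(theta[l]) * sum(gc[l:K])
      }
    }
    gtheta[(K + 1L):(K + p)] <- gbeta
    list(ll = ll, grad = gtheta, grad_natural = c(gc, gbeta))
  }

  # start: marginal cumulative logits, beta = 0
  marg <- vapply(seq_len(J), function(j) sum(weights[state == j]), 0)
  cum <- cumsum(marg / sum(marg))
  c0 <- stats::qlogis(pmin(pmax(cum[seq_len(K)], 1e-4), 1 - 1e-4))
  c0 <- cummax(c0 + seq_len(K) * 1e-8)  # enforce strict order
  theta <- c(c0[1L], if (K > 1L) log(pmax(diff(c0), 1e-4)), rep(0, p))

  cur <- ll_grad(theta)
  converged <- FALSE
  iter <- 0L
  h <- 1e-5
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- cur$grad
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    # Hessian by central differences of the analytic gradient
    d <- length(theta)
    H <- matrix(0, d, d)
    for (k in seq_len(d)) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      H[, k] <- (ll_grad(tp)$grad - ll_grad(tm)$grad) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || sum(step * g) <= 0) {
      step <- g / max(1, sqrt(sum(g^2)))  # fallback: ascent direction
    }
    # step halving until the likelihood increases
    lambda <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- theta + lambda * step
      cand_eval <- ll_grad(cand)
      if (is.finite(cand_eval$ll) && cand_eval$ll > cur$ll) {
        theta <- cand
        cur <- cand_eval
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      if (sqrt(sum(cur$grad^2)) < sqrt(tol)) converged <- TRUE
      break
    }
  }
  if (!converged && sqrt(sum(cur$grad^2)) < tol) converged <- TRUE
  if (!converged) {
    warning("proportional-odds fit did not converge (gradient norm ",
            format(sqrt(sum(cur$grad^2)), digits = 3), " after ", iter,
            " iterations); possible separation")
  }

  cuts <- cut_from_theta(theta)
  beta <- theta[(K + 1L):(K + p)]
  names(beta) <- colnames(X)

  # observed information in the natural parameterization (c, beta)
  natural_grad <- function(par) {
    th <- c(par[1L], if (K > 1L) log(pmax(diff(par[seq_len(K)]), 1e-12)),
            par[(K + 1L):(K + p)])
    ll_grad(th)$grad_natural
  }
  par_nat <- c(cuts, beta)
  d <- K + p
  Hn <- matrix(0, d, d)
  for (k in seq_len(d)) {
    pp <- par_nat; pp[k] <- pp[k] + h
    pm <- par_nat; pm[k] <- pm[k] - h
    Hn[, k] <- (natural_grad(pp) - natural_grad(pm)) / (2 * h)
  }
  Hn <- (Hn + t(Hn)) / 2
  vc <- tryCatch(solve(-Hn), error = function(e) {
    matrix(NA_real_, d, d)
  })
  se <- sqrt(pmax(diag(vc)[(K + 1L):(K + p)], 0))
  names(se) <- names(beta)
  if (converged && (any(!is.finite(se)) || any(se > 100))) {
    # flat likelihood ridge: coefficients diverge under separation
    converged <- FALSE
    warning("proportional-odds fit did not converge to an interior ",
            "maximum (unbounded standard error); possible complete ",
            "separation")
  }
  z <- beta / se
  structure(
    list(cutpoints = cuts, coefficients = beta, se = se, z = z,
         p_value = 2 * stats::pnorm(-abs(z)), vcov = vc,
         log_likelihood = cur$ll, converged = converged, n_iter = iter,
         states = J),
    class = "po_fit"
  )
}

#' @export
print.po_fit <- function(x, ...) {
  cat("Proportional-odds fit (", x$states, " states, ",
      if (x$converged) "converged" else "NOT converged", ", ",
      x$n_iter, " iterations)\n", sep = "")
  cat("Cutpoints:", format(x$cutpoints, digits = 5), "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value)
  print(tab, digits = 5)
  cat("Log-likelihood:", format(x$log_likelihood, digits = 7), "\n")
  invisible(x)
}
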