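# Constrained Bethe free energy minimization by coordinate ascent for the
# supported conjugate pairs. Updates are closed form; the free-energy trace
# is evaluated after every coordinate update and must be non-increasing.

#' Conjugate coordinate ascent on a constrained Bethe free energy
#'
#' Supported model families:
#' \describe{
#'   \item{`beta_bernoulli`}{`theta ~ Beta(a, b)`, `y_i ~ Bernoulli(theta)`,
#'     functional form `q(theta) :: Beta`.}
#'   \item{`normal_known_precision`}{`mu ~ Normal(m0, v0)` (variance), data
#'     `y_i ~ Normal(mu, 1/tau)` with known precision `tau`; `q(mu)`
#'     Gaussian. Exact (conjugate) at the fixed point.}
#'   \item{`normal_gamma`}{`mu ~ Normal(m0, v0)`, `tau ~ Gamma(a0, b0)`,
#'     `y_i ~ Normal(mu, 1/tau)`, mean-field `q(mu, tau) = q(mu) q(tau)`.}
#' }
#' Anything else raises a `NotSupported` condition.
#'
#' @param model_spec List with `model` (one of the above), the family's
#'   hyperparameters, and `y` (numeric data vector).
#' @param graph Optional `ffg` graph; when given together with `family_tags`
#'   the functional-form tags are validated against the family the update
#'   equations assume.
#' @param local_factorization Optional; retained in the returned object.
#' @param family_tags Optional named map variable id -> family label, as
#'   returned by [apply_functional_form()].
#' @param max_iters Iteration budget.
#' @param tol Stop when the free energy improves by less than `tol`.
#' @param seed Optional seed (the updates are deterministic; the seed guards
#'   any randomized initialization a family might use).
#' @return An `ffg_cbfe_result`: `posterior` (named parameter list),
#'   `trace` (free energy per iteration, nats), `converged`, `iterations`,
#'   `diagnostics`.
#' @export
cbfe_coordinate_ascent <- function(model_spec, graph = NULL,
                                   local_factorization = NULL, family_tags = NULL,
                                   max_iters = 50L, tol = 1e-12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- model_spec$model
  if (is.null(model) ||
      !model %in% c("beta_bernoulli", "normal_known_precision", "normal_gamma")) {
    ffg_stop("not_supported", "no closed-form coordinate updates for model '%s'",
             if (is.null(model)) "<missing>" else model)
  }
  if (!is.null(family_tags) && model == "beta_bernoulli" &&
      length(family_tags) > 0L && !all(family_tags %in% "Beta")) {
    ffg_stop("not_supported", "beta_bernoulli requires q(theta) :: Beta")
  }
  res <- switch(model,
    beta_bernoulli = cbfe_beta_bernoulli(model_spec, max_iters, tol),
    normal_known_precision = cbfe_normal_known_precision(model_spec, max_iters, tol),
    normal_gamma = cbfe_normal_gamma(model_spec, max_iters, tol))
  diagnostics <- character(0)
  inc <- diff(res$trace)
  if (length(inc) > 0L && any(inc > 1e-9)) {
    diagnostics <- c(diagnostics, sprintf(
      "NonDecreasingEnergy: free energy increased by %.3g", max(inc)))
  }
  structure(list(model = model, posterior = res$posterior, trace = res$trace,
                 converged = res$converged, iterations = res$iterations,
                 local_factorization = local_factorization,
                 diagnostics = diagnostics),
            class = "ffg_cbfe_result")
}

#' @export
print.ffg_cbfe_result <- function(x, ...) {
  cat(sprintf("<ffg_cbfe_result> %s: converged = %s after %d iteration(s), F = %.6f nats\n",
              x$model, x$converged, x$iterations, x$trace[length(x$trace)]))
  str(x$posterior, give.head = FALSE)
  invisible(x)
}

#' Tidy the free-energy trace of a CBFE run
#' @param x An `ffg_cbfe_result`.
#' @export
tidy_trace <- function(x) {
  tibble::tibble(iteration = seq_along(x$trace) - 1L, free_energy = x$trace)
}

# F[q] for q(theta) = Beta(a, b) against prior Beta(a0, b0) and s successes
# out of n Bernoulli trials: E_q[log q - log p(theta) - sum log p(y_i|theta)]
beta_bernoulli_fe <- function(a, b, a0, b0, s, n) {
  elog <- digamma(a) - digamma(a + b)
  elog1m <- digamma(b) - digamma(a + b)
  # -H[q]
  neg_entropy <- -lbeta(a, b) + (a - 1) * elog + (b - 1) * elog1m
  e_log_prior <- -lbeta(a0, b0) + (a0 - 1) * elog + (b0 - 1) * elog1m
  e_log_lik <- s * elog + (n - s) * elog1m
  neg_entropy - e_log_prior - e_log_lik
}

cbfe_beta_bernoulli <- function(spec, max_iters, tol) {
  a0 <- spec$a %||% 1; b0 <- spec$b %||% 1
  y <- spec$y %||% numeric(0)
  if (length(y) > 0L && !all(y %in% c(0, 1))) {
    ffg_stop("not_supported", "beta_bernoulli data must be 0/1")
  }
  s <- sum(y); n <- length(y)
  a <- a0; b <- b0
  trace <- beta_bernoulli_fe(a, b, a0, b0, s, n)
  converged <- FALSE; iterations <- 0L
  for (it in seq_len(max_iters)) {
    a <- a0 + s
    b <- b0 + n - s
    trace <- c(trace, beta_bernoulli_fe(a, b, a0, b0, s, n))
    iterations <- it
    if (abs(trace[it + 1L] - trace[it]) < tol) { converged <- TRUE; break }
  }
  list(posterior = list(family = "Beta", a = a, b = b),
       trace = trace, converged = converged, iterations = iterations)
}

normal_known_prec_fe <- function(m, v, m0, v0, tau, y) {
  n <- length(y)
  # KL(q || prior) for Gaussians
  kl <- 0.5 * (log(v0 / v) + (v + (m - m0)^2) / v0 - 1)
  e_loglik <- sum(-0.5 * log(2 * pi) + 0.5 * log(tau) -
                    0.5 * tau * ((y - m)^2 + v))
  kl - e_loglik
}

cbfe_normal_known_precision <- function(spec, max_iters, tol) {
  m0 <- spec$m0 %||% 0; v0 <- spec$v0 %||% 1
  tau <- spec$tau
  if (is.null(tau) || tau <= 0) ffg_stop("not_supported", "known precision tau > 0 required")
  y <- spec$y %||% numeric(0)
  n <- length(y)
  m <- m0; v <- v0
  trace <- normal_known_prec_fe(m, v, m0, v0, tau, y)
  converged <- FALSE; iterations <- 0L
  for (it in seq_len(max_iters)) {
    v <- 1 / (1 / v0 + n * tau)
    m <- v * (m0 / v0 + tau * sum(y))
    trace <- c(trace, normal_known_prec_fe(m, v, m0, v0, tau, y))
    iterations <- it
    if (abs(trace[it + 1L] - trace[it]) < tol) { converged <- TRUE; break }
  }
  list(posterior = list(family = "Normal", mean = m, var = v),
       trace = trace, converged = converged, iterations = iterations)
}

normal_gamma_fe <- function(m, v, a, b, m0, v0, a0, b0, y) {
  n <- length(y)
  e_tau <- a / b
  e_logtau <- digamma(a) - log(b)
  kl_mu <- 0.5 * (log(v0 / v) + (v + (m - m0)^2) / v0 - 1)
  kl_tau <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  e_loglik <- sum(-0.5 * log(2 * pi) + 0.5 * e_logtau -
                    0.5 * e_tau * ((y - m)^2 + v))
  kl_mu + kl_tau - e_loglik
}

cbfe_normal_gamma <- function(spec, max_iters, tol) {
  m0 <- spec$m0 %||% 0; v0 <- spec$v0 %||% 1
  a0 <- spec$a0 %||% 1; b0 <- spec$b0 %||% 1
  y <- spec$y
  if (is.null(y) || length(y) == 0L) {
    # no data: the mean-field optimum is the prior itself
    return(list(posterior = list(mu = list(mean = m0, var = v0),
                                 tau = list(shape = a0, rate = b0)),
                trace = normal_gamma_fe(m0, v0, a0, b0, m0, v0, a0, b0, numeric(0)),
                converged = TRUE, iterations = 0L))
  }
  n <- length(y)
  m <- m0; v <- v0; a <- a0; b <- b0
  trace <- normal_gamma_fe(m, v, a, b, m0, v0, a0, b0, y)
  converged <- FALSE; iterations <- 0L
  for (it in seq_len(max_iters)) {
    e_tau <- a / b
    v <- 1 / (1 / v0 + n * e_tau)
    m <- v * (m0 / v0 + e_tau * sum(y))
    a <- a0 + n / 2
    b <- b0 + 0.5 * sum((y - m)^2 + v)
    trace <- c(trace, normal_gamma_fe(m, v, a, b, m0, v0, a0, b0, y))
    iterations <- it
    if (abs(trace[it + 1L] - trace[it]) < tol) { converged <- TRUE; break }
  }
  list(posterior = list(mu = list(mean = m, var = v),
                        tau = list(shape = a, rate = b)),
       trace = trace, converged = converged, iterations = iterations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
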