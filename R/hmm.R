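# Unsupervised two-state Gaussian hidden Markov model on log(1 + MIMS).
#
# The sleep state is identified after fitting as the state with the smaller
# emission mean; EM label-switching is therefore harmless. Recursions run in
# compiled code with per-step scaling (stable for week-long, 10080-minute
# series).

#' Log(1 + x) activity transform
#'
#' Monotone variance-stabilising transform applied to per-minute MIMS
#' before HMM fitting; maps 0 to 0.
#'
#' @param x non-negative activity values (masking must already have removed
#'   the \code{-0.01} sentinel)
#' @return \code{log(1 + x)}
#' @export
transform_counts <- function(x) {
  .assert(!anyNA(x) && all(x >= 0),
          "activity values must be non-negative and non-missing (mask and impute first)",
          "actisleep_error")
  log1p(x)
}

.check_model <- function(model) {
  .assert(inherits(model, "sleep_hmm"), "model must be a sleep_hmm object",
          "actisleep_error")
  .assert(abs(sum(model$pi) - 1) < 1e-8 &&
            all(abs(rowSums(model$A) - 1) < 1e-8) && all(model$sd > 0),
          "invalid HMM parameters", "actisleep_error")
}

.new_hmm <- function(pi, A, mu, sd, ...) {
  structure(list(pi = as.numeric(pi), A = matrix(as.numeric(A), 2, 2),
                 mu = as.numeric(mu), sd = as.numeric(sd),
                 sleep_state = which.min(mu), ...),
            class = "sleep_hmm")
}

#' Construct a two-state HMM from explicit parameters
#'
#' @param pi initial state probabilities (length 2)
#' @param A 2x2 transition matrix (rows sum to 1)
#' @param mu,sd per-state Gaussian emission parameters on the transformed
#'   scale
#' @return a \code{sleep_hmm} object; the sleep state is the state with the
#'   smaller emission mean
#' @export
sleep_hmm_model <- function(pi, A, mu, sd) {
  m <- .new_hmm(pi, A, mu, sd)
  .check_model(m)
  m
}

#' Exact forward log-likelihood
#'
#' Scaled forward recursion; the exact marginal log-likelihood of the
#' series summed over all \eqn{2^T} state paths.
#'
#' @param model a \code{sleep_hmm}
#' @param y transformed activity series
#' @return log-likelihood (scalar)
#' @export
forward_loglik <- function(model, y) {
  .check_model(model)
  .assert(length(y) >= 1 && all(is.finite(y)), "y must be finite",
          "actisleep_error")
  .hmm_forward_cpp(as.numeric(y), model$pi, model$A, model$mu, model$sd)
}

#' Brute-force log-likelihood by path enumeration
#'
#' Test oracle: enumerates all \eqn{2^T} state paths (refused for
#' \eqn{T > 16}) and log-sum-exps their joint densities. Independent of the
#' forward recursion.
#'
#' @inheritParams forward_loglik
#' @return log-likelihood (scalar)
#' @export
brute_force_loglik <- function(model, y) {
  .check_model(model)
  T <- length(y)
  .assert(T <= 16, "brute-force enumeration refused for T > 16",
          "actisleep_error")
  lb <- cbind(dnorm(y, model$mu[1], model$sd[1], log = TRUE),
              dnorm(y, model$mu[2], model$sd[2], log = TRUE))
  lpi <- log(model$pi); lA <- log(model$A)
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  lp <- lpi[paths[, 1]] + lb[cbind(1L, paths[, 1])]
  if (T > 1) for (t in 2:T)
    lp <- lp + lA[cbind(paths[, t - 1], paths[, t])] +
      lb[cbind(t, paths[, t])]
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

.init_hmm <- function(y, init, seed) {
  if (init == "quantile_split") {
    mu <- as.numeric(quantile(y, c(0.25, 0.75), names = FALSE))
  } else {
    if (!is.null(seed)) set.seed(seed)
    km <- kmeans(y, centers = 2, nstart = 3)
    mu <- sort(km$centers[, 1])
  }
  s <- max(sd(y) / 2, 1e-3)
  list(pi = c(0.5, 0.5), A = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2),
       mu = mu, sd = c(s, s))
}

#' Fit a two-state sleep/wake HMM by Baum-Welch EM
#'
#' Unsupervised fit of a two-state Gaussian HMM to a transformed
#' (\code{log(1+x)}) minute-level activity series, typically one subject's
#' concatenated 7-day recording. The log-likelihood is non-decreasing over
#' iterations; fitting stops when the relative increase falls below
#' \code{tol} or after \code{max_iter} iterations. The sleep state is the
#' lower-mean state.
#'
#' A (near-)constant series cannot support two emission components; the fit
#' is then flagged \code{degenerate} and downstream scoring should skip the
#' subject.
#'
#' @param y transformed activity series (length >= 100 recommended)
#' @param init \code{"quantile_split"} (deterministic: state means started
#'   at the 25th/75th percentiles) or \code{"kmeans"} (seeded)
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations
#' @param seed seed for \code{init = "kmeans"}
#' @return object of class \code{sleep_hmm} with elements \code{pi},
#'   \code{A}, \code{mu}, \code{sd}, \code{sleep_state}, \code{logLik},
#'   \code{loglik_trace}, \code{n_iter}, \code{converged},
#'   \code{degenerate}, \code{n}
#' @export
sleep_hmm <- function(y, init = c("quantile_split", "kmeans"), tol = 1e-6,
                      max_iter = 200L, seed = NULL) {
  init <- match.arg(init)
  y <- as.numeric(y)
  .assert(length(y) >= 2 && all(is.finite(y)),
          "y must be a finite series of length >= 2", "actisleep_error")
  if (sd(y) < 1e-8) {
    m <- .new_hmm(c(1, 0), diag(2) * 0.98 + 0.01, c(mean(y), mean(y) + 1),
                  c(1e-3, 1e-3), degenerate = TRUE, converged = FALSE,
                  logLik = NA_real_, loglik_trace = numeric(0),
                  n_iter = 0L, n = length(y))
    return(m)
  }
  p <- .init_hmm(y, init, seed)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- .hmm_fb_cpp(y, p$pi, p$A, p$mu, p$sd)
    trace <- c(trace, fb$loglik)
    g <- fb$gamma
    p$pi <- pmax(g[1, ], 1e-12); p$pi <- p$pi / sum(p$pi)
    A <- fb$xi
    A <- pmax(A, 1e-12)
    p$A <- A / rowSums(A)
    ng <- colSums(g)
    p$mu <- colSums(g * y) / ng
    p$sd <- pmax(sqrt(colSums(g * (y - rep(p$mu, each = length(y)))^2) / ng),
                 1e-3)
    if (is.finite(ll_old) &&
        (fb$loglik - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- fb$loglik
  }
  .new_hmm(p$pi, p$A, p$mu, p$sd, degenerate = FALSE, converged = converged,
           logLik = trace[length(trace)], loglik_trace = trace,
           n_iter = length(trace), n = length(y))
}

#' Decode per-minute sleep/wake states
#'
#' \code{rule = "posterior"} (default) labels a minute sleep iff its
#' forward-backward smoothed marginal probability of the sleep state
#' exceeds 0.5 (an exact tie decodes to wake); \code{rule = "viterbi"}
#' returns the joint MAP path.
#'
#' @param model a fitted \code{sleep_hmm}
#' @param y the transformed series the model is applied to
#' @param rule \code{"posterior"} or \code{"viterbi"}
#' @return data.frame with columns \code{sleep} (logical) and
#'   \code{post_sleep} (posterior probability of the sleep state)
#' @export
decode <- function(model, y, rule = c("posterior", "viterbi")) {
  rule <- match.arg(rule)
  .check_model(model)
  .assert(!isTRUE(model$degenerate),
          "degenerate fit: decoding skipped for this subject",
          "actisleep_error")
  y <- as.numeric(y)
  fb <- .hmm_fb_cpp(y, model$pi, model$A, model$mu, model$sd)
  ps <- fb$gamma[, model$sleep_state]
  if (rule == "posterior") {
    sleep <- ps > 0.5
  } else {
    path <- .hmm_viterbi_cpp(y, model$pi, model$A, model$mu, model$sd)
    sleep <- (path + 1L) == model$sleep_state
  }
  data.frame(sleep = sleep, post_sleep = ps)
}

# S3 methods ----------------------------------------------------------------

#' @export
print.sleep_hmm <- function(x, ...) {
  cat("Two-state sleep/wake HMM (Gaussian emissions on log(1 + MIMS))\n")
  if (isTRUE(x$degenerate)) {
    cat("  DEGENERATE fit (constant series); scoring should be skipped\n")
    return(invisible(x))
  }
  st <- ifelse(seq_len(2) == x$sleep_state, "sleep", "wake")
  for (k in 1:2)
    cat(sprintf("  state %d (%s): mean %.3f, sd %.3f, self-transition %.4f\n",
                k, st[k], x$mu[k], x$sd[k], x$A[k, k]))
  cat(sprintf("  logLik %.2f after %d EM iterations (%s), n = %d\n",
              x$logLik, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$n))
  invisible(x)
}

#' @export
summary.sleep_hmm <- function(object, ...) {
  print(object)
  if (!isTRUE(object$degenerate)) {
    st <- object$A
    statd <- c(st[2, 1], st[1, 2]) / (st[1, 2] + st[2, 1])
    cat(sprintf("  stationary distribution: %.3f / %.3f\n",
                statd[1], statd[2]))
    cat(sprintf("  expected dwell (min): state 1 %.1f, state 2 %.1f\n",
                1 / (1 - st[1, 1]), 1 / (1 - st[2, 2])))
  }
  invisible(object)
}

#' @export
coef.sleep_hmm <- function(object, ...) {
  list(pi = object$pi, A = object$A,
       emissions = cbind(mean = object$mu, sd = object$sd),
       sleep_state = object$sleep_state)
}

#' @export
logLik.sleep_hmm <- function(object, ...) {
  structure(object$logLik, df = 7, nobs = object$n, class = "logLik")
}

#' @export
predict.sleep_hmm <- function(object, y, rule = c("posterior", "viterbi"),
                              ...) {
  decode(object, y, match.arg(rule))
}

#' Simulate a series from a fitted (or constructed) two-state HMM
#'
#' @param object a \code{sleep_hmm}
#' @param nsim series length
#' @param seed optional seed
#' @param ... unused
#' @return data.frame with the hidden \code{state} (1/2) and emitted
#'   \code{y}
#' @export
simulate.sleep_hmm <- function(object, nsim = 1440L, seed = NULL, ...) {
  .check_model(object)
  if (!is.null(seed)) set.seed(seed)
  s <- integer(nsim)
  s[1] <- sample(1:2, 1, prob = object$pi)
  for (t in seq_len(nsim)[-1])
    s[t] <- sample(1:2, 1, prob = object$A[s[t - 1], ])
  data.frame(state = s, y = rnorm(nsim, object$mu[s], object$sd[s]))
}
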