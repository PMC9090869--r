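# Design-based estimation for stratified multi-PSU samples with analysis
# weights: Taylor-linearized (with-replacement PSU) variance for means,
# totals, weighted least squares and proportional-odds regression, plus
# weighted quantiles.
#
# Variance convention: for a statistic with per-unit influence values d_i,
#   V = sum_h n_h/(n_h - 1) * sum_j (u_hj - ubar_h) (u_hj - ubar_h)'
# where u_hj is the sum of d_i over PSU j of stratum h. A stratum with a
# single PSU among analyzed cases ("lonely PSU") contributes its deviation
# from the grand mean of all PSU totals. Design degrees of freedom:
# #PSUs - #strata.

#' Nine standard age groups
#'
#' 6-13, 14-17, 18-25, 26-35, 36-45, 46-55, 56-65, 66-75, >=76.
#'
#' @param age age in years
#' @return ordered factor
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 13, 17, 25, 35, 45, 55, 65, 75, Inf),
      labels = c("6-13", "14-17", "18-25", "26-35", "36-45", "46-55",
                 "56-65", "66-75", ">=76"), ordered_result = TRUE)
}

.age_group <- age_group

#' Quartic age basis on scaled age
#'
#' Raw age raised to the fourth power is numerically hostile; all age-trend
#' models use powers of \eqn{s = (age - 45)/40} instead. The synthetic
#' generator's curves live on the same basis, so fitted coefficients are
#' directly comparable to generator coefficients.
#'
#' @param age age in years
#' @param degree polynomial degree (default 4)
#' @return matrix with columns \code{age1..age<degree>}
#' @export
age_basis <- function(age, degree = 4L) {
  s <- .age_s(age)
  m <- sapply(seq_len(degree), function(k) s^k)
  colnames(m) <- paste0("age", seq_len(degree))
  m
}

#' Combine two 2-year cycles into 4-year analysis weights
#'
#' For two equal-length combined cycles the 4-year weight is half the
#' 2-year exam weight. Subjects with a missing weight are dropped (with a
#' message). If only one cycle is present the weights pass through
#' unhalved under \code{single_cycle = "keep"} (with a warning), otherwise
#' this is an error.
#'
#' @param demographics data.frame with \code{weight_2yr} and \code{cycle}
#' @param single_cycle \code{"error"} or \code{"keep"}
#' @return the input with an added \code{weight_4yr} column
#' @export
four_year_weights <- function(demographics, single_cycle = c("error", "keep")) {
  single_cycle <- match.arg(single_cycle)
  drop <- is.na(demographics$weight_2yr)
  if (any(drop)) {
    message(sum(drop), " subject(s) dropped: missing 2-year weight")
    demographics <- demographics[!drop, ]
  }
  cycles <- unique(demographics$cycle)
  if (length(cycles) < 2) {
    if (single_cycle == "error")
      .assert(FALSE, "only one cycle present; pass single_cycle = \"keep\" to use 2-year weights as-is",
              "actisleep_validation_error")
    warning("single cycle: weights passed through unhalved")
    demographics$weight_4yr <- demographics$weight_2yr
  } else {
    demographics$weight_4yr <- demographics$weight_2yr / 2
  }
  demographics
}

#' Survey design object
#'
#' @param strata stratum identifiers
#' @param psu primary-sampling-unit identifiers (nested in strata)
#' @param weights positive analysis weights
#' @return object of class \code{svy_design}
#' @export
svy_design <- function(strata, psu, weights) {
  n <- length(weights)
  .assert(length(strata) == n && length(psu) == n,
          "strata, psu, weights must have equal length", "actisleep_error")
  .assert(all(is.finite(weights) & weights > 0),
          "weights must be positive", "actisleep_validation_error")
  cl <- interaction(strata, psu, drop = TRUE)
  structure(list(strata = as.character(strata), psu = as.character(psu),
                 cluster = cl, weights = as.numeric(weights), n = n),
            class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  np <- length(unique(paste(x$strata, x$psu)))
  nh <- length(unique(x$strata))
  cat(sprintf("Survey design: %d units, %d strata, %d PSUs (design df %d)\n",
              x$n, nh, np, np - nh))
  invisible(x)
}

.design_subset <- function(design, idx) {
  svy_design(design$strata[idx], design$psu[idx], design$weights[idx])
}

.design_df <- function(design) {
  length(unique(paste(design$strata, design$psu))) -
    length(unique(design$strata))
}

# Taylor-linearized covariance of a total of per-unit influence rows U
# (n x p, already weighted)
.taylor_vcov <- function(U, design) {
  U <- as.matrix(U)
  key <- paste(design$strata, design$psu, sep = "\r")
  tot <- rowsum(U, key, reorder = FALSE)
  str_of <- vapply(strsplit(rownames(tot), "\r", fixed = TRUE), `[`,
                   character(1), 1)
  p <- ncol(U)
  V <- matrix(0, p, p)
  grand <- colMeans(tot)
  for (h in unique(str_of)) {
    rows <- which(str_of == h)
    nh <- length(rows)
    if (nh == 1) {            # lonely PSU: center at the grand mean
      warning("lonely PSU in stratum '", h,
              "': contribution centered at the grand mean", call. = FALSE)
      d <- tot[rows, ] - grand
      V <- V + tcrossprod(d)
    } else {
      ctr <- sweep(tot[rows, , drop = FALSE], 2, colMeans(tot[rows, ,
                                                              drop = FALSE]))
      V <- V + nh / (nh - 1) * crossprod(ctr)
    }
  }
  V
}

#' Design-based weighted mean and standard error
#'
#' Horvitz-Thompson ratio mean with Taylor-linearized SE.
#'
#' @param x values, aligned with the design
#' @param design a \code{\link{svy_design}}
#' @param na.rm drop missing values (subsetting the design accordingly)
#' @return named vector \code{c(mean, se)}
#' @export
svy_mean <- function(x, design, na.rm = FALSE) {
  .assert(length(x) == design$n, "x must align with the design",
          "actisleep_error")
  if (na.rm && anyNA(x)) {
    keep <- !is.na(x)
    design <- .design_subset(design, keep)
    x <- x[keep]
  }
  w <- design$weights
  W <- sum(w)
  mu <- sum(w * x) / W
  z <- w * (x - mu) / W
  c(mean = mu, se = sqrt(.taylor_vcov(matrix(z, ncol = 1), design)[1, 1]))
}

#' Design-based weighted total
#'
#' @inheritParams svy_mean
#' @return named vector \code{c(total, se)}
#' @export
svy_total <- function(x, design) {
  w <- design$weights
  c(total = sum(w * x),
    se = sqrt(.taylor_vcov(matrix(w * x, ncol = 1), design)[1, 1]))
}

#' Weighted quantiles by lower inverse of the weighted CDF
#'
#' \eqn{q(p) = \min\{x : F_w(x) \ge p\}} where \eqn{F_w} is the weighted
#' empirical CDF. This step-function rule is exactly invertible, invariant
#' to weight rescaling, and reduces to the usual type-1 sample quantile
#' under equal weights.
#'
#' @param x values
#' @param weights positive weights
#' @param probs probabilities (default the 5/10/25/50/75/90 percentiles)
#' @return named numeric vector of quantiles
#' @export
svy_quantile <- function(x, weights,
                         probs = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90)) {
  .assert(length(x) > 0 && length(x) == length(weights),
          "x and weights must be non-empty and aligned", "actisleep_error")
  o <- order(x)
  cw <- cumsum(weights[o])
  W <- cw[length(cw)]
  out <- vapply(probs, function(p) x[o][which(cw >= p * W)[1]], numeric(1))
  names(out) <- paste0(format(100 * probs, trim = TRUE), "%")
  out
}

# svy_lm ---------------------------------------------------------------------

#' Survey-weighted linear regression with linearized covariance
#'
#' Weighted least squares point estimates with a design-based sandwich
#' covariance (Taylor linearization over strata/PSUs). With equal weights
#' and a single stratum the point estimates coincide with ordinary least
#' squares.
#'
#' By default the cluster-level leverage adjustment of Bell-McCaffrey
#' (CR2, the bias-reduced linearization used for few-cluster inference)
#' is applied to the PSU score contributions before the stratified
#' between-PSU variance is formed; the plain estimator underestimates
#' variance when the number of PSUs is modest relative to the number of
#' regression parameters. \code{small_sample = "none"} gives the classical
#' unadjusted linearization.
#'
#' @param formula model formula
#' @param data data.frame, rows aligned with the design
#' @param design a \code{\link{svy_design}}
#' @param small_sample \code{"cr2"} (default) or \code{"none"}
#' @return object of class \code{svy_lm} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{predict},
#'   \code{residuals}
#' @export
svy_lm <- function(formula, data, design, small_sample = c("cr2", "none")) {
  small_sample <- match.arg(small_sample)
  .assert(nrow(data) == design$n, "data rows must align with the design",
          "actisleep_error")
  mf <- model.frame(formula, data, na.action = NULL)
  keep <- complete.cases(mf)
  if (!all(keep)) {
    mf <- mf[keep, , drop = FALSE]
    design <- .design_subset(design, keep)
  }
  X <- model.matrix(attr(mf, "terms"), mf)
  y <- model.response(mf)
  w <- design$weights
  qrX <- qr(X * sqrt(w))
  .assert(qrX$rank == ncol(X),
          paste("rank-deficient design matrix; collinear columns:",
                paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]],
                      collapse = ", ")), "actisleep_error")
  XtWX <- crossprod(X * sqrt(w))
  beta <- drop(solve(XtWX, crossprod(X, w * y)))
  names(beta) <- colnames(X)
  e <- drop(y - X %*% beta)
  M <- solve(XtWX)
  scores <- X * (w * e)                     # per-unit score contributions
  if (small_sample == "cr2") {
    # leverage-adjust residuals per PSU: e*_j = (I - H~_jj)^{-1/2} e~_j in
    # the sqrt(w) metric, the weighted Bell-McCaffrey adjustment
    cl <- paste(design$strata, design$psu, sep = "\r")
    for (j in unique(cl)) {
      i <- which(cl == j)
      Xs <- X[i, , drop = FALSE] * sqrt(w[i])
      Hs <- Xs %*% M %*% t(Xs)
      es <- eigen(diag(length(i)) - Hs, symmetric = TRUE)
      Ai <- es$vectors %*% (t(es$vectors) / sqrt(pmax(es$values, 1e-10)))
      scores[i, ] <- Xs * drop(Ai %*% (sqrt(w[i]) * e[i]))
    }
  }
  infl <- scores %*% M                      # per-unit influence on beta
  V <- .taylor_vcov(infl, design)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = V, residuals = e,
                 fitted.values = drop(X %*% beta),
                 df_design = .design_df(design), n = length(y),
                 formula = formula, terms = attr(mf, "terms"),
                 xlevels = .getXlevels(attr(mf, "terms"), mf),
                 contrasts = attr(X, "contrasts")),
            class = "svy_lm")
}

#' @importFrom stats .getXlevels residuals
#' @export
coef.svy_lm <- function(object, ...) object$coefficients

#' @export
vcov.svy_lm <- function(object, ...) object$vcov

#' @export
residuals.svy_lm <- function(object, ...) object$residuals

#' @export
print.svy_lm <- function(x, ...) {
  cat("Survey-weighted linear regression\n")
  cat(sprintf("  n = %d, design df = %d\n", x$n, x$df_design))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.svy_lm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  t <- object$coefficients / se
  p <- 2 * pt(-abs(t), object$df_design)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = t, `Pr(>|t|)` = p)
  out <- list(coefficients = tab, df_design = object$df_design,
              n = object$n, formula = object$formula)
  class(out) <- "summary.svy_lm"
  out
}

#' @export
print.summary.svy_lm <- function(x, ...) {
  cat("Survey-weighted linear regression\n")
  cat(sprintf("  n = %d, design df = %d\n\n", x$n, x$df_design))
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.svy_lm <- function(object, newdata, se.fit = FALSE, ...) {
  X <- model.matrix(delete.response(terms(object$formula)), newdata,
                    xlev = object$xlevels, contrasts.arg = object$contrasts)
  fit <- drop(X %*% object$coefficients)
  if (!se.fit) return(fit)
  list(fit = fit, se.fit = sqrt(rowSums((X %*% object$vcov) * X)))
}

#' @importFrom stats delete.response
#' @keywords internal
NULL

#' Design-adjusted Wald test of a coefficient block
#'
#' Korn-Graubard adjusted Wald test: with Wald statistic
#' \eqn{W = (R\beta)'(RVR')^{-1}(R\beta)}, design degrees of freedom df
#' (#PSUs - #strata) and d restrictions, the statistic
#' \eqn{F = W (\mathrm{df} - d + 1)/(\mathrm{df}\, d)} is referred to
#' \eqn{F(d, \mathrm{df} - d + 1)} (the default adjustment in standard
#' survey software; it counters the over-rejection of multi-df Wald tests
#' under a noisily estimated covariance).
#'
#' @param fit a \code{\link{svy_lm}} or \code{\link{svy_polr}}
#' @param pattern regular expression selecting coefficient names, or an
#'   integer/character index vector
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{terms}
#' @export
svy_wald <- function(fit, pattern) {
  b <- coef(fit)
  V <- vcov(fit)[names(b), names(b)]
  idx <- if (is.character(pattern) && length(pattern) == 1 &&
             !pattern %in% names(b)) grep(pattern, names(b)) else
               match(pattern, names(b))
  .assert(length(idx) > 0 && !anyNA(idx),
          "pattern selects no coefficients", "actisleep_error")
  d <- length(idx)
  W <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE], b[idx]))
  df2 <- fit$df_design - d + 1
  .assert(df2 > 0, "not enough design df for this Wald test",
          "actisleep_error")
  Fst <- W * df2 / (fit$df_design * d)
  list(F = Fst, df1 = d, df2 = df2, p = pf(Fst, d, df2, lower.tail = FALSE),
       terms = names(b)[idx])
}

# svy_polr -------------------------------------------------------------------

.polr_zeta <- function(theta, K) {
  if (K == 2) theta[1] else cumsum(c(theta[1], exp(theta[2:(K - 1)])))
}

.polr_nll <- function(theta, X, yk, K, w) {
  zeta <- .polr_zeta(theta, K)
  beta <- theta[-(1:(K - 1))]
  eta <- drop(X %*% beta)
  Fm <- cbind(0, plogis(outer(-eta, zeta, `+`)), 1)
  P <- pmax(Fm[cbind(seq_along(yk), yk + 1L)] -
              Fm[cbind(seq_along(yk), yk)], 1e-12)
  -sum(w * log(P))
}

# scores in the natural (zeta, beta) parametrization, one row per unit,
# weighted
.polr_scores <- function(zeta, beta, X, yk, K, w) {
  n <- length(yk)
  eta <- drop(X %*% beta)
  Fm <- cbind(0, plogis(outer(-eta, zeta, `+`)), 1)
  fm <- Fm * (1 - Fm)
  P <- pmax(Fm[cbind(seq_len(n), yk + 1L)] - Fm[cbind(seq_len(n), yk)],
            1e-12)
  S <- matrix(0, n, (K - 1) + ncol(X))
  for (j in seq_len(K - 1)) {
    dj <- (yk == j) * fm[, j + 1L] - (yk == j + 1L) * fm[, j + 1L]
    # dP/dzeta_j = f(zeta_j - eta) (1{y=j} - 1{y=j+1})
    S[, j] <- w * dj / P
  }
  dPdeta <- -fm[cbind(seq_len(n), yk + 1L)] + fm[cbind(seq_len(n), yk)]
  S[, K:ncol(S)] <- (w * dPdeta / P) * X
  S
}

#' Survey-weighted proportional-odds (ordinal logistic) regression
#'
#' Fits \eqn{\mathrm{logit}\,P(Y \le k) = \zeta_k - x'\beta} by weighted
#' maximum likelihood (so positive coefficients shift mass to higher
#' categories, the MASS::polr convention), with a design-based linearized
#' sandwich covariance.
#'
#' @param formula model formula; the response must be an ordered factor (or
#'   coercible to one)
#' @param data data.frame aligned with the design
#' @param design a \code{\link{svy_design}}
#' @return object of class \code{svy_polr} with \code{coefficients}
#'   (\eqn{\beta}), \code{zeta}, \code{vcov} (for \eqn{\beta}),
#'   \code{df_design}
#' @export
svy_polr <- function(formula, data, design) {
  .assert(nrow(data) == design$n, "data rows must align with the design",
          "actisleep_error")
  mf <- model.frame(formula, data, na.action = NULL)
  keep <- complete.cases(mf)
  if (!all(keep)) {
    mf <- mf[keep, , drop = FALSE]
    design <- .design_subset(design, keep)
  }
  y <- model.response(mf)
  if (!is.factor(y)) y <- factor(y, ordered = TRUE)
  yk <- as.integer(y)
  K <- nlevels(y)
  .assert(K >= 2, "response needs >= 2 ordered categories",
          "actisleep_error")
  X <- model.matrix(attr(mf, "terms"), mf)[, -1, drop = FALSE]
  w <- design$weights
  tabw <- vapply(seq_len(K), function(k) sum(w[yk == k]), numeric(1))
  .assert(all(tabw > 0), "empty response category under the weights",
          "actisleep_error")
  cum <- cumsum(tabw) / sum(tabw)
  z0 <- qlogis(cum[-K])
  theta0 <- c(z0[1], if (K > 2) log(pmax(diff(z0), 1e-3)),
              rep(0, ncol(X)))
  opt <- optim(theta0, .polr_nll, X = X, yk = yk, K = K, w = w,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  zeta <- .polr_zeta(opt$par, K)
  beta <- opt$par[-(1:(K - 1))]
  names(beta) <- colnames(X)
  names(zeta) <- paste(levels(y)[-K], levels(y)[-1], sep = "|")
  # observed information in the natural parametrization
  nat_nll <- function(par) {
    z <- par[1:(K - 1)]; b <- par[-(1:(K - 1))]
    eta <- drop(X %*% b)
    Fm <- cbind(0, plogis(outer(-eta, z, `+`)), 1)
    P <- pmax(Fm[cbind(seq_along(yk), yk + 1L)] -
                Fm[cbind(seq_along(yk), yk)], 1e-12)
    -sum(w * log(P))
  }
  H <- optimHess(c(zeta, beta), nat_nll)
  S <- .polr_scores(zeta, beta, X, yk, K, w)
  G <- .taylor_vcov(S, design)
  Hi <- solve(H)
  V <- Hi %*% G %*% Hi
  pn <- c(names(zeta), names(beta))
  dimnames(V) <- list(pn, pn)
  bidx <- K:(K - 1 + ncol(X))
  structure(list(coefficients = beta, zeta = zeta,
                 vcov = V[bidx, bidx, drop = FALSE], vcov_full = V,
                 df_design = .design_df(design), n = length(yk),
                 levels = levels(y), logLik = -opt$value,
                 convergence = opt$convergence, formula = formula),
            class = "svy_polr")
}

#' @export
coef.svy_polr <- function(object, ...) object$coefficients

#' @export
vcov.svy_polr <- function(object, ...) object$vcov

#' @export
print.svy_polr <- function(x, ...) {
  cat("Survey-weighted proportional-odds regression\n")
  cat(sprintf("  n = %d, %d categories, design df = %d\n", x$n,
              length(x$levels), x$df_design))
  se <- sqrt(diag(x$vcov))
  t <- x$coefficients / se
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = se,
               `t value` = t,
               `Pr(>|t|)` = 2 * pt(-abs(t), x$df_design))
  printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  cat("Cutpoints:\n"); print(round(x$zeta, 4))
  invisible(x)
}

#' @export
summary.svy_polr <- function(object, ...) print(object)

# table-shaped outputs -------------------------------------------------------

#' Population summary (Table-1 shape)
#'
#' Weighted mean age, sex/race percentages, and weighted means with SEs of
#' the three sleep parameters, plus the estimated population size.
#'
#' @param data per-subject analysis table with \code{age_years},
#'   \code{sex}, \code{race}, \code{mean_duration_h},
#'   \code{mean_onset_clock}, \code{mean_efficiency}
#' @param design a \code{\link{svy_design}}
#' @return data.frame with columns \code{variable}, \code{estimate},
#'   \code{se}
#' @export
population_summary <- function(data, design) {
  w <- design$weights
  rows <- list()
  add <- function(v, est, se = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(variable = v, estimate = est,
                                             se = se)
  m <- svy_mean(data$age_years, design); add("age_years", m[1], m[2])
  add("female_pct", 100 * sum(w * (data$sex == "female")) / sum(w))
  for (r in .RACE_LEVELS)
    add(paste0("race_", gsub(" ", "_", r), "_pct"),
        100 * sum(w * (data$race == r)) / sum(w))
  for (v in c("mean_duration_h", "mean_onset_clock", "mean_efficiency")) {
    m <- svy_mean(data[[v]], design); add(v, m[1], m[2])
  }
  add("n_subjects", nrow(data))
  add("population_size", sum(w))
  do.call(rbind, rows)
}

#' Weighted quantile grid by age group (Table-2 shape)
#'
#' @param data per-subject analysis table
#' @param design a \code{\link{svy_design}}
#' @param outcomes columns to summarize
#' @param probs quantile probabilities
#' @return long data.frame: \code{age_group}, \code{n}, \code{outcome},
#'   one column per quantile
#' @export
quantile_table <- function(data, design,
                           outcomes = c("mean_onset_clock",
                                        "mean_duration_h",
                                        "mean_efficiency"),
                           probs = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90)) {
  g <- .age_group(data$age_years)
  out <- list()
  for (lev in levels(g)) {
    idx <- which(g == lev)
    for (oc in outcomes) {
      if (!length(idx)) {
        q <- setNames(rep(NA_real_, length(probs)),
                      paste0(format(100 * probs, trim = TRUE), "%"))
      } else {
        q <- svy_quantile(data[[oc]][idx], design$weights[idx], probs)
      }
      out[[length(out) + 1L]] <-
        cbind(data.frame(age_group = lev, n = length(idx), outcome = oc),
              as.data.frame(as.list(q), check.names = FALSE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quartic-age trend regression for a sleep parameter
#'
#' Survey-weighted regression of the outcome on the quartic age basis, sex
#' and race, with optional sex-by-age and race-by-age interaction blocks,
#' block Wald tests, and a fitted-curve grid (ages 6-85 by 1 year, per sex
#' and race) for plotting.
#'
#' @param outcome outcome column name (e.g. \code{"mean_onset_clock"})
#' @param data per-subject analysis table (needs \code{age_years},
#'   \code{sex}, \code{race})
#' @param design a \code{\link{svy_design}}
#' @param interactions character subset of \code{c("sex", "race")}
#' @return list of class \code{sleep_trend}: \code{fit} (a
#'   \code{\link{svy_lm}}), \code{wald} (sex, race and interaction block
#'   tests), \code{curves} (fitted grid)
#' @export
sleep_trend <- function(outcome, data, design,
                        interactions = character(0)) {
  d <- cbind(data, age_basis(data$age_years))
  d$sex <- droplevels(factor(d$sex, levels = .SEX_LEVELS))
  d$race <- droplevels(factor(d$race, levels = .RACE_LEVELS))
  age_terms <- paste0("age", 1:4)
  rhs <- c(age_terms, if (nlevels(d$sex) > 1) "sex",
           if (nlevels(d$race) > 1) "race")
  if ("sex" %in% interactions)
    rhs <- c(rhs, paste0("sex:", age_terms))
  if ("race" %in% interactions)
    rhs <- c(rhs, paste0("race:", age_terms))
  f <- stats::reformulate(rhs, response = outcome)
  fit <- svy_lm(f, d, design)
  cn <- names(coef(fit))
  wald <- list()
  if (nlevels(d$sex) > 1) wald$sex <- svy_wald(fit, "^sexfemale$")
  if (nlevels(d$race) > 1)
    wald$race <- svy_wald(fit, cn[grepl("^race", cn) & !grepl(":", cn)])
  if ("sex" %in% interactions)
    wald$sex_age <- svy_wald(fit, "^age[0-9]+:sexfemale$")
  if ("race" %in% interactions)
    wald$race_age <- svy_wald(fit, "^age[0-9]+:race")
  grid <- expand.grid(age_years = 6:85, sex = levels(d$sex),
                      race = levels(d$race), stringsAsFactors = FALSE)
  gd <- cbind(grid, age_basis(grid$age_years))
  gd$sex <- factor(gd$sex, levels = levels(d$sex))
  gd$race <- factor(gd$race, levels = levels(d$race))
  grid$fitted <- predict(fit, gd)
  structure(list(outcome = outcome, fit = fit, wald = wald, curves = grid),
            class = "sleep_trend")
}

#' @export
print.sleep_trend <- function(x, ...) {
  cat(sprintf("Age/sex/race trend model for %s\n", x$outcome))
  print(summary(x$fit))
  for (nm in names(x$wald)) {
    wt <- x$wald[[nm]]
    cat(sprintf("  Wald [%s]: F(%d, %d) = %.3f, p = %.4g\n", nm, wt$df1,
                wt$df2, wt$F, wt$p))
  }
  invisible(x)
}

#' Survey-weighted ordinal regression on sleep-efficiency quartiles
#'
#' Sleep efficiency is left-skewed; the linear trend model is confirmed on
#' efficiency quartiles (cut at the weighted quartiles of the analysis
#' sample) with survey-weighted proportional-odds regression.
#'
#' @inheritParams sleep_trend
#' @param efficiency efficiency column name
#' @return list: \code{fit} (a \code{\link{svy_polr}}), \code{cutpoints}
#'   (the weighted quartile cut-points)
#' @export
efficiency_quartile_ordinal <- function(data, design,
                                        efficiency = "mean_efficiency",
                                        interactions = character(0)) {
  e <- data[[efficiency]]
  cuts <- svy_quantile(e, design$weights, c(0.25, 0.5, 0.75))
  q <- cut(e, breaks = c(-Inf, unique(cuts), Inf), labels = FALSE)
  d <- cbind(data, age_basis(data$age_years))
  d$eff_quartile <- factor(q, ordered = TRUE)
  d$sex <- droplevels(factor(d$sex, levels = .SEX_LEVELS))
  d$race <- droplevels(factor(d$race, levels = .RACE_LEVELS))
  rhs <- c(paste0("age", 1:4), if (nlevels(d$sex) > 1) "sex",
           if (nlevels(d$race) > 1) "race")
  fit <- svy_polr(stats::reformulate(rhs, response = "eff_quartile"), d,
                  design)
  list(fit = fit, cutpoints = cuts)
}
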