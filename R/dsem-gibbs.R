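# Gibbs sampler internals for the two-level AR(1) DSEM.
#
# Within level (per person i, trial t):
#   y_it = mu_i + x_it,   x_it = phi_i x_i,t-1 + zeta_it,  zeta ~ N(0, s2z)
# Between level: (mu_i, phi_i, iSD_i) ~ MVN(gamma, Sigma), with iSD_i an
# observed variable; optional linear regressions of error counts on the
# triple. Missing trials (correct NoGo, incorrect, trimmed) are latent and
# imputed each sweep, so lag pairs never skip across the time axis.
#
# Conditionals used:
#  - missing x_t: N(phi(x_{t-1}+x_{t+1})/(1+phi^2), s2z/(1+phi^2)) in the
#    interior; N(phi x_2, s2z) at t=1 (stationary prior times forward
#    likelihood); N(phi x_{T-1}, s2z) at t=T.
#  - mu_i | .: normal, combining the AR likelihood (conditional on the
#    first trial), the level-2 conditional prior given (phi_i, iSD_i), and
#    any error-regression terms where mu_i is a predictor.
#  - phi_i | .: normal, same structure; unconstrained (normal random
#    effect), divergent persons show up in the diagnostics.
#  - gamma | Sigma: normal (vague N(0, 1e10) prior); Sigma: inverse-Wishart
#    (d+2, data-scale diagonal); s2z: inverse-gamma(0.001, 0.001);
#    level-2 regression coefficients and residual variances: weakly
#    informative data-scaled priors (see below).

.PRIOR_LOC_PREC <- 1e-10   # N(0, 1e10) location priors (fixed effects)
.PRIOR_IG_A <- 0.001
.PRIOR_IG_B <- 0.001
# Level-2 regressions of observed counts on latent random effects are
# subject to a known degeneracy under fully vague priors: a weakly
# determined latent (phi_i has a per-person likelihood SD of ~0.1 from 116
# trials) can be dragged to fit the outcome exactly, sending the residual
# variance to zero and the coefficients to infinity along a posterior
# ridge. A second, milder symptom of the same geometry: because a latent
# predictor is weakly determined, the coefficient's posterior can stay
# prior-wide, and its square then acts as spurious precision in every
# person's latent conditional, compressing the random-effect variance and
# narrowing the fixed-effect intervals. The package therefore uses weakly
# informative, data-scaled priors there: coefficients
# N(0, (scale * sd(y)/sd(x))^2) with scale 1.5 on the standardized-weight
# scale (about twice the largest standardized weight the error
# regressions plausibly produce), and residual variances IG(2, var(y))
# (prior mean = the outcome variance). Intercepts keep the vague
# N(0, 1e10) prior.
.PRIOR_COEF_SCALE <- 1.5
.PRIOR_RESID_SHAPE <- 2

# --- small helpers ---------------------------------------------------------

.rmvnorm_prec <- function(b, prec) {
  # draw from N(prec^{-1} b, prec^{-1}) given natural parameters
  R <- chol(prec)
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  m + backsolve(R, stats::rnorm(length(b)))
}

.rinvwishart <- function(df, S) {
  # inverse-Wishart(df, scale S): if W ~ Wishart(df, S^{-1}) then W^{-1}
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}

.riginv <- function(a, b) 1 / stats::rgamma(1, shape = a, rate = b)

# lag-1 autocorrelation over observed adjacent pairs; 0 when undefined
.init_phi <- function(y) {
  x <- y - mean(y, na.rm = TRUE)
  x1 <- x[-length(x)]; x2 <- x[-1]
  ok <- !is.na(x1) & !is.na(x2)
  if (sum(ok) < 3) return(0)
  den <- sum(x1[ok]^2)
  if (den <= 0) return(0)
  max(min(sum(x1[ok] * x2[ok]) / den, 0.95), -0.95)
}

# per-block AR state used by the samplers
.ar_state <- function(Y) {
  T_ <- nrow(Y); N <- ncol(Y)
  miss <- is.na(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  phi <- apply(Y, 2, .init_phi)
  Yimp <- Y
  for (j in seq_len(N)) Yimp[miss[, j], j] <- mu[j]
  miss_at <- lapply(seq_len(T_), function(t) which(miss[t, ]))
  list(T = T_, N = N, Yimp = Yimp, miss_at = miss_at,
       has_miss = which(vapply(miss_at, length, 1L) > 0L),
       mu = mu, phi = phi)
}

# one imputation sweep for a block (updates st$Yimp in place, returns st)
.impute_block <- function(st, s2z) {
  T_ <- st$T
  mu <- st$mu; phi <- st$phi
  for (t in st$has_miss) {
    idx <- st$miss_at[[t]]
    p <- phi[idx]
    if (t == 1L) {
      x2 <- st$Yimp[2L, idx] - mu[idx]
      m <- p * x2; v <- rep(s2z, length(idx))
    } else if (t == T_) {
      x1 <- st$Yimp[T_ - 1L, idx] - mu[idx]
      m <- p * x1; v <- rep(s2z, length(idx))
    } else {
      x1 <- st$Yimp[t - 1L, idx] - mu[idx]
      x2 <- st$Yimp[t + 1L, idx] - mu[idx]
      m <- p * (x1 + x2) / (1 + p^2); v <- s2z / (1 + p^2)
    }
    st$Yimp[t, idx] <- mu[idx] + m + stats::rnorm(length(idx)) * sqrt(v)
  }
  st
}

# AR-likelihood natural parameters for mu (given phi) over the full
# augmented series, conditioning on the first trial
.ar_mu_lik <- function(st, s2z) {
  T_ <- st$T
  cstot <- colSums(st$Yimp)
  cs2 <- cstot - st$Yimp[1L, ]          # sum_{t=2..T} y_t
  cs1 <- cstot - st$Yimp[T_, ]          # sum_{t=1..T-1} y_t
  csum <- cs2 - st$phi * cs1
  list(prec = (T_ - 1) * (1 - st$phi)^2 / s2z,
       b = (1 - st$phi) * csum / s2z)
}

# AR-likelihood natural parameters for phi (given mu)
.ar_phi_lik <- function(st, s2z) {
  X <- sweep(st$Yimp, 2L, st$mu)
  T_ <- st$T
  x1 <- X[-T_, , drop = FALSE]; x2 <- X[-1L, , drop = FALSE]
  list(prec = colSums(x1^2) / s2z, b = colSums(x1 * x2) / s2z)
}

.ar_ssr <- function(st) {
  X <- sweep(st$Yimp, 2L, st$mu)
  T_ <- st$T
  resid <- X[-1L, , drop = FALSE] -
    sweep(X[-T_, , drop = FALSE], 2L, st$phi, `*`)
  sum(resid^2)
}

# conditional prior of component j of an MVN triple given the other two
.mvn_cond <- function(Sinv, gamma, V, j) {
  others <- setdiff(1:3, j)
  b <- Sinv[j, j] * gamma[j]
  for (k in others) b <- b - Sinv[j, k] * (V[, k] - gamma[k])
  list(prec = Sinv[j, j], b = b)
}

# scalar-regression contribution for a latent predictor with coefficient a:
# y = rest + a * theta + e, e ~ N(0, s2)
.reg_pred_contrib <- function(a, y, rest, s2) {
  list(prec = a^2 / s2, b = a * (y - rest) / s2)
}

# coefficient prior precisions for a regression with design scales sx and
# outcome scale sy; the intercept (first entry) stays vague
.reg_prior_prec <- function(sx, sy) {
  sy <- max(sy, 1e-8)
  c(.PRIOR_LOC_PREC,
    pmax(sx, 1e-8)^2 / (.PRIOR_COEF_SCALE^2 * sy^2))
}

# draw coefficients and residual variance of y ~ X with weakly informative
# data-scaled priors (see header comment); prior_prec has length ncol(X)
.draw_regression <- function(X, y, s2, prior_prec, resid_rate) {
  prec <- crossprod(X) / s2 + diag(prior_prec, ncol(X))
  beta <- .rmvnorm_prec(crossprod(X, y) / s2, prec)
  resid <- y - X %*% beta
  s2_new <- .riginv(.PRIOR_RESID_SHAPE + length(y) / 2,
                    resid_rate + sum(resid^2) / 2)
  fitted <- X %*% beta
  list(beta = as.numeric(beta), s2 = s2_new,
       r2 = stats::var(as.numeric(fitted)) / stats::var(y))
}

# draw (gamma, Sigma) of the level-2 MVN given the person triples V (N x 3).
# S0 is the inverse-Wishart prior scale (diagonal of data-scale variances,
# worth about one pseudo-observation; guards the near-singular directions
# the latent wiggling degeneracy exploits).
.draw_mvn_level2 <- function(V, Sigma, S0) {
  N <- nrow(V)
  Sinv <- chol2inv(chol(Sigma))
  prec <- N * Sinv + diag(.PRIOR_LOC_PREC, 3)
  gamma <- .rmvnorm_prec(Sinv %*% colSums(V), prec)
  D <- sweep(V, 2L, gamma)
  Sigma_new <- .rinvwishart(5 + N, S0 + crossprod(D))
  list(gamma = as.numeric(gamma), Sigma = Sigma_new, Sinv = Sinv)
}

# --- single-block sampler --------------------------------------------------

.gibbs_single_block <- function(model, config, chain_seed, with_errors) {
  set.seed(chain_seed)
  blk <- model$blocks[[1]]
  st <- .ar_state(blk$Y)
  N <- st$N; T_ <- st$T
  isd <- blk$isd
  CE <- if (with_errors) model$ce[[1]] else NULL

  # method-of-moments style initials
  s2z <- max(mean(apply(blk$Y, 2, stats::var, na.rm = TRUE)) *
               (1 - mean(st$phi)^2), 1e-4)
  V <- cbind(st$mu, st$phi, isd)
  gamma <- colMeans(V)
  Sigma <- stats::cov(V) + diag(1e-6, 3)
  S0 <- diag(pmax(diag(Sigma), 1e-8))   # IW prior scale: data-scale diagonal
  beta <- rep(0, 4); s2e <- 1; r2 <- 0
  prior_prec_ce <- NULL; resid_rate_ce <- NULL
  if (with_errors) {
    X0 <- cbind(1, V)
    beta <- tryCatch(as.numeric(stats::lm.fit(X0, CE)$coefficients),
                     error = function(e) rep(0, 4))
    beta[is.na(beta)] <- 0
    s2e <- max(stats::var(CE - X0 %*% beta), 1e-4)
    prior_prec_ce <- .reg_prior_prec(apply(V, 2, stats::sd), stats::sd(CE))
    resid_rate_ce <- stats::var(CE)
  }

  par_names <- c("gamma_mu", "gamma_phi", "gamma_isd",
                 "var_mu", "var_phi", "var_isd",
                 "cov_mu_phi", "cov_mu_isd", "cov_phi_isd",
                 "sigma2_zeta", "sd_mu", "sd_phi")
  if (with_errors) {
    par_names <- c(par_names, "beta_0", "beta_mu", "beta_phi", "beta_isd",
                   "sigma2_e", "r2_ce")
  }
  keep <- matrix(NA_real_, config$retained, length(par_names),
                 dimnames = list(NULL, par_names))
  burn_end <- floor(config$n_iterations * config$burn_in)
  k <- 0L

  for (iter in seq_len(config$n_iterations)) {
    st <- .impute_block(st, s2z)
    Sinv <- chol2inv(chol(Sigma))

    # mu_i
    V <- cbind(st$mu, st$phi, isd)
    pr <- .mvn_cond(Sinv, gamma, V, 1L)
    lik <- .ar_mu_lik(st, s2z)
    prec <- pr$prec + lik$prec
    b <- pr$b + lik$b
    if (with_errors) {
      rest <- beta[1] + beta[3] * st$phi + beta[4] * isd
      ec <- .reg_pred_contrib(beta[2], CE, rest, s2e)
      prec <- prec + ec$prec; b <- b + ec$b
    }
    st$mu <- stats::rnorm(N, b / prec, sqrt(1 / prec))

    # phi_i
    V <- cbind(st$mu, st$phi, isd)
    pr <- .mvn_cond(Sinv, gamma, V, 2L)
    lik <- .ar_phi_lik(st, s2z)
    prec <- pr$prec + lik$prec
    b <- pr$b + lik$b
    if (with_errors) {
      rest <- beta[1] + beta[2] * st$mu + beta[4] * isd
      ec <- .reg_pred_contrib(beta[3], CE, rest, s2e)
      prec <- prec + ec$prec; b <- b + ec$b
    }
    st$phi <- stats::rnorm(N, b / prec, sqrt(1 / prec))

    # innovation variance
    s2z <- .riginv(.PRIOR_IG_A + N * (T_ - 1) / 2,
                   .PRIOR_IG_B + .ar_ssr(st) / 2)

    # level-2 joint distribution
    V <- cbind(st$mu, st$phi, isd)
    l2 <- .draw_mvn_level2(V, Sigma, S0)
    gamma <- l2$gamma; Sigma <- l2$Sigma

    # error regression
    if (with_errors) {
      reg <- .draw_regression(cbind(1, V), CE, s2e, prior_prec_ce,
                              resid_rate_ce)
      beta <- reg$beta; s2e <- reg$s2; r2 <- reg$r2
    }

    if (iter > burn_end && (iter - burn_end) %% config$thin == 0L &&
        k < config$retained) {
      k <- k + 1L
      row <- c(gamma, Sigma[1, 1], Sigma[2, 2], Sigma[3, 3],
               Sigma[1, 2], Sigma[1, 3], Sigma[2, 3],
               s2z, stats::sd(st$mu), stats::sd(st$phi))
      if (with_errors) row <- c(row, beta, s2e, r2)
      keep[k, ] <- row
    }
  }
  keep[seq_len(k), , drop = FALSE]
}

# --- two-block sampler -----------------------------------------------------

.gibbs_two_block <- function(model, config, chain_seed, with_covariate) {
  set.seed(chain_seed)
  b1 <- model$blocks[[1]]; b2 <- model$blocks[[2]]
  id1 <- b1$id; id2 <- b2$id
  st1 <- .ar_state(b1$Y); st2 <- .ar_state(b2$Y)
  N <- st1$N
  isd1 <- b1$isd; isd2 <- b2$isd
  CE1 <- model$ce[[1]]; CE2 <- model$ce[[2]]; PO <- model$po
  LNS <- model$covariate

  s2z1 <- max(mean(apply(b1$Y, 2, stats::var, na.rm = TRUE)) *
                (1 - mean(st1$phi)^2), 1e-4)
  s2z2 <- max(mean(apply(b2$Y, 2, stats::var, na.rm = TRUE)) *
                (1 - mean(st2$phi)^2), 1e-4)
  V1 <- cbind(st1$mu, st1$phi, isd1)
  V2 <- cbind(st2$mu, st2$phi, isd2)
  gamma1 <- colMeans(V1)
  Sigma1 <- stats::cov(V1) + diag(1e-6, 3)
  S0_1 <- diag(pmax(diag(Sigma1), 1e-8))
  X12 <- cbind(1, V1)
  B <- tryCatch(qr.coef(qr(X12), V2), error = function(e) matrix(0, 4, 3))
  B[is.na(B)] <- 0
  Sigma2r <- stats::cov(V2 - X12 %*% B) + diag(1e-6, 3)
  S0_2 <- diag(pmax(diag(Sigma2r), 1e-8))

  # data-scale prior precisions (see header comment)
  sV1 <- apply(V1, 2, stats::sd); sV2 <- apply(V2, 2, stats::sd)
  sCE1 <- stats::sd(CE1); sCE2 <- stats::sd(CE2); sPO <- stats::sd(PO)
  sLNS <- if (with_covariate) stats::sd(LNS) else numeric()
  prior_prec_B <- vapply(1:3, function(j) {
    .reg_prior_prec(sV1, sV2[j])
  }, numeric(4))                         # 4 x 3, column-major like vec(B)
  pp_ce1 <- .reg_prior_prec(c(sV1, sLNS), sCE1)
  pp_ce2 <- .reg_prior_prec(c(sV2, sCE1, sLNS), sCE2)
  pp_po <- .reg_prior_prec(c(sV2, sCE2, sLNS), sPO)
  rr_ce1 <- stats::var(CE1); rr_ce2 <- stats::var(CE2); rr_po <- stats::var(PO)

  mk_X <- function(base) if (with_covariate) cbind(base, LNS) else base
  Xce1 <- mk_X(cbind(1, V1))
  a1 <- as.numeric(stats::lm.fit(Xce1, CE1)$coefficients); a1[is.na(a1)] <- 0
  s2e1 <- max(stats::var(CE1 - Xce1 %*% a1), 1e-4)
  Xce2 <- mk_X(cbind(1, V2, CE1))
  a2 <- as.numeric(stats::lm.fit(Xce2, CE2)$coefficients); a2[is.na(a2)] <- 0
  s2e2 <- max(stats::var(CE2 - Xce2 %*% a2), 1e-4)
  Xpo <- mk_X(cbind(1, V2, CE2))
  a3 <- as.numeric(stats::lm.fit(Xpo, PO)$coefficients); a3[is.na(a3)] <- 0
  s2e3 <- max(stats::var(PO - Xpo %*% a3), 1e-4)
  r2_1 <- r2_2 <- r2_3 <- 0

  sfx1 <- paste0(".", id1); sfx2 <- paste0(".", id2)
  cov_names <- if (with_covariate) "_on_lns" else character()
  par_names <- c(
    paste0(c("gamma_mu", "gamma_phi", "gamma_isd",
             "var_mu", "var_phi", "var_isd",
             "cov_mu_phi", "cov_mu_isd", "cov_phi_isd", "sigma2_zeta"), sfx1),
    paste0("sigma2_zeta", sfx2),
    paste0(rep(paste0(c("mu", "phi", "isd"), sfx2), each = 4), "_on_",
           rep(c("intercept", paste0(c("mu", "phi", "isd"), sfx1)), 3)),
    paste0(c("rvar_mu", "rvar_phi", "rvar_isd",
             "rcov_mu_phi", "rcov_mu_isd", "rcov_phi_isd"), sfx2),
    paste0("ce", sfx1, c("_intercept", "_on_mu", "_on_phi", "_on_isd",
                         cov_names)),
    paste0("sigma2_e_ce", sfx1), paste0("r2_ce", sfx1),
    paste0("ce", sfx2, c("_intercept", "_on_mu", "_on_phi", "_on_isd",
                         paste0("_on_ce", sfx1), cov_names)),
    paste0("sigma2_e_ce", sfx2), paste0("r2_ce", sfx2),
    paste0("po", sfx2, c("_intercept", "_on_mu", "_on_phi", "_on_isd",
                         paste0("_on_ce", sfx2), cov_names)),
    paste0("sigma2_e_po", sfx2), paste0("r2_po", sfx2),
    paste0("r2_mu", sfx2), paste0("r2_phi", sfx2), paste0("r2_isd", sfx2),
    paste0("sd_mu", sfx1), paste0("sd_phi", sfx1),
    paste0("sd_mu", sfx2), paste0("sd_phi", sfx2))
  keep <- matrix(NA_real_, config$retained, length(par_names),
                 dimnames = list(NULL, par_names))
  burn_end <- floor(config$n_iterations * config$burn_in)
  k <- 0L
  nc <- if (with_covariate) 1L else 0L   # extra covariate column count

  for (iter in seq_len(config$n_iterations)) {
    st1 <- .impute_block(st1, s2z1)
    st2 <- .impute_block(st2, s2z2)
    Sinv1 <- chol2inv(chol(Sigma1))
    K2 <- chol2inv(chol(Sigma2r))

    # ---- earlier-block latents -------------------------------------------
    # mu (block 1)
    V1 <- cbind(st1$mu, st1$phi, isd1)
    V2 <- cbind(st2$mu, st2$phi, isd2)
    X12 <- cbind(1, V1)
    pr <- .mvn_cond(Sinv1, gamma1, V1, 1L)
    lik <- .ar_mu_lik(st1, s2z1)
    g <- B[2L, ]
    R0 <- V2 - X12 %*% B + outer(st1$mu, g)
    prec <- pr$prec + lik$prec + drop(g %*% K2 %*% g)
    b <- pr$b + lik$b + as.numeric(R0 %*% (K2 %*% g))
    rest <- Xce1[, -2L, drop = FALSE] %*% a1[-2L]
    ec <- .reg_pred_contrib(a1[2L], CE1, as.numeric(rest), s2e1)
    prec <- prec + ec$prec; b <- b + ec$b
    st1$mu <- stats::rnorm(N, b / prec, sqrt(1 / prec))
    V1[, 1L] <- st1$mu
    Xce1 <- mk_X(cbind(1, V1))

    # phi (block 1)
    X12 <- cbind(1, V1)
    pr <- .mvn_cond(Sinv1, gamma1, V1, 2L)
    lik <- .ar_phi_lik(st1, s2z1)
    g <- B[3L, ]
    R0 <- V2 - X12 %*% B + outer(st1$phi, g)
    prec <- pr$prec + lik$prec + drop(g %*% K2 %*% g)
    b <- pr$b + lik$b + as.numeric(R0 %*% (K2 %*% g))
    rest <- Xce1[, -3L, drop = FALSE] %*% a1[-3L]
    ec <- .reg_pred_contrib(a1[3L], CE1, as.numeric(rest), s2e1)
    prec <- prec + ec$prec; b <- b + ec$b
    st1$phi <- stats::rnorm(N, b / prec, sqrt(1 / prec))
    V1[, 2L] <- st1$phi
    Xce1 <- mk_X(cbind(1, V1))
    X12 <- cbind(1, V1)

    # ---- later-block latents ---------------------------------------------
    M <- X12 %*% B                      # conditional means of the V2 triple
    # mu (block 2)
    V2 <- cbind(st2$mu, st2$phi, isd2)
    prec <- K2[1L, 1L] + 0
    b <- K2[1L, 1L] * M[, 1L] - K2[1L, 2L] * (V2[, 2L] - M[, 2L]) -
      K2[1L, 3L] * (V2[, 3L] - M[, 3L])
    lik <- .ar_mu_lik(st2, s2z2)
    prec <- prec + lik$prec; b <- b + lik$b
    Xce2 <- mk_X(cbind(1, V2, CE1))
    rest <- Xce2[, -2L, drop = FALSE] %*% a2[-2L]
    ec <- .reg_pred_contrib(a2[2L], CE2, as.numeric(rest), s2e2)
    prec <- prec + ec$prec; b <- b + ec$b
    Xpo <- mk_X(cbind(1, V2, CE2))
    rest <- Xpo[, -2L, drop = FALSE] %*% a3[-2L]
    ec <- .reg_pred_contrib(a3[2L], PO, as.numeric(rest), s2e3)
    prec <- prec + ec$prec; b <- b + ec$b
    st2$mu <- stats::rnorm(N, b / prec, sqrt(1 / prec))
    V2[, 1L] <- st2$mu

    # phi (block 2)
    prec <- K2[2L, 2L] + 0
    b <- K2[2L, 2L] * M[, 2L] - K2[2L, 1L] * (V2[, 1L] - M[, 1L]) -
      K2[2L, 3L] * (V2[, 3L] - M[, 3L])
    lik <- .ar_phi_lik(st2, s2z2)
    prec <- prec + lik$prec; b <- b + lik$b
    Xce2 <- mk_X(cbind(1, V2, CE1))
    rest <- Xce2[, -3L, drop = FALSE] %*% a2[-3L]
    ec <- .reg_pred_contrib(a2[3L], CE2, as.numeric(rest), s2e2)
    prec <- prec + ec$prec; b <- b + ec$b
    Xpo <- mk_X(cbind(1, V2, CE2))
    rest <- Xpo[, -3L, drop = FALSE] %*% a3[-3L]
    ec <- .reg_pred_contrib(a3[3L], PO, as.numeric(rest), s2e3)
    prec <- prec + ec$prec; b <- b + ec$b
    st2$phi <- stats::rnorm(N, b / prec, sqrt(1 / prec))
    V2[, 2L] <- st2$phi

    # ---- variances and level-2 structure ---------------------------------
    s2z1 <- .riginv(.PRIOR_IG_A + N * (st1$T - 1) / 2,
                    .PRIOR_IG_B + .ar_ssr(st1) / 2)
    s2z2 <- .riginv(.PRIOR_IG_A + N * (st2$T - 1) / 2,
                    .PRIOR_IG_B + .ar_ssr(st2) / 2)

    l2 <- .draw_mvn_level2(V1, Sigma1, S0_1)
    gamma1 <- l2$gamma; Sigma1 <- l2$Sigma

    # multivariate regression V2 ~ (1, V1): vec(B) draw given Sigma2r,
    # with elementwise data-scaled coefficient priors
    X12 <- cbind(1, V1)
    K2 <- chol2inv(chol(Sigma2r))
    precB <- K2 %x% crossprod(X12) + diag(as.numeric(prior_prec_B), 12)
    bB <- as.numeric(crossprod(X12, V2) %*% K2)
    B <- matrix(.rmvnorm_prec(bB, precB), 4, 3)
    E <- V2 - X12 %*% B
    Sigma2r <- .rinvwishart(5 + N, S0_2 + crossprod(E))

    # error regressions
    Xce1 <- mk_X(cbind(1, V1))
    reg <- .draw_regression(Xce1, CE1, s2e1, pp_ce1, rr_ce1)
    a1 <- reg$beta; s2e1 <- reg$s2; r2_1 <- reg$r2
    Xce2 <- mk_X(cbind(1, V2, CE1))
    reg <- .draw_regression(Xce2, CE2, s2e2, pp_ce2, rr_ce2)
    a2 <- reg$beta; s2e2 <- reg$s2; r2_2 <- reg$r2
    Xpo <- mk_X(cbind(1, V2, CE2))
    reg <- .draw_regression(Xpo, PO, s2e3, pp_po, rr_po)
    a3 <- reg$beta; s2e3 <- reg$s2; r2_3 <- reg$r2

    if (iter > burn_end && (iter - burn_end) %% config$thin == 0L &&
        k < config$retained) {
      k <- k + 1L
      M <- X12 %*% B
      r2_trip <- vapply(1:3, function(j) {
        stats::var(M[, j]) / stats::var(V2[, j])
      }, 1)
      keep[k, ] <- c(
        gamma1, Sigma1[1, 1], Sigma1[2, 2], Sigma1[3, 3],
        Sigma1[1, 2], Sigma1[1, 3], Sigma1[2, 3], s2z1,
        s2z2,
        as.numeric(B),                       # column-major: mu2|., phi2|., isd2|.
        Sigma2r[1, 1], Sigma2r[2, 2], Sigma2r[3, 3],
        Sigma2r[1, 2], Sigma2r[1, 3], Sigma2r[2, 3],
        a1, s2e1, r2_1,
        a2, s2e2, r2_2,
        a3, s2e3, r2_3,
        r2_trip,
        stats::sd(st1$mu), stats::sd(st1$phi),
        stats::sd(st2$mu), stats::sd(st2$phi))
    }
  }
  keep[seq_len(k), , drop = FALSE]
}

# --- public fitting interface ----------------------------------------------

#' Fit a DSEM by Gibbs sampling
#'
#' Runs `config$n_chains` independent chains of the blocked Gibbs sampler
#' with missing-data augmentation. Each sweep imputes the latent
#' within-person deviations at missing trials, draws every person's mean
#' and autoregression from their normal full conditionals, and updates the
#' innovation variance, the level-2 mean vector and covariance matrix, and
#' any level-2 regression coefficients and residual variances from their
#' conjugate conditionals.
#'
#' @param model A [build_model()] result.
#' @param config A [sampler_config()].
#' @return Object of class `dsem_fit`: `draws` (list of retained-draw
#'   matrices, one per chain), `model`, `config`, `scales` (observed SDs
#'   used for standardization).
#' @seealso [summary.dsem_fit()], [compute_psr()], [standardize()]
#' @export
dsem_fit <- function(model, config = sampler_config()) {
  stopifnot(inherits(model, "dsem_model"), inherits(config, "sampler_config"))
  variant <- model$spec$variant
  draws <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    seed_ch <- config$seed + ch - 1L
    draws[[ch]] <- switch(
      variant,
      single_block = .gibbs_single_block(model, config, seed_ch, FALSE),
      single_block_with_errors =
        .gibbs_single_block(model, config, seed_ch, TRUE),
      two_block = .gibbs_two_block(model, config, seed_ch, FALSE),
      two_block_with_covariate =
        .gibbs_two_block(model, config, seed_ch, TRUE))
  }
  scales <- list()
  for (b in model$blocks) {
    scales[[paste0("sd_isd.", b$id)]] <- stats::sd(b$isd)
  }
  if (!is.null(model$ce)) {
    for (nm in names(model$ce)) {
      scales[[paste0("sd_ce.", nm)]] <- stats::sd(model$ce[[nm]])
    }
  }
  if (!is.null(model$po)) {
    scales[[paste0("sd_po.", model$blocks[[2]]$id)]] <- stats::sd(model$po)
  }
  if (!is.null(model$covariate)) {
    scales$sd_lns <- stats::sd(model$covariate)
  }
  structure(list(draws = draws, model = model, config = config,
                 scales = scales),
            class = "dsem_fit")
}

#' Single-series AR(1) Gibbs fit with flat priors
#'
#' Reference sampler for one complete (or gappy) series without the
#' hierarchical level: flat priors on the mean and autoregression,
#' inverse-gamma(0.001, 0.001) on the innovation variance. Used to check
#' the full sampler against conditional least squares on a single series.
#'
#' @param y Numeric series (NA allowed).
#' @param config A [sampler_config()] (chains run sequentially).
#' @return List with `draws`: matrix of retained draws (columns `mu`,
#'   `phi`, `sigma2_zeta`) pooled over chains, and `per_chain` list.
#' @export
ar1_fit <- function(y, config = sampler_config(n_chains = 1L,
                                               n_iterations = 4000L,
                                               thin = 1L)) {
  Y <- matrix(as.numeric(y), ncol = 1L)
  per_chain <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    st <- .ar_state(Y)
    s2z <- max(stats::var(y, na.rm = TRUE) * (1 - st$phi^2), 1e-6)
    keep <- matrix(NA_real_, config$retained, 3,
                   dimnames = list(NULL, c("mu", "phi", "sigma2_zeta")))
    burn_end <- floor(config$n_iterations * config$burn_in)
    k <- 0L
    for (iter in seq_len(config$n_iterations)) {
      st <- .impute_block(st, s2z)
      lik <- .ar_mu_lik(st, s2z)
      st$mu <- stats::rnorm(1, lik$b / lik$prec, sqrt(1 / lik$prec))
      lik <- .ar_phi_lik(st, s2z)
      st$phi <- stats::rnorm(1, lik$b / lik$prec, sqrt(1 / lik$prec))
      s2z <- .riginv(.PRIOR_IG_A + (st$T - 1) / 2,
                     .PRIOR_IG_B + .ar_ssr(st) / 2)
      if (iter > burn_end && (iter - burn_end) %% config$thin == 0L &&
          k < config$retained) {
        k <- k + 1L
        keep[k, ] <- c(st$mu, st$phi, s2z)
      }
    }
    per_chain[[ch]] <- keep[seq_len(k), , drop = FALSE]
  }
  list(draws = do.call(rbind, per_chain), per_chain = per_chain)
}

#' Conditional least-squares AR(1) estimate
#'
#' Closed-form oracle: OLS of `y_t` on `(1, y_(t-1))` over observed
#' adjacent pairs; `mu = intercept / (1 - phi)`,
#' `sigma2 = RSS / (n - 2)`.
#'
#' @param y Numeric series (NA allowed).
#' @return List `mu`, `phi`, `sigma2`.
#' @export
ar1_cls <- function(y) {
  y1 <- y[-length(y)]; y2 <- y[-1]
  ok <- !is.na(y1) & !is.na(y2)
  X <- cbind(1, y1[ok])
  fit <- stats::lm.fit(X, y2[ok])
  a <- fit$coefficients[1]; phi <- fit$coefficients[2]
  list(mu = unname(a / (1 - phi)), phi = unname(phi),
       sigma2 = sum(fit$residuals^2) / (sum(ok) - 2))
}

#' @export
print.dsem_fit <- function(x, ...) {
  cat(sprintf("DSEM fit (%s): %d chain(s) x %d retained draws, %d persons\n",
              x$model$spec$variant, length(x$draws), nrow(x$draws[[1]]),
              length(x$model$persons)))
  invisible(x)
}
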