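#' Population-level generating parameters
#'
#' Bundles the fixed effects, level-2 (co)variances, and error-regression
#' weights of the generative model. Person-level triples
#' (mu_i, phi_i, iSD_i) -- mean log reaction time, lag-1 autoregression,
#' and fluctuation amplitude (stationary SD of the log-RT process) -- are
#' drawn from a trivariate normal with mean `c(gamma_mu, gamma_phi,
#' gamma_isd)` and covariance `cov_matrix`. Commission-error counts follow
#' a linear model on the triple with Gaussian residual; prospective
#' omissions add the person's commission count as a predictor.
#'
#' @param gamma_mu Mean log-RT fixed effect (log-ms).
#' @param gamma_phi Fixed lag-1 autoregressive effect (unitless).
#' @param gamma_isd Mean fluctuation amplitude (SD of log-ms).
#' @param var_mu,var_phi,var_isd Level-2 variances of the triple.
#' @param cor_mu_phi,cor_mu_isd,cor_phi_isd Level-2 correlations.
#' @param beta0,beta_mu,beta_phi,beta_isd Commission-error regression
#'   intercept and raw-scale weights.
#' @param sigma_e Residual SD of the commission-error regression.
#' @param po_beta0,po_beta_mu,po_beta_phi,po_beta_isd,po_beta_ce
#'   Prospective-omission regression intercept and weights (the last on the
#'   person's commission count in the same block).
#' @param po_sigma_e Residual SD of the omission regression.
#' @param beta_lns Optional weight of the working-memory (LNS) covariate in
#'   the error regressions (default 0).
#' @return An object of class `population_parameters`.
#' @seealso [default_population()] for study-calibrated per-block values.
#' @export
population_parameters <- function(gamma_mu = 6.25, gamma_phi = 0.30,
                                  gamma_isd = 0.15,
                                  var_mu = 0.02, var_phi = 0.01,
                                  var_isd = 0.001,
                                  cor_mu_phi = 0.22, cor_mu_isd = 0.11,
                                  cor_phi_isd = 0.65,
                                  beta0 = 16.14, beta_mu = -3.05,
                                  beta_phi = -6.24, beta_isd = 40.0,
                                  sigma_e = 1.19,
                                  po_beta0 = 0.65, po_beta_mu = 0,
                                  po_beta_phi = 0, po_beta_isd = 0,
                                  po_beta_ce = 0.24, po_sigma_e = 2.03,
                                  beta_lns = 0) {
  if (any(c(var_mu, var_phi, var_isd) < 0)) stop("variances must be >= 0")
  sds <- sqrt(c(var_mu, var_phi, var_isd))
  R <- matrix(c(1, cor_mu_phi, cor_mu_isd,
                cor_mu_phi, 1, cor_phi_isd,
                cor_mu_isd, cor_phi_isd, 1), 3, 3)
  cov_matrix <- R * tcrossprod(sds)
  dimnames(cov_matrix) <- list(c("mu", "phi", "isd"), c("mu", "phi", "isd"))
  ev <- eigen(cov_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("level-2 covariance matrix is not positive semi-definite")
  }
  structure(
    list(gamma_mu = gamma_mu, gamma_phi = gamma_phi, gamma_isd = gamma_isd,
         var_mu = var_mu, var_phi = var_phi, var_isd = var_isd,
         cov_matrix = cov_matrix,
         beta0 = beta0, beta_mu = beta_mu, beta_phi = beta_phi,
         beta_isd = beta_isd, sigma_e = sigma_e,
         po_beta0 = po_beta0, po_beta_mu = po_beta_mu,
         po_beta_phi = po_beta_phi, po_beta_isd = po_beta_isd,
         po_beta_ce = po_beta_ce, po_sigma_e = po_sigma_e,
         beta_lns = beta_lns),
    class = "population_parameters")
}

#' Study-calibrated generating parameters per block
#'
#' Returns the per-block [population_parameters()] used as the package's
#' default "stated world": fixed effects and random-effect (co)variances of
#' the four task blocks (CGNG1, CGNG2, PGNG1, PGNG2) as estimated on the
#' study's single-block models, and commission-error regressions whose raw
#' weights reproduce the reported standardized weights, block error means,
#' SDs, and between-level R-squared. The level-2 variance of iSD is set to
#' 0.001 (the estimates print as 0.00 with upper interval 0.01), keeping
#' the phi--iSD correlation well defined.
#'
#' @param blocks Character vector of block identifiers to return.
#' @return Named list of `population_parameters`, one per block.
#' @export
default_population <- function(blocks = c("CGNG1", "CGNG2", "PGNG1", "PGNG2")) {
  # fixed effects / variances / correlations per block, plus the error-count
  # moments (mean, SD) and standardized CE weights used to back out raw scales
  tab <- list(
    CGNG1 = list(g = c(6.25, 0.30, 0.15), v = c(0.02, 0.01, 0.001),
                 r = c(0.22, 0.11, 0.65),
                 ce = c(mean = 1.18, sd = 1.60), r2 = 0.45,
                 b_std = c(mu = -0.27, phi = -0.39, isd = 0.79)),
    CGNG2 = list(g = c(6.22, 0.27, 0.14), v = c(0.02, 0.02, 0.001),
                 r = c(0.18, 0.05, 0.29),
                 ce = c(mean = 1.03, sd = 1.15), r2 = 0.25,
                 b_std = c(mu = -0.20, phi = 0.08, isd = 0.42)),
    PGNG1 = list(g = c(6.38, 0.23, 0.20), v = c(0.01, 0.02, 0.001),
                 r = c(-0.18, 0.11, 0.33),
                 ce = c(mean = 3.61, sd = 2.49), r2 = 0.16,
                 b_std = c(mu = -0.27, phi = -0.24, isd = 0.31),
                 po = c(mean = 1.53, sd = 2.17), po_r2 = 0.127,
                 po_b_ce_std = 0.28),
    PGNG2 = list(g = c(6.33, 0.14, 0.18), v = c(0.02, 0.01, 0.001),
                 r = c(0.09, 0.14, -0.11),
                 ce = c(mean = 2.48, sd = 1.79), r2 = 0.17,
                 b_std = c(mu = -0.32, phi = 0.16, isd = 0.20),
                 po = c(mean = 0.75, sd = 1.58), po_r2 = 0.127,
                 po_b_ce_std = 0.28))
  out <- lapply(tab[blocks], function(p) {
    sds <- sqrt(p$v)
    b_raw <- p$b_std * p$ce[["sd"]] / sds          # raw = std * SD(y)/SD(x)
    sigma_e <- sqrt(max(1 - p$r2, 0.05)) * p$ce[["sd"]]
    b0 <- p$ce[["mean"]] - sum(b_raw * p$g)
    args <- list(gamma_mu = p$g[1], gamma_phi = p$g[2], gamma_isd = p$g[3],
                 var_mu = p$v[1], var_phi = p$v[2], var_isd = p$v[3],
                 cor_mu_phi = p$r[1], cor_mu_isd = p$r[2],
                 cor_phi_isd = p$r[3],
                 beta0 = b0, beta_mu = b_raw[["mu"]],
                 beta_phi = b_raw[["phi"]], beta_isd = b_raw[["isd"]],
                 sigma_e = sigma_e)
    if (!is.null(p$po)) {
      po_b_ce <- p$po_b_ce_std * p$po[["sd"]] / p$ce[["sd"]]
      args$po_beta_ce <- po_b_ce
      args$po_beta0 <- p$po[["mean"]] - po_b_ce * p$ce[["mean"]]
      args$po_sigma_e <- sqrt(1 - p$po_r2) * p$po[["sd"]]
    }
    do.call(population_parameters, args)
  })
  out
}

#' Draw person-level parameter triples
#'
#' Samples `(mu_i, phi_i, iSD_i)` jointly multivariate normal around the
#' population fixed effects with the level-2 covariance matrix. Draws with
#' `|phi_i| >= 1` are rejected and redrawn (the fitted model assumes
#' person-level stationarity); the number of rejected draws is recorded in
#' the `"n_phi_rejected"` attribute. `iSD_i` is truncated below at
#' `isd_floor` to keep fluctuation amplitudes positive.
#'
#' @param pop A [population_parameters()] object.
#' @param n_persons Number of persons to draw.
#' @param seed Optional integer seed.
#' @param isd_floor Lower truncation for iSD draws (default 1e-3).
#' @return A data.frame with columns `person`, `mu`, `phi`, `isd`;
#'   attribute `n_phi_rejected` counts redrawn persons.
#' @export
sample_person_parameters <- function(pop, n_persons, seed = NULL,
                                     isd_floor = 1e-3) {
  stopifnot(inherits(pop, "population_parameters"), n_persons >= 1)
  if (!is.null(seed)) set.seed(seed)
  gam <- c(pop$gamma_mu, pop$gamma_phi, pop$gamma_isd)
  L <- tryCatch(chol(pop$cov_matrix),
                error = function(e) NULL)
  draw <- function(n) {
    if (is.null(L)) {
      # PSD but singular (e.g. some variance 0): use eigen square root
      e <- eigen(pop$cov_matrix, symmetric = TRUE)
      A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 3)
      matrix(gam, n, 3, byrow = TRUE) + matrix(stats::rnorm(3 * n), n, 3) %*% t(A)
    } else {
      matrix(gam, n, 3, byrow = TRUE) + matrix(stats::rnorm(3 * n), n, 3) %*% L
    }
  }
  V <- draw(n_persons)
  n_rejected <- 0L
  repeat {
    bad <- which(abs(V[, 2]) >= 1)
    if (!length(bad)) break
    n_rejected <- n_rejected + length(bad)
    V[bad, ] <- draw(length(bad))
  }
  out <- data.frame(person = seq_len(n_persons),
                    mu = V[, 1], phi = V[, 2],
                    isd = pmax(V[, 3], isd_floor))
  attr(out, "n_phi_rejected") <- n_rejected
  out
}
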