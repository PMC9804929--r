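#' Fit a hierarchical Bayesian Gaussian mixed model by Gibbs sampling
#'
#' Full conditional updates for: the stacked location effects (fixed effects
#' and every random-effect block jointly, multivariate normal); each block's
#' us/idh (co)variance (inverse-Wishart, or per-column inverse-gamma for
#' idh), with phylogenetic association entering through the block's inverse
#' relatedness matrix; the residual variance (inverse-gamma) or two-trait
#' residual covariance (inverse-Wishart); and missing responses (conditional
#' normal data augmentation). The per-iteration deviance (-2 x Gaussian
#' log-likelihood of the observed responses conditional on location effects)
#' is recorded for DIC. Deterministic given the seed.
#'
#' @param design An "mm_design" from [build_design()].
#' @param priors A [prior_spec()] (defaults filled per model).
#' @param mcmc An [mcmc_config()].
#' @param store_latents Keep posterior draws of random-effect levels
#'   (default TRUE; needed for per-level slope summaries).
#' @return List of class "mm_fit": `samples` (retained draws, named
#'   columns), `deviance` (per-draw), `summary` (mean, 95% HPD, ESS,
#'   Geweke z per parameter), `dic`, `p_d`, `param_map`, `mcmc`, `priors`.
#' @export
gibbs_fit <- function(design, priors = prior_spec(), mcmc = mcmc_config(),
                      store_latents = TRUE) {
  stopifnot(inherits(design, "mm_design"))
  pr <- fill_priors(priors, design)

  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    run_gibbs_chain(design, pr, mcmc, seed = mcmc$seed + ch - 1L)
  })
  samples <- do.call(rbind, lapply(chains, `[[`, "samples"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"))

  keep_cols <- if (store_latents) colnames(samples) else {
    grep("^(fixed|G|resid)\\.", colnames(samples), value = TRUE)
  }

  dbar <- mean(deviance)
  theta_hat <- colMeans(samples[, attr(chains[[1]]$samples, "theta_cols"),
                                drop = FALSE])
  disp_hat <- colMeans(samples[, attr(chains[[1]]$samples, "disp_cols"),
                               drop = FALSE])
  dhat <- deviance_at(design, theta_hat, disp_hat)
  dic <- 2 * dbar - dhat

  fit <- structure(list(
    samples = samples[, keep_cols, drop = FALSE],
    deviance = deviance,
    dic = dic, p_d = dbar - dhat, d_bar = dbar, d_hat = dhat,
    param_map = attr(chains[[1]]$samples, "param_map"),
    theta_cols = attr(chains[[1]]$samples, "theta_cols"),
    disp_cols = attr(chains[[1]]$samples, "disp_cols"),
    n_variance_params = attr(chains[[1]]$samples, "n_variance_params"),
    design = design, mcmc = mcmc, priors = pr
  ), class = "mm_fit")
  fit$summary <- summarize_fit(fit)
  fit
}

# Fill per-model prior defaults: nu = dim + 0.002 and a diagonal scale with
# V_dd = var(y on the rows the d-th design column touches) / 2, so blocks
# whose columns address one trait of a multiresponse stack are scaled by
# that trait's variance, not the pooled variance across traits.
fill_priors <- function(priors, design) {
  vy <- stats::var(design$y[design$observed])
  if (!is.finite(vy) || vy <= 0) vy <- 1
  col_var <- function(Z, q, L, d) {
    rows <- rowSums(abs(Z[, (d - 1L) * L + seq_len(L), drop = FALSE])) > 0
    v <- stats::var(design$y[rows & design$observed])
    if (!is.finite(v) || v <= 0) vy else v
  }
  if (is.null(priors$blocks)) priors$blocks <- vector("list",
                                                      length(design$blocks))
  for (i in seq_along(design$blocks)) {
    q <- design$blocks[[i]]$q
    if (is.null(priors$blocks[[i]])) {
      b <- design$blocks[[i]]
      vd <- vapply(seq_len(q), function(d) col_var(b$Z, q, b$L, d),
                   numeric(1))
      priors$blocks[[i]] <- list(V = diag(vd / 2, q), nu = q + 0.002)
    } else {
      b <- priors$blocks[[i]]
      if (!is.matrix(b$V)) b$V <- diag(b$V, q)
      if (b$nu <= q - 1) stop("block prior nu must exceed dim - 1",
                              call. = FALSE)
      if (min(eigen(b$V, symmetric = TRUE,
                    only.values = TRUE)$values) <= 0) {
        stop("block prior V must be positive definite", call. = FALSE)
      }
      priors$blocks[[i]] <- b
    }
  }
  rdim <- if (design$residual$type == "iid") 1L else 2L
  if (is.null(priors$residual)) {
    if (rdim == 2L) {
      o1 <- design$residual$idx1; o2 <- design$residual$idx2
      v1 <- stats::var(design$y[o1][design$observed[o1]])
      v2 <- stats::var(design$y[o2][design$observed[o2]])
      if (!is.finite(v1) || v1 <= 0) v1 <- vy
      if (!is.finite(v2) || v2 <= 0) v2 <- vy
      priors$residual <- list(V = diag(c(v1, v2) / 2), nu = rdim + 0.002)
    } else {
      priors$residual <- list(V = diag(vy / 2, rdim), nu = rdim + 0.002)
    }
  } else if (!is.null(priors$residual$fixed)) {
    # residual (co)variance treated as known: no residual updates
    fx <- priors$residual$fixed
    if (!is.matrix(fx)) fx <- diag(fx, rdim)
    stopifnot(nrow(fx) == rdim, all(diag(fx) > 0))
    priors$residual <- list(fixed = fx, V = fx, nu = rdim + 0.002)
  } else {
    r <- priors$residual
    if (!is.matrix(r$V)) r$V <- diag(r$V, rdim)
    stopifnot(nrow(r$V) == rdim, r$nu > rdim - 1)
    priors$residual <- r
  }
  priors
}

# inverse-Wishart draw: G ~ IW(scale S, df) via Wishart on the inverse
riwish <- function(df, S) {
  Sinv <- chol2inv(chol(S))
  Sinv <- (Sinv + t(Sinv)) / 2
  W <- stats::rWishart(1, df, Sinv)[, , 1]
  G <- chol2inv(chol(W))
  (G + t(G)) / 2
}

run_gibbs_chain <- function(design, pr, mcmc, seed) {
  set.seed(seed)
  y <- design$y
  obs <- design$observed
  mis <- which(!obs)
  X <- design$X
  blocks <- design$blocks
  res <- design$residual
  n <- design$n
  p_fix <- ncol(X)
  W <- X
  for (b in blocks) W <- cbind(W, b$Z)
  P <- ncol(W)
  block_cols <- list()
  off <- p_fix
  for (i in seq_along(blocks)) {
    qL <- blocks[[i]]$q * blocks[[i]]$L
    block_cols[[i]] <- off + seq_len(qL)
    off <- off + qL
  }

  iid <- res$type == "iid"
  if (iid) {
    CW <- crossprod(W)
  } else {
    W1 <- W[res$idx1, , drop = FALSE]
    W2 <- W[res$idx2, , drop = FALSE]
    C11 <- crossprod(W1); C22 <- crossprod(W2); C12 <- crossprod(W1, W2)
    C12s <- C12 + t(C12)
    obs1 <- obs[res$idx1]; obs2 <- obs[res$idx2]
  }

  prior_prec_fixed <- rep(1 / pr$fixed_var, p_fix)
  prior_mean_fixed <- rep(pr$fixed_mean, length.out = p_fix)

  # initial values
  vy <- stats::var(y[obs]); if (!is.finite(vy) || vy <= 0) vy <- 1
  y[mis] <- mean(y[obs])
  theta <- numeric(P)
  G <- lapply(blocks, function(b) diag(vy / 2, b$q))
  resid_fixed <- !is.null(pr$residual$fixed)
  if (resid_fixed) {
    if (iid) s2 <- pr$residual$fixed[1, 1] else Rm <- pr$residual$fixed
  } else {
    if (iid) s2 <- vy else Rm <- diag(vy / 2, 2)
  }

  n_keep <- (mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thin
  if (n_keep < 1) stop("no retained iterations", call. = FALSE)

  # parameter names
  nm_fixed <- paste0("fixed.", colnames(X))
  nm_lat <- unlist(lapply(blocks, function(b) colnames(b$Z)))
  nm_G <- unlist(lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (b$struct == "us") {
      idx <- which(upper.tri(diag(b$q), diag = TRUE), arr.ind = TRUE)
      paste0("G.", b$name, ".", b$design_names[idx[, 1]], ":",
             b$design_names[idx[, 2]])
    } else {
      paste0("G.", b$name, ".", b$design_names)
    }
  }))
  nm_res <- if (iid) "resid.s2" else {
    tn <- res$trait_names
    paste0("resid.", c(paste0(tn[1], ":", tn[1]), paste0(tn[1], ":", tn[2]),
                       paste0(tn[2], ":", tn[2])))
  }
  nms <- c(nm_fixed, nm_lat, nm_G, nm_res)
  out <- matrix(NA_real_, n_keep, length(nms), dimnames = list(NULL, nms))
  dev_out <- numeric(n_keep)
  kept <- 0L

  for (iter in seq_len(mcmc$n_iterations)) {
    # --- location effects -------------------------------------------------
    if (iid) {
      Cmat <- CW / s2
      bvec <- crossprod(W, y) / s2
    } else {
      Rinv <- chol2inv(chol(Rm))
      y1 <- y[res$idx1]; y2 <- y[res$idx2]
      Cmat <- Rinv[1, 1] * C11 + Rinv[2, 2] * C22 + Rinv[1, 2] * C12s
      bvec <- crossprod(W1, Rinv[1, 1] * y1 + Rinv[1, 2] * y2) +
        crossprod(W2, Rinv[1, 2] * y1 + Rinv[2, 2] * y2)
    }
    dg <- seq_len(p_fix)
    Cmat[cbind(dg, dg)] <- Cmat[cbind(dg, dg)] + prior_prec_fixed
    bvec[dg] <- bvec[dg] + prior_prec_fixed * prior_mean_fixed
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      Ginv <- chol2inv(chol(G[[i]]))
      prec <- if (is.null(b$Ainv)) kronecker(Ginv, diag(b$L)) else
        kronecker(Ginv, b$Ainv)
      cols <- block_cols[[i]]
      Cmat[cols, cols] <- Cmat[cols, cols] + prec
    }
    U <- tryCatch(chol(Cmat), error = function(e) NULL)
    if (is.null(U)) {
      Cmat <- Cmat + diag(1e-8 * max(diag(Cmat)), P)
      U <- tryCatch(chol(Cmat), error = function(e)
        stop("divergent conditional covariance at iteration ", iter,
             "; condition number too large", call. = FALSE))
    }
    m <- backsolve(U, backsolve(U, bvec, transpose = TRUE))
    theta <- drop(m + backsolve(U, stats::rnorm(P)))

    fitted <- drop(W %*% theta)
    e <- y - fitted

    # --- residual (co)variance -------------------------------------------
    if (!resid_fixed) {
      if (iid) {
        s2 <- 1 / stats::rgamma(1, (pr$residual$nu + n) / 2,
                                rate = (pr$residual$V[1, 1] + sum(e^2)) / 2)
      } else {
        E <- cbind(e[res$idx1], e[res$idx2])
        Rm <- riwish(pr$residual$nu + res$n_units,
                     pr$residual$V + crossprod(E))
      }
    }

    # --- block (co)variances ---------------------------------------------
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      Um <- matrix(theta[block_cols[[i]]], b$L, b$q)
      S <- if (is.null(b$Ainv)) crossprod(Um) else t(Um) %*% b$Ainv %*% Um
      if (b$struct == "us") {
        G[[i]] <- riwish(pr$blocks[[i]]$nu + b$L, pr$blocks[[i]]$V + S)
      } else {
        gd <- vapply(seq_len(b$q), function(d) {
          1 / stats::rgamma(1, (pr$blocks[[i]]$nu + b$L) / 2,
                            rate = (pr$blocks[[i]]$V[d, d] + S[d, d]) / 2)
        }, numeric(1))
        G[[i]] <- diag(gd, b$q)
      }
    }

    # --- impute missing responses ----------------------------------------
    if (length(mis)) {
      if (iid) {
        y[mis] <- fitted[mis] + stats::rnorm(length(mis), 0, sqrt(s2))
      } else {
        m1 <- !obs1; m2 <- !obs2
        both <- which(m1 & m2)
        if (length(both)) {
          Lr <- t(chol(Rm))
          Zr <- matrix(stats::rnorm(2 * length(both)), 2)
          draw <- Lr %*% Zr
          y[res$idx1[both]] <- fitted[res$idx1[both]] + draw[1, ]
          y[res$idx2[both]] <- fitted[res$idx2[both]] + draw[2, ]
        }
        only1 <- which(m1 & !m2)   # trait 1 missing, trait 2 observed
        if (length(only1)) {
          cm <- fitted[res$idx1[only1]] + Rm[1, 2] / Rm[2, 2] *
            (y[res$idx2[only1]] - fitted[res$idx2[only1]])
          cv <- Rm[1, 1] - Rm[1, 2]^2 / Rm[2, 2]
          y[res$idx1[only1]] <- cm + stats::rnorm(length(only1), 0,
                                                  sqrt(max(cv, 0)))
        }
        only2 <- which(!m1 & m2)
        if (length(only2)) {
          cm <- fitted[res$idx2[only2]] + Rm[1, 2] / Rm[1, 1] *
            (y[res$idx1[only2]] - fitted[res$idx1[only2]])
          cv <- Rm[2, 2] - Rm[1, 2]^2 / Rm[1, 1]
          y[res$idx2[only2]] <- cm + stats::rnorm(length(only2), 0,
                                                  sqrt(max(cv, 0)))
        }
      }
    }

    # --- record ----------------------------------------------------------
    if (iter > mcmc$burn_in && (iter - mcmc$burn_in) %% mcmc$thin == 0) {
      kept <- kept + 1L
      gvals <- unlist(lapply(seq_along(blocks), function(i) {
        b <- blocks[[i]]
        if (b$struct == "us") G[[i]][upper.tri(G[[i]], diag = TRUE)] else
          diag(G[[i]])
      }))
      rvals <- if (iid) s2 else c(Rm[1, 1], Rm[1, 2], Rm[2, 2])
      out[kept, ] <- c(theta, gvals, rvals)
      disp <- c(gvals, rvals)
      dev_out[kept] <- deviance_obs(design, e, if (iid) s2 else Rm)
    }
  }

  theta_cols <- c(nm_fixed, nm_lat)
  disp_cols <- c(nm_G, nm_res)
  attr(out, "theta_cols") <- theta_cols
  attr(out, "disp_cols") <- disp_cols
  attr(out, "n_variance_params") <- length(disp_cols)
  attr(out, "param_map") <- list(fixed = nm_fixed, latent = nm_lat,
                                 G = nm_G, residual = nm_res)
  list(samples = out, deviance = dev_out[seq_len(kept)])
}

# -2 log-likelihood of the observed responses given location effects
deviance_obs <- function(design, e, disp) {
  obs <- design$observed
  res <- design$residual
  if (res$type == "iid") {
    s2 <- if (is.matrix(disp)) disp[1, 1] else disp[[1]]
    eo <- e[obs]
    return(length(eo) * log(2 * pi * s2) + sum(eo^2) / s2)
  }
  Rm <- disp
  e1 <- e[res$idx1]; e2 <- e[res$idx2]
  o1 <- obs[res$idx1]; o2 <- obs[res$idx2]
  both <- o1 & o2
  d <- 0
  if (any(both)) {
    detR <- Rm[1, 1] * Rm[2, 2] - Rm[1, 2]^2
    Rinv <- chol2inv(chol(Rm))
    q <- Rinv[1, 1] * e1[both]^2 + 2 * Rinv[1, 2] * e1[both] * e2[both] +
      Rinv[2, 2] * e2[both]^2
    d <- d + sum(log((2 * pi)^2 * detR) + q)
  }
  u1 <- o1 & !o2
  if (any(u1)) d <- d + sum(log(2 * pi * Rm[1, 1]) + e1[u1]^2 / Rm[1, 1])
  u2 <- !o1 & o2
  if (any(u2)) d <- d + sum(log(2 * pi * Rm[2, 2]) + e2[u2]^2 / Rm[2, 2])
  d
}

# deviance at point estimates (posterior means), used for DIC's plug-in term
deviance_at <- function(design, theta_hat, disp_hat) {
  W <- design$X
  for (b in design$blocks) W <- cbind(W, b$Z)
  e <- design$y - drop(W %*% theta_hat)
  e[!design$observed] <- 0
  if (design$residual$type == "iid") {
    s2 <- disp_hat[[length(disp_hat)]]
    return(deviance_obs(design, e, s2))
  }
  k <- length(disp_hat)
  Rm <- matrix(c(disp_hat[k - 2], disp_hat[k - 1],
                 disp_hat[k - 1], disp_hat[k]), 2, 2)
  deviance_obs(design, e, Rm)
}

#' Highest posterior density interval
#'
#' Empirical shortest interval containing the requested posterior mass:
#' among all windows of `ceil(mass * n)` consecutive order statistics, the
#' narrowest.
#'
#' @param samples Numeric vector (>= 2 values; < 100 draws warns).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Numeric c(lower, upper).
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("need >= 2 samples", call. = FALSE)
  if (n < 100L) warning("HPD on fewer than 100 samples is unstable",
                        call. = FALSE)
  s <- sort(samples)
  k <- min(n, max(2L, ceiling(mass * n)))
  widths <- s[k:n] - s[1:(n - k + 1L)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k - 1L])
}

#' Deviance information criterion of a fit
#'
#' `DIC = 2 * mean(deviance) - deviance(posterior means)`, the conditional
#' convention: deviance is computed given location effects (random effects
#' plugged in at their draws / posterior means), matching the convention of
#' the common animal-model software family. `p_d = mean(D) - D(hat)`.
#'
#' @param fit An "mm_fit".
#' @return Numeric DIC (the fit also carries `fit$dic`, `fit$p_d`).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  if (length(fit$deviance) < 10L) {
    stop("fewer than 10 retained iterations", call. = FALSE)
  }
  2 * mean(fit$deviance) - fit$d_hat
}

#' Posterior samples of a derived covariance-ratio coefficient
#'
#' For each retained iteration, divides the between-response covariance of a
#' 2x2 covariance block by one response's variance — the regression
#' coefficient of one trait on the other implied by that block. By default
#' the two-trait residual block `us(trait):units` is used.
#'
#' @param fit An "mm_fit" whose samples include the block's 2x2 covariance.
#' @param block `"residual"` or the name of a us() block with 2 design
#'   columns.
#' @param denom 1 or 2: which trait's variance is the denominator
#'   (coefficient of the *other* trait regressed on this one).
#' @return List: `samples` (coefficient draws), `mean`, `hpd` (95%),
#'   `p_negative`.
#' @export
derived_coefficient <- function(fit, block = "residual", denom = 2L) {
  stopifnot(inherits(fit, "mm_fit"))
  if (identical(block, "residual")) {
    nm <- fit$param_map$residual
    if (length(nm) != 3L) {
      stop("residual block is not a 2x2 covariance", call. = FALSE)
    }
    v11 <- fit$samples[, nm[1]]
    v12 <- fit$samples[, nm[2]]
    v22 <- fit$samples[, nm[3]]
  } else {
    nm <- grep(paste0("^G\\.", block, "\\."), fit$param_map$G, value = TRUE)
    if (length(nm) != 3L) {
      stop("block '", block, "' does not carry a 2x2 covariance",
           call. = FALSE)
    }
    v11 <- fit$samples[, nm[1]]
    v12 <- fit$samples[, nm[2]]
    v22 <- fit$samples[, nm[3]]
  }
  den <- if (denom == 2L) v22 else v11
  if (any(den <= 0)) {
    stop("non-positive variance draws encountered", call. = FALSE)
  }
  coefs <- v12 / den
  list(samples = coefs, mean = mean(coefs), hpd = hpd_interval(coefs),
       p_negative = mean(coefs < 0))
}

#' Effective sample size of an MCMC chain
#'
#' `n / tau` with the integrated autocorrelation time `tau` estimated by
#' Geyer's initial positive sequence on the empirical autocorrelations,
#' capped at `n`.
#'
#' @param x Numeric chain.
#' @return ESS (NA for a degenerate, constant chain).
#' @export
ess_chain <- function(x) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  mmax <- (length(rho) - 1L) %/% 2L
  tau <- 0
  for (m in 0:mmax) {
    gam <- rho[2 * m + 1L] + if (2 * m + 2L <= length(rho))
      rho[2 * m + 2L] else 0
    if (gam <= 0) break
    tau <- tau + 2 * gam
  }
  tau <- max(tau - 1, 1)
  min(n / tau, n)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first 10% of a chain with the mean of the last
#' 50%, with window variances estimated from AR-fitted spectral densities
#' at frequency zero.
#'
#' @param x Numeric chain (>= 100 draws recommended).
#' @return z-score (NA for a degenerate chain).
#' @export
geweke_z <- function(x) {
  n <- length(x)
  if (n < 20L || stats::var(x) == 0) return(NA_real_)
  a <- x[1:max(2, floor(0.1 * n))]
  b <- x[(floor(0.5 * n) + 1L):n]
  s0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    fit <- tryCatch(stats::ar(v, aic = TRUE,
                              order.max = min(20, length(v) %/% 4)),
                    error = function(e) NULL)
    if (is.null(fit)) return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  va <- s0(a) / length(a)
  vb <- s0(b) / length(b)
  if (va + vb <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Per-parameter diagnostics of a fit
#'
#' @param fit An "mm_fit" with >= 100 retained draws.
#' @return Data frame: parameter, ess, geweke_z (NA rows flag degenerate
#'   chains).
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  x <- fit$samples
  data.frame(
    parameter = colnames(x),
    ess = vapply(seq_len(ncol(x)), function(j) ess_chain(x[, j]),
                 numeric(1)),
    geweke_z = vapply(seq_len(ncol(x)), function(j) geweke_z(x[, j]),
                      numeric(1)),
    stringsAsFactors = FALSE
  )
}

summarize_fit <- function(fit, mass = 0.95) {
  x <- fit$samples
  hp <- apply(x, 2, function(v) {
    if (stats::var(v) == 0) return(c(v[1], v[1]))
    suppressWarnings(hpd_interval(v, mass))
  })
  data.frame(
    parameter = colnames(x),
    mean = colMeans(x),
    lower = hp[1, ],
    upper = hp[2, ],
    ess = vapply(seq_len(ncol(x)), function(j) ess_chain(x[, j]),
                 numeric(1)),
    geweke_z = vapply(seq_len(ncol(x)), function(j) geweke_z(x[, j]),
                      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Bayesian Gaussian mixed model (Gibbs)\n")
  cat(sprintf("  retained draws: %d   DIC: %.3f   pD: %.2f\n",
              nrow(x$samples), x$dic, x$p_d))
  hdr <- x$summary[x$summary$parameter %in%
                     c(x$param_map$fixed, x$param_map$G,
                       x$param_map$residual), ]
  print(hdr, digits = 4)
  invisible(x)
}
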