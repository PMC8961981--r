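# Posterior density, analytic gradients and the sampler for the two
# hierarchical Bayesian GLMs.
#
# Parameter vector layout (built by make_param_map):
#   b0 | beta (fixed effects) | alpha (one per catalogue DMT, partially
#   pooled) | [s_edss, s_rel per DMT + log_sigma_s if dmt_slopes] |
#   log_sigma_alpha | [gamma_exposure if logit CDP] | [log_r if relapse]
#
# The posterior is set up in two parameterisations. The centred posterior
# (alpha directly) is the one sampled: when the DMT effects are identified it
# is close to elliptical, which the proposal machinery needs. Its joint MODE
# however sits degenerately deep in the hierarchical funnel (sigma -> 0, all
# effects zero), so the mode search runs in the non-centred parameterisation
# (alpha = sigma * alpha_raw, alpha_raw ~ N(0,1)), whose mode is regular; the
# mode and its Laplace covariance are then mapped back to centred
# coordinates to initialise the sampler. DMT effects with user-specified
# informative priors are centred in both versions.
#
# The sampler is preconditioned Hamiltonian Monte Carlo with interleaved
# slice-sampling updates of the pooling-scale coordinates (whose full
# conditionals are likelihood-free). Each chain starts from its own random
# initial point for the mode search, giving the "randomly sampled
# initialization" stream that the empirical coefficient intervals measure.

make_param_map <- function(p_beta, k_dmt, outcome, cdp_link, dmt_slopes,
                           beta_names, dmt_names) {
  idx <- list(b0 = 1L, beta = 1L + seq_len(p_beta))
  at <- 1L + p_beta
  idx$alpha <- at + seq_len(k_dmt); at <- at + k_dmt
  if (dmt_slopes) {
    idx$s_edss <- at + seq_len(k_dmt); at <- at + k_dmt
    idx$s_rel <- at + seq_len(k_dmt); at <- at + k_dmt
    idx$log_sigma_s <- at + 1L; at <- at + 1L
  }
  idx$log_sigma_alpha <- at + 1L; at <- at + 1L
  if (outcome == "cdp" && cdp_link == "logit") {
    idx$gamma_exposure <- at + 1L; at <- at + 1L
  }
  if (outcome == "relapse") {
    idx$log_r <- at + 1L; at <- at + 1L
  }
  idx$n_par <- at
  nm <- c("(Intercept)", beta_names, paste0("dmt_", dmt_names))
  if (dmt_slopes) {
    nm <- c(nm, paste0("slope_edss_", dmt_names), paste0("slope_rel_", dmt_names),
            "log_sigma_slope")
  }
  nm <- c(nm, "log_sigma_dmt")
  if (!is.null(idx$gamma_exposure)) nm <- c(nm, "log_exposure_coef")
  if (!is.null(idx$log_r)) nm <- c(nm, "log_dispersion")
  idx$names <- nm
  idx
}

# Environment-free closure factory: returns list(lp = function(theta),
# gr = function(theta)) for the given data and spec.
make_posterior <- function(design, y, log_expo, outcome, spec, idx,
                           centred = FALSE) {
  X <- design$X
  dmt <- design$dmt
  k <- length(idx$alpha)
  n <- length(y)
  m <- spec$prior_scale_mult
  sb0 <- spec$prior_scale_intercept * m
  sbe <- spec$prior_scale_beta * m
  # lognormal priors on the pooling SDs keep the joint posterior mode finite
  # (a scale prior that is positive at 0 makes the hierarchical funnel's
  # density unbounded at sigma -> 0, which breaks mode-centred inference)
  mal <- log(0.5 * spec$prior_scale_alpha * m)  # meanlog for sigma_alpha
  msl <- log(0.25 * m)                          # meanlog for sigma_slope
  sr <- spec$prior_r_scale * m
  info <- spec$informative_priors         # named list dmt -> c(location, scale)
  info_idx <- match(names(info), colnames_to_dmt(idx))
  pooled <- setdiff(seq_len(k), info_idx)
  z_edss <- X[, "edss"]
  z_rel <- X[, "relapses_last_12m"]
  logit_cdp <- outcome == "cdp" && spec$cdp_link == "logit"

  # effective (centred) DMT terms from the parameter vector
  alpha_eff <- function(th) {
    a <- th[idx$alpha]
    if (!centred) a[pooled] <- a[pooled] * exp(pmin(th[idx$log_sigma_alpha], 5))
    a
  }
  slope_eff <- function(th) {
    if (centred) return(list(se = th[idx$s_edss], sr = th[idx$s_rel]))
    sgs <- exp(pmin(th[idx$log_sigma_s], 5))
    list(se = th[idx$s_edss] * sgs, sr = th[idx$s_rel] * sgs)
  }
  eta_of <- function(th) {
    eta <- th[idx$b0] + drop(X %*% th[idx$beta]) + alpha_eff(th)[dmt]
    if (!is.null(idx$s_edss)) {
      sl <- slope_eff(th)
      eta <- eta + sl$se[dmt] * z_edss + sl$sr[dmt] * z_rel
    }
    if (logit_cdp) eta + th[idx$gamma_exposure] * log_expo else eta + log_expo
  }

  ll_parts <- function(th, eta) {
    if (outcome == "relapse") {
      nb_ll_parts(y, eta, th[idx$log_r])
    } else if (!logit_cdp) {
      cloglog_ll_parts(y, eta)
    } else {
      logit_ll_parts(y, eta)
    }
  }

  log_prior <- function(th) {
    a <- th[idx$alpha]
    lp <- -th[idx$b0]^2 / (2 * sb0^2) - sum(th[idx$beta]^2) / (2 * sbe^2)
    if (centred) {
      sig <- exp(pmin(th[idx$log_sigma_alpha], 5))
      lp <- lp - length(pooled) * log(sig) - sum(a[pooled]^2) / (2 * sig^2)
    } else {
      lp <- lp - sum(a[pooled]^2) / 2            # raw effects ~ N(0, 1)
    }
    if (length(info_idx)) {
      for (j in seq_along(info_idx)) {
        pr <- info[[j]]
        lp <- lp - (a[info_idx[j]] - pr[1])^2 / (2 * pr[2]^2)
      }
    }
    lp <- lp - (th[idx$log_sigma_alpha] - mal)^2 / 2  # lognormal(mal, 1) on sigma
    if (!is.null(idx$s_edss)) {
      if (centred) {
        sgs <- exp(pmin(th[idx$log_sigma_s], 5))
        lp <- lp - 2 * k * log(sgs) -
          (sum(th[idx$s_edss]^2) + sum(th[idx$s_rel]^2)) / (2 * sgs^2) -
          (th[idx$log_sigma_s] - msl)^2 / 2
      } else {
        lp <- lp - (sum(th[idx$s_edss]^2) + sum(th[idx$s_rel]^2)) / 2 -
          (th[idx$log_sigma_s] - msl)^2 / 2
      }
    }
    if (logit_cdp) lp <- lp - th[idx$gamma_exposure]^2 / (2 * sbe^2)
    if (!is.null(idx$log_r)) {
      lp <- lp - (th[idx$log_r] - spec$prior_r_location)^2 / (2 * sr^2)
    }
    lp
  }

  # data-side gradient sums; depend only on the likelihood parts, so they
  # are cached together with them
  lik_grad_parts <- function(lk) {
    u <- lk$u
    if (any(!is.finite(u))) u[!is.finite(u)] <- 0
    list(su = sum(u), xtu = drop(crossprod(X, u)),
         ga = rowsum_by(u, dmt, k),
         ge = if (!is.null(idx$s_edss)) rowsum_by(u * z_edss, dmt, k),
         gr = if (!is.null(idx$s_edss)) rowsum_by(u * z_rel, dmt, k),
         ue = if (logit_cdp) sum(u * log_expo))
  }

  assemble_grad <- function(th, lk, gp) {
    g <- numeric(idx$n_par)
    g[idx$b0] <- gp$su - th[idx$b0] / sb0^2
    g[idx$beta] <- gp$xtu - th[idx$beta] / sbe^2
    sig <- exp(pmin(th[idx$log_sigma_alpha], 5))
    a <- th[idx$alpha]
    ga <- gp$ga                            # d loglik / d alpha_eff
    gal <- ga
    if (centred) {
      gal[pooled] <- ga[pooled] - a[pooled] / sig^2
    } else {
      gal[pooled] <- sig * ga[pooled] - a[pooled]
    }
    if (length(info_idx)) {
      for (j in seq_along(info_idx)) {
        pr <- info[[j]]
        gal[info_idx[j]] <- ga[info_idx[j]] - (a[info_idx[j]] - pr[1]) / pr[2]^2
      }
    }
    g[idx$alpha] <- gal
    g[idx$log_sigma_alpha] <- if (centred) {
      -length(pooled) + sum(a[pooled]^2) / sig^2 - (th[idx$log_sigma_alpha] - mal)
    } else {
      sum(sig * a[pooled] * ga[pooled]) - (th[idx$log_sigma_alpha] - mal)
    }
    if (!is.null(idx$s_edss)) {
      sgs <- exp(pmin(th[idx$log_sigma_s], 5))
      ge <- gp$ge
      gr_ <- gp$gr
      if (centred) {
        g[idx$s_edss] <- ge - th[idx$s_edss] / sgs^2
        g[idx$s_rel] <- gr_ - th[idx$s_rel] / sgs^2
        g[idx$log_sigma_s] <- -2 * k +
          (sum(th[idx$s_edss]^2) + sum(th[idx$s_rel]^2)) / sgs^2 -
          (th[idx$log_sigma_s] - msl)
      } else {
        g[idx$s_edss] <- sgs * ge - th[idx$s_edss]
        g[idx$s_rel] <- sgs * gr_ - th[idx$s_rel]
        g[idx$log_sigma_s] <- sgs * (sum(th[idx$s_edss] * ge) +
                                       sum(th[idx$s_rel] * gr_)) -
          (th[idx$log_sigma_s] - msl)
      }
    }
    if (logit_cdp) {
      g[idx$gamma_exposure] <- gp$ue - th[idx$gamma_exposure] / sbe^2
    }
    if (!is.null(idx$log_r)) {
      g[idx$log_r] <- lk$dlr - (th[idx$log_r] - spec$prior_r_location) / sr^2
    }
    g[!is.finite(g)] <- 0
    g
  }

  # joint evaluation with a one-entry cache: MALA and BFGS ask for lp and
  # gradient at the same point back to back, and the interleaved
  # slice-sampling scale updates change only coordinates that leave the
  # linear predictor (hence the likelihood parts) untouched in the centred
  # form, so those reuse the cached likelihood.
  scale_coords <- c(if (centred && length(pooled)) idx$log_sigma_alpha,
                    if (centred && !is.null(idx$s_edss)) idx$log_sigma_s)
  lik_coords <- setdiff(seq_len(idx$n_par), scale_coords)
  cache <- new.env(parent = emptyenv())
  eval_all <- function(th) {
    lk <- NULL
    gp <- NULL
    if (!is.null(cache$th)) {
      if (identical(th, cache$th)) return(cache$res)
      if (length(scale_coords) &&
          identical(th[lik_coords], cache$th[lik_coords])) {
        lk <- cache$lk
        gp <- cache$gp
      }
    }
    if (is.null(lk)) {
      lk <- ll_parts(th, eta_of(th))
      gp <- lik_grad_parts(lk)
    }
    lp <- lk$ll + log_prior(th)
    if (!is.finite(lp)) lp <- -1e10
    res <- list(lp = lp, gr = assemble_grad(th, lk, gp))
    cache$th <- th
    cache$lk <- lk
    cache$gp <- gp
    cache$res <- res
    res
  }
  lp_fun <- function(th) eval_all(th)$lp
  gr_fun <- function(th) eval_all(th)$gr

  # 1-D full-conditional log densities of the pooling-scale parameters in
  # the centred form (likelihood-free: given the effects, sigma only sees
  # the hierarchy prior); used for interleaved slice-sampling updates.
  cond_scales <- list()
  if (length(pooled)) {
    cond_scales$log_sigma_alpha <- function(th) {
      a2 <- sum(th[idx$alpha][pooled]^2)
      np <- length(pooled)
      function(v) {
        -np * v - a2 / (2 * exp(2 * pmin(v, 5))) - (v - mal)^2 / 2
      }
    }
  }
  if (!is.null(idx$s_edss)) {
    cond_scales$log_sigma_s <- function(th) {
      s2 <- sum(th[idx$s_edss]^2) + sum(th[idx$s_rel]^2)
      function(v) {
        -2 * k * v - s2 / (2 * exp(2 * pmin(v, 5))) - (v - msl)^2 / 2
      }
    }
  }

  # map a non-centred parameter point to centred coordinates, and the
  # Jacobian of that map (for transporting the Laplace covariance)
  to_centred <- function(th) {
    th[idx$alpha] <- alpha_eff(th)
    if (!is.null(idx$s_edss)) {
      sl <- slope_eff(th)
      th[idx$s_edss] <- sl$se
      th[idx$s_rel] <- sl$sr
    }
    th
  }
  centred_jacobian <- function(th) {
    J <- diag(idx$n_par)
    sig <- exp(pmin(th[idx$log_sigma_alpha], 5))
    for (j in pooled) {
      J[idx$alpha[j], idx$alpha[j]] <- sig
      J[idx$alpha[j], idx$log_sigma_alpha] <- sig * th[idx$alpha[j]]
    }
    if (!is.null(idx$s_edss)) {
      sgs <- exp(pmin(th[idx$log_sigma_s], 5))
      for (j in seq_len(k)) {
        J[idx$s_edss[j], idx$s_edss[j]] <- sgs
        J[idx$s_edss[j], idx$log_sigma_s] <- sgs * th[idx$s_edss[j]]
        J[idx$s_rel[j], idx$s_rel[j]] <- sgs
        J[idx$s_rel[j], idx$log_sigma_s] <- sgs * th[idx$s_rel[j]]
      }
    }
    J
  }

  list(lp = lp_fun, gr = gr_fun, to_centred = to_centred,
       centred_jacobian = centred_jacobian,
       scale_idx = c(log_sigma_alpha = if (length(pooled)) idx$log_sigma_alpha,
                     log_sigma_s = idx$log_sigma_s),
       cond_scales = cond_scales)
}

rowsum_by <- function(x, g, k) {
  # group sums over a small fixed number of groups; tabulate-style, no names
  vapply(seq_len(k), function(j) sum(x[g == j]), 0)
}

colnames_to_dmt <- function(idx) {
  sub("^dmt_", "", idx$names[idx$alpha])
}

# Robust inverse of the Hessian; escalating ridge if needed.
laplace_cov <- function(H) {
  p <- nrow(H)
  for (ridge in c(0, 10^(-8:2))) {
    S <- tryCatch(solve(H + diag(ridge, p)), error = function(e) NULL)
    if (is.null(S)) next
    S <- (S + t(S)) / 2
    if (all(is.finite(S)) && all(diag(S) > 0)) return(S)
  }
  diag(1 / pmax(abs(diag(H)), 1e-4), p)
}

# Robust lower Cholesky factor of a covariance matrix.
laplace_chol_of <- function(S) {
  p <- nrow(S)
  S <- (S + t(S)) / 2
  for (ridge in c(0, 10^(-10:0))) {
    L <- tryCatch(t(chol(S + diag(ridge, p))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  diag(sqrt(pmax(diag(S), 1e-8)), p)
}

laplace_chol <- function(H) laplace_chol_of(laplace_cov(H))

# Multivariate-t log density (up to a constant shared by all evaluations).
mvt_logdens <- function(z2, df, p) {
  -(df + p) / 2 * log1p(z2 / df)
}

# Univariate slice sampler (Neal 2003, stepping out + shrinkage).
slice_sample_1d <- function(logf, x0, w = 0.7, max_steps = 30) {
  y <- logf(x0) + log(stats::runif(1))
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  steps <- 0
  while (logf(lo) > y && steps < max_steps) { lo <- lo - w; steps <- steps + 1 }
  steps <- 0
  while (logf(hi) > y && steps < max_steps) { hi <- hi + w; steps <- steps + 1 }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# One Hamiltonian Monte Carlo chain in the centred parameterisation, with
# interleaved slice-sampling updates of the pooling-scale coordinates. The
# mass matrix is the inverse of a covariance that starts at the Laplace
# estimate (transported from the non-centred mode) and is re-estimated from
# the chain history during warmup; the leapfrog step size adapts towards
# ~80% acceptance and the trajectory length is jittered to avoid
# resonances. Momenta p ~ N(0, S^-1) are drawn as L^-T z so the kinetic
# energy is |z|^2/2 in the preconditioned frame.
run_chain <- function(post, start, S0, n_draws, warmup, chain_seed,
                      target_accept = 0.8, thin = 1, leap_max = 10) {
  p <- length(start)
  with_seed(chain_seed, {
    Sg <- S0
    L <- laplace_chol_of(Sg)
    Lt_inv <- backsolve(t(L), diag(p))   # L^-T
    eps <- 0.5
    cur <- start
    e_cur <- post$lp(cur)
    g_cur <- post$gr(cur)
    hist <- matrix(NA_real_, warmup, p)

    hmc_step <- function() {
      z <- stats::rnorm(p)
      mom <- drop(Lt_inv %*% z)
      k0 <- sum(z^2) / 2
      th <- cur
      g <- g_cur
      n_leap <- sample.int(leap_max, 1)
      mom <- mom + (eps / 2) * g
      for (l in seq_len(n_leap)) {
        th <- th + eps * drop(Sg %*% mom)
        g <- post$gr(th)
        if (l < n_leap) mom <- mom + eps * g
      }
      mom <- mom + (eps / 2) * g
      lp_new <- post$lp(th)
      zt <- drop(t(L) %*% mom)
      k1 <- sum(zt^2) / 2
      lacc <- (lp_new - k1) - (e_cur - k0)
      list(th = th, lp = lp_new, g = g,
           a = if (is.finite(lacc)) min(1, exp(lacc)) else 0)
    }
    gibbs_scales <- function() {
      if (!length(post$cond_scales)) return(FALSE)
      for (nm in names(post$cond_scales)) {
        j <- post$scale_idx[[nm]]
        cur[j] <<- slice_sample_1d(post$cond_scales[[nm]](cur), cur[j])
      }
      e_cur <<- post$lp(cur)
      g_cur <<- post$gr(cur)
      TRUE
    }

    for (s in seq_len(warmup)) {
      st <- hmc_step()
      if (stats::runif(1) < st$a) {
        cur <- st$th; e_cur <- st$lp; g_cur <- st$g
      }
      gibbs_scales()
      eps <- eps * exp((st$a - target_accept) / 15)
      hist[s, ] <- cur
      if (s %% 100 == 0 && s >= 200) {
        S_emp <- stats::cov(hist[max(1, s - 399):s, , drop = FALSE])
        S_new <- 0.7 * S_emp + 0.3 * S0 + diag(1e-10, p)
        L_new <- tryCatch(t(chol(S_new)), error = function(e) NULL)
        if (!is.null(L_new)) {
          Sg <- S_new
          L <- L_new
          Lt_inv <- backsolve(t(L_new), diag(p))
        }
      }
    }
    draws <- matrix(NA_real_, n_draws, p)
    acc <- 0
    total <- n_draws * thin
    for (s in seq_len(total)) {
      st <- hmc_step()
      if (stats::runif(1) < st$a) {
        cur <- st$th; e_cur <- st$lp; g_cur <- st$g
        acc <- acc + 1L
      }
      gibbs_scales()
      if (s %% thin == 0) draws[s / thin, ] <- cur
    }
    list(draws = draws, accept = acc / total)
  })
}

# Split-chain potential-scale-reduction statistic per parameter.
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    m <- nrow(ch)
    h <- floor(m / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  p <- ncol(chains[[1]])
  vapply(seq_len(p), function(j) {
    xs <- lapply(halves, function(h) h[, j])
    m <- length(xs); n <- length(xs[[1]])
    means <- vapply(xs, mean, 0)
    vars <- vapply(xs, stats::var, 0)
    B <- n * stats::var(means)
    W <- mean(vars)
    if (W < 1e-12) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

# Posterior mode from a random start, then Laplace proposal.
find_map <- function(post, n_par, init_seed, init_sd = 0.3) {
  init <- with_seed(init_seed, stats::rnorm(n_par, 0, init_sd))
  opt <- stats::optim(init, fn = function(t) -post$lp(t),
                      gr = function(t) -post$gr(t),
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  H <- stats::optimHess(opt$par, fn = function(t) -post$lp(t),
                        gr = function(t) -post$gr(t))
  list(map = opt$par, H = H, convergence = opt$convergence)
}
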