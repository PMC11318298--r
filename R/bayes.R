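# Bayesian estimation of (f, D*, D).
#
# Model: y_b = f exp(-b D*) + (1-f) exp(-b D) + eps_b, eps_b ~ N(0, sigma^2),
# uniform priors on the constraint box, Jeffreys prior p(sigma) ~ 1/sigma.
# Marginalising sigma gives the closed-form marginal posterior
#   p(f, D*, D | y) propto RSS(f, D*, D)^(-n/2)
# on the box. The point estimate is the marginal posterior mean of each
# parameter. Two engines compute it:
#   grid — deterministic midpoint integration on an adaptive grid that zooms
#          onto the posterior mass (resolution-limited SD shrinks each stage);
#   mcmc — seeded random-walk Metropolis with reflection at the box walls.

.bayes_log_post <- function(rss, n) -(n / 2) * log(pmax(rss, 1e-300))

# Deterministic grid engine. The model is linear in f for fixed (D*, D):
#   S(b) = e2(b) + f (e1(b) - e2(b)),
# so RSS(f | D*, D) = a (f - fhat)^2 + r is an exact quadratic and the f
# dimension can be integrated with a per-cell quadrature whose nodes adapt
# to the local peak location fhat and scale s = sqrt(r / (a (n-1))). Only
# (D*, D) need gridding, which allows a fine 2-D mesh; the sharp
# RSS^(-n/2) integrand makes coarse 3-D grids badly distort the marginals.
# Support-based zoom stages refine (D*, D) for near-noiseless curves whose
# posterior is narrower than the initial mesh.
.bayes_grid <- function(curve, bounds, control) {
  y <- curve$signal; b <- curve$b; n <- length(y)
  ng <- control$bayes_grid_n
  nds <- 3L * ng; nd <- 3L * ng
  K_ad <- ng; K_edge <- max(8L, ng %/% 4L)
  flo <- bounds$f_range[1]; fhi <- bounds$f_range[2]
  nu <- n - 1
  box_ds <- bounds$Dstar_range; box_d <- bounds$D_range
  est <- NULL
  for (stage in seq_len(control$bayes_stages)) {
    dsg <- seq(box_ds[1], box_ds[2], length.out = nds)
    dg <- seq(box_d[1], box_d[2], length.out = nd)
    E1 <- exp(-outer(dsg, b)); E2 <- exp(-outer(dg, b))
    S11 <- rowSums(E1 * E1); S22 <- rowSums(E2 * E2)
    C12 <- E1 %*% t(E2)
    e1y <- as.vector(E1 %*% y); e2y <- as.vector(E2 %*% y)
    A <- pmax(outer(S11, S22, "+") - 2 * C12, 1e-300)
    B <- matrix(e1y, nds, nd) - C12 -
      matrix(e2y, nds, nd, byrow = TRUE) + matrix(S22, nds, nd, byrow = TRUE)
    Cm <- matrix(sum(y * y) - 2 * e2y + S22, nds, nd, byrow = TRUE)
    fh <- as.vector(B / A)
    av <- as.vector(A)
    rv <- pmax(as.vector(Cm) - av * fh * fh, 1e-300)
    sv <- sqrt(rv / (av * nu))
    # three disjoint integration segments in f: the +/-10 s window around
    # the peak (clipped to the box) and the two remaining edge pieces
    seg_lo <- pmin(pmax(fh - 10 * sv, flo), fhi)
    seg_hi <- pmin(pmax(fh + 10 * sv, flo), fhi)
    ncell <- length(fh)
    logM <- rep(-Inf, ncell); m1 <- numeric(ncell); m2 <- numeric(ncell)
    accumulate <- function(lo, hi, K) {
      len <- hi - lo
      use <- len > 0
      tt <- (seq_len(K) - 0.5) / K
      # running log-sum-exp merge of segment masses and f-moments
      for (k in seq_len(K)) {
        f <- lo + len * tt[k]
        logg <- -(n / 2) * log(av * (f - fh)^2 + rv) + log(pmax(len / K, 1e-300))
        logg[!use] <- -Inf
        hi_l <- pmax(logM, logg)
        hi_l[hi_l == -Inf] <- 0
        w_old <- exp(logM - hi_l); w_new <- exp(logg - hi_l)
        tot <- w_old + w_new
        m1 <<- (w_old * m1 + w_new * f) / pmax(tot, 1e-300)
        m2 <<- (w_old * m2 + w_new * f * f) / pmax(tot, 1e-300)
        logM <<- hi_l + log(pmax(tot, 1e-300))
      }
    }
    accumulate(rep(flo, ncell), seg_lo, K_edge)
    accumulate(seg_lo, seg_hi, K_ad)
    accumulate(seg_hi, rep(fhi, ncell), K_edge)
    w <- exp(logM - max(logM))
    w <- w / sum(w)
    mean_f <- sum(w * m1)
    sd_f <- sqrt(max(sum(w * m2) - mean_f^2, 0))
    W <- matrix(w, nds, nd)
    wds <- rowSums(W); wd <- colSums(W)
    mean_ds <- sum(wds * dsg); mean_d <- sum(wd * dg)
    sd_ds <- sqrt(max(sum(wds * dsg^2) - mean_ds^2, 0))
    sd_d <- sqrt(max(sum(wd * dg^2) - mean_d^2, 0))
    est <- list(par = c(mean_f, mean_ds, mean_d), sd = c(sd_f, sd_ds, sd_d))
    if (stage < control$bayes_stages) {
      # refine (D*, D) onto the support of their marginals (+2 cells);
      # this never clips non-negligible mass but resolves narrow posteriors
      shrink <- function(marg, grid, full) {
        sidx <- range(which(marg > 1e-9))
        c(max(full[1], grid[max(1L, sidx[1] - 2L)]),
          min(full[2], grid[min(length(grid), sidx[2] + 2L)]))
      }
      new_ds <- shrink(wds, dsg, bounds$Dstar_range)
      new_d <- shrink(wd, dg, bounds$D_range)
      # stop early when no further refinement is possible
      if (isTRUE(all.equal(new_ds, box_ds)) && isTRUE(all.equal(new_d, box_d)))
        break
      box_ds <- new_ds; box_d <- new_d
    }
  }
  list(par = est$par, sd = est$sd, converged = TRUE)
}

.bayes_mcmc <- function(curve, bounds, control) {
  y <- curve$signal; b <- curve$b; n <- length(y)
  if (is.null(control$bayes_seed))
    stop("the MCMC engine needs an explicit bayes_seed")
  set.seed(control$bayes_seed)
  lo <- c(bounds$f_range[1], bounds$Dstar_range[1], bounds$D_range[1])
  hi <- c(bounds$f_range[2], bounds$Dstar_range[2], bounds$D_range[2])
  wdt <- hi - lo
  reflect <- function(x) {
    # fold proposals back into the box so the chain respects the priors
    for (i in 1:3) {
      while (x[i] < lo[i] || x[i] > hi[i]) {
        if (x[i] < lo[i]) x[i] <- 2 * lo[i] - x[i]
        if (x[i] > hi[i]) x[i] <- 2 * hi[i] - x[i]
      }
    }
    x
  }
  lpost <- function(th) {
    p <- list(f = th[1], Dstar = th[2], D = th[3])
    r <- y - ivim_signal(p, b)
    .bayes_log_post(sum(r * r), n)
  }
  cur <- (lo + hi) / 2
  lcur <- lpost(cur)
  step <- 0.05 * wdt
  total <- control$bayes_burn + control$bayes_samples
  keep <- matrix(NA_real_, control$bayes_samples, 3)
  acc <- 0L
  for (i in seq_len(total)) {
    prop <- reflect(cur + stats::rnorm(3, 0, step))
    lprop <- lpost(prop)
    if (log(stats::runif(1)) < lprop - lcur) {
      cur <- prop; lcur <- lprop; acc <- acc + 1L
    }
    if (i <= control$bayes_burn && i %% 100 == 0) {
      # crude adaptation toward ~30% acceptance during burn-in only
      rate <- acc / i
      step <- step * ifelse(rate > 0.35, 1.2, ifelse(rate < 0.2, 0.8, 1))
    }
    if (i > control$bayes_burn) keep[i - control$bayes_burn, ] <- cur
  }
  ess <- apply(keep, 2, function(v) {
    ac <- stats::acf(v, lag.max = 100, plot = FALSE)$acf[-1]
    pos <- ac[ac > 0.05]
    nrow(keep) / (1 + 2 * sum(pos))
  })
  list(par = colMeans(keep), sd = apply(keep, 2, stats::sd),
       ess = ess, converged = all(ess > 50))
}

.fit_bayes <- function(curve, bounds, control) {
  res <- if (control$bayes_engine == "grid") .bayes_grid(curve, bounds, control)
         else .bayes_mcmc(curve, bounds, control)
  params <- ivim_params(res$par[1], res$par[2], res$par[3])
  tol <- control$boundary_tol
  at <- c(f = .snap_bounds(params$f, bounds$f_range, tol)$at,
          Dstar = .snap_bounds(params$Dstar, bounds$Dstar_range, tol)$at,
          D = .snap_bounds(params$D, bounds$D_range, tol)$at)
  .new_ivim_fit(curve, params, "bayes", bounds, at_boundary = at,
                converged = res$converged,
                extra = list(posterior_sd = c(f = res$sd[1], Dstar = res$sd[2],
                                              D = res$sd[3]),
                             ess = if (is.null(res$ess)) NULL
                                   else c(f = res$ess[1], Dstar = res$ess[2],
                                          D = res$ess[3]),
                             engine = control$bayes_engine))
}
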