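# Adaptive blocked Metropolis-within-Gibbs sampler for the ML-NMR posterior.
#
# Parameter blocks: per-study intercepts, cutpoint increments, prognostic
# coefficients, interaction coefficients, and the treatment-effect structure
# (fixed-effect gammas / UME contrasts as scalar blocks; random-effects
# deltas per study with a conjugate Gibbs update for the consistency means
# and a Metropolis step on log tau). Each Metropolis block carries its own
# adapted proposal scale (Robbins-Monro on the acceptance probability) and,
# for multivariate blocks, an adapted empirical proposal covariance.
# Adaptation runs only during warmup.

half_normal_lpdf <- function(x, scale) {
  if (x < 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

# fast CS-structured RE log density, sans constant checks (tau > 0, lengths ok)
re_lpdf_fast <- function(x, tau) {
  m <- length(x)
  quad <- (2 * sum(x^2) - 2 / (m + 1) * sum(x)^2) / tau^2
  -0.5 * (m * log(2 * pi) + 2 * m * log(tau) + m * log(0.5) + log(m + 1) + quad)
}

new_block <- function(name, kind, dim, units, scale, extra = list()) {
  c(list(name = name, kind = kind, dim = dim, units = units,
         lambda = scale, mean = rep(0, dim),
         cov = diag(dim), chol = diag(dim), count = 0,
         target = if (dim == 1) 0.44 else 0.28,
         n_acc = 0, n_try = 0),
    extra)
}

# RE structure: mapping from the effect parameters (active gammas or UME
# contrasts) to the per-delta consistency means, grouped by study
build_re_structure <- function(design) {
  nd <- which(!design$unit_arm1)
  n_delta <- length(nd)
  n_eff <- if (design$spec$contrasts == "ume") length(design$pairs)
           else design$K - 1L
  M <- matrix(0, n_delta, n_eff)
  delta_study <- design$unit_study[nd]
  for (i in seq_along(nd)) {
    u <- nd[i]
    if (design$spec$contrasts == "ume") {
      M[i, design$unit_pair[u]] <- 1
    } else {
      k <- design$unit_trt[u]
      a1 <- design$arm1[design$unit_study[u]]
      if (k > 1) M[i, k - 1L] <- 1          # active treatment columns
      if (a1 > 1) M[i, a1 - 1L] <- M[i, a1 - 1L] - 1
    }
  }
  groups <- split(seq_along(nd), delta_study)
  list(nd_units = nd, n_delta = n_delta, n_eff = n_eff, M = M,
       delta_study = delta_study, groups = groups)
}

init_chain_state <- function(design, priors, jitter_sd, link) {
  J <- design$J; C <- design$C; p <- design$p
  qf <- if (link == 0L) stats::qnorm else stats::qlogis
  # pooled inclusive proportions -> cutpoint inits; arm-1 proportions -> mu
  tot <- rep(0, C)
  for (u in design$units) {
    tot <- tot + if (u$type == 1L) tabulate(u$y, C) else u$counts
  }
  P <- rev(cumsum(rev(tot)))[-1] / sum(tot)         # inclusive proportions
  P <- clamp(P, 0.005, 0.995)
  cuts <- c(0, qf(P[1]) - qf(P[-1]))
  cuts <- cummax(cuts + c(0, seq_len(C - 2) * 1e-3))
  mu <- numeric(J)
  effz <- numeric(design$n_units)
  for (u in seq_len(design$n_units)) {
    un <- design$units[[u]]
    cnt <- if (un$type == 1L) tabulate(un$y, C) else un$counts
    p1 <- clamp(sum(cnt[-1]) / sum(cnt), 0.01, 0.99)
    effz[u] <- qf(p1)
  }
  for (j in seq_len(J)) {
    a1u <- which(design$unit_study == j & design$unit_arm1)
    mu[j] <- mean(effz[a1u])
  }
  # crude per-treatment effect inits from arm-level probit differences
  gamma0 <- rep(0, design$K)
  for (k in seq_len(design$K)[-1]) {
    us <- which(design$unit_trt == k)
    if (length(us)) gamma0[k] <- mean(effz[us] - mu[design$unit_study[us]])
  }
  list(mu = mu + stats::rnorm(J, 0, jitter_sd),
       cuts = cuts,
       cut_inc = diff(cuts) * exp(stats::rnorm(C - 2, 0, jitter_sd)),
       beta1 = stats::rnorm(p, 0, jitter_sd),
       b2free = stats::rnorm(design$ia$n_free, 0, jitter_sd),
       gamma0 = gamma0)
}

expand_B2 <- function(design, b2free) {
  full <- c(0, b2free)
  matrix(full[design$ia$map + 1L], design$p, design$K)
}

run_chain <- function(design, priors, n_warmup, n_iter, seed, jitter_sd = 0.1,
                      report_lp = TRUE) {
  set.seed(seed)
  sd0 <- priors$effect_sd
  link <- design$link
  random <- design$spec$effects == "random"
  ume <- design$spec$contrasts == "ume"
  J <- design$J; C <- design$C; p <- design$p; K <- design$K
  m2 <- design$ia$n_free
  init <- init_chain_state(design, priors, jitter_sd, link)

  st <- new.env(parent = emptyenv())
  st$mu <- init$mu
  st$cuts <- c(0, cumsum(init$cut_inc))
  st$beta1 <- init$beta1
  st$b2free <- init$b2free
  st$B2 <- expand_B2(design, st$b2free)
  # covariate row owning each free interaction coefficient
  lmap <- vapply(seq_len(m2), function(i)
    which(design$ia$map == i, arr.ind = TRUE)[1, 1], 0L)
  st$phi <- st$beta1[lmap] + st$b2free
  if (ume) {
    eff_lab <- design$pairs
    a1t <- design$trts[design$arm1[design$unit_study]]
    st$theta_eff <- vapply(seq_along(design$pairs), function(e) {
      us <- which(!design$unit_arm1 & design$unit_pair == e)
      kk <- design$unit_trt[us[1]]
      a1 <- design$arm1[design$unit_study[us[1]]]
      init$gamma0[kk] - init$gamma0[a1]
    }, 0)
  } else {
    eff_lab <- design$trts[-1]
    st$theta_eff <- init$gamma0[-1]
  }
  st$theta_eff <- st$theta_eff + stats::rnorm(length(st$theta_eff), 0, jitter_sd)
  re <- if (random) build_re_structure(design) else NULL
  if (random) {
    st$tau <- abs(stats::rnorm(1, 0.2, 0.1)) + 0.01
    st$delta <- as.numeric(re$M %*% st$theta_eff) +
      stats::rnorm(re$n_delta, 0, jitter_sd)
  }

  compute_eff <- function() {
    eff <- numeric(design$n_units)
    if (random) {
      eff[re$nd_units] <- st$delta
    } else if (ume) {
      nd <- !design$unit_arm1
      eff[nd] <- st$theta_eff[design$unit_pair[nd]]
    } else {
      gam <- c(0, st$theta_eff)
      eff <- gam[design$unit_trt]
    }
    eff
  }
  st$eff <- compute_eff()

  # Internal grand-mean centering: the likelihood rows are shifted by the
  # data-weighted covariate mean, so intercept/effect moves are orthogonal
  # to the regression coefficients. Draws are mapped back to the user frame
  # (the declared centering values) at snapshot time; priors are placed on
  # the sampling frame (with vague scales the difference is negligible).
  xbar <- numeric(p)
  if (p > 0) {
    wtot <- 0
    for (u in seq_len(design$n_units)) {
      un <- design$units[[u]]
      w <- if (un$type == 1L) 1 else un$N / nrow(un$X)
      xbar <- xbar + colSums(un$X) * w
      wtot <- wtot + nrow(un$X) * w
    }
    xbar <- xbar / wtot
  }
  cunits <- design$units
  if (p > 0) for (u in seq_along(cunits))
    cunits[[u]]$X <- sweep(cunits[[u]]$X, 2, xbar)
  # (arm-1 treatment, treatment) indices per UME contrast
  pair_k <- pair_a1 <- integer(length(design$pairs))
  for (e in seq_along(design$pairs)) {
    u0 <- which(design$unit_pair == e)[1]
    pair_k[e] <- design$unit_trt[u0]
    pair_a1[e] <- design$arm1[design$unit_study[u0]]
  }

  ll_units <- function(which) {
    cpp_unit_loglik(cunits, st$mu, st$cuts, st$beta1, st$B2, st$eff,
                    which, link)
  }
  all_units <- seq_len(design$n_units)
  st$ull <- ll_units(all_units)

  # ---- block construction -------------------------------------------------
  blocks <- list()
  for (j in seq_len(J)) {
    blocks[[length(blocks) + 1L]] <-
      new_block(paste0("mu", j), "mu", 1L, which(design$unit_study == j), 0.1,
                list(j = j))
  }
  if (C > 2)
    blocks[[length(blocks) + 1L]] <-
      new_block("cuts", "cuts", C - 2L, all_units, 0.03)
  # The likelihood sees x'(beta1 + beta2_k): on arms covered by an
  # interaction coefficient only the sum phi_i = beta1_l + beta2_i is
  # informed, so we sample phi (one block per coefficient owner, i.e. class
  # or treatment) and beta1 (informed by the arms with no interaction term,
  # chiefly the reference arms). beta2 = phi - beta1 is recovered for
  # reporting; the N(0, sd0^2) prior on beta2 couples the blocks only weakly.
  if (p > 0) {
    b1_units <- which(vapply(seq_len(design$n_units), function(u)
      any(design$ia$map[, design$unit_trt[u]] == 0L) || design$p == 0, TRUE))
    if (!length(b1_units)) b1_units <- all_units
    blocks[[length(blocks) + 1L]] <-
      new_block("beta1", "beta1", p, b1_units, 0.05)
  }
  if (m2 > 0) {
    owners <- sub(":[^:]*$", "", design$ia$labels)
    for (ow in unique(owners)) {
      idx <- which(owners == ow)
      trt_uses <- which(apply(design$ia$map, 2, function(col) any(col %in% idx)))
      us <- which(design$unit_trt %in% trt_uses)
      blocks[[length(blocks) + 1L]] <-
        new_block(paste0("phi_", ow), "phi", length(idx), us,
                  0.05, list(idx = idx))
    }
  }
  if (!random) {
    for (e in seq_along(st$theta_eff)) {
      us <- if (ume) which(!design$unit_arm1 & design$unit_pair == e)
            else which(design$unit_trt == e + 1L)
      blocks[[length(blocks) + 1L]] <-
        new_block(paste0("eff", e), "eff", 1L, us, 0.1, list(e = e))
    }
    # joint (effect, intercepts of its studies) blocks: arm-level abilities
    # mu_j + gamma_k are tightly determined, so gamma and the mu's of the
    # studies informing it move along a sharp ridge the adapted covariance
    # can follow
    for (e in seq_along(st$theta_eff)) {
      uk <- if (ume) which(!design$unit_arm1 & design$unit_pair == e)
            else which(design$unit_trt == e + 1L)
      js <- unique(design$unit_study[uk])
      us <- which(design$unit_study %in% js)
      blocks[[length(blocks) + 1L]] <-
        new_block(paste0("tj", e), "trtjoint", 1L + length(js), us, 0.05,
                  list(e = e, js = js, uk = uk))
    }
  } else {
    for (g in seq_along(re$groups)) {
      ids <- re$groups[[g]]
      blocks[[length(blocks) + 1L]] <-
        new_block(paste0("delta", g), "delta", length(ids),
                  re$nd_units[ids], 0.1, list(ids = ids))
    }
    # joint (mu_j, delta_j) per-study blocks for the within-study ridge
    for (g in seq_along(re$groups)) {
      ids <- re$groups[[g]]
      j <- re$delta_study[ids[1]]
      us <- which(design$unit_study == j)
      blocks[[length(blocks) + 1L]] <-
        new_block(paste0("sj", g), "studyjoint", 1L + length(ids), us, 0.05,
                  list(j = j, ids = ids))
    }
  }
  # Joint adapted block over (intercepts, cutpoints, effect structure):
  # arm-level "abilities" mu_j + eff are tightly determined by the data, so
  # the scalar blocks alone diffuse slowly along the treatment-graph ridge;
  # the adapted covariance of this block learns those ridge directions.
  gdim <- J + (C - 2L) + if (random) re$n_delta else length(st$theta_eff)
  blocks[[length(blocks) + 1L]] <-
    new_block("global", "global", gdim, all_units, 0.05)

  re_mean <- function() as.numeric(re$M %*% st$theta_eff)

  re_lprior_groups <- function(delta, mean, tau) {
    s <- 0
    for (ids in re$groups) s <- s + re_lpdf_fast(delta[ids] - mean[ids], tau)
    s
  }

  # ---- MH update for one block -------------------------------------------
  update_block <- function(b, adapt, t) {
    dim <- b$dim
    z <- stats::rnorm(dim)
    step <- b$lambda * as.numeric(t(b$chol) %*% z)
    cur <- switch(b$kind,
      mu = st$mu[b$j], cuts = diff(st$cuts), beta1 = st$beta1,
      phi = st$phi[b$idx],
      eff = st$theta_eff[b$e], delta = st$delta[b$ids],
      trtjoint = c(st$theta_eff[b$e], st$mu[b$js]),
      studyjoint = c(st$mu[b$j], st$delta[b$ids]),
      global = c(st$mu, if (C > 2) diff(st$cuts),
                 if (random) st$delta else st$theta_eff))
    prop <- cur + step
    reject <- FALSE
    if (b$kind == "cuts" && any(prop <= 0)) reject <- TRUE
    if (b$kind == "global" && C > 2 && any(prop[J + seq_len(C - 2)] <= 0))
      reject <- TRUE
    lpd <- 0
    if (!reject) {
      old_ull <- st$ull[b$units]
      # stage proposal into state
      switch(b$kind,
        mu = { old <- st$mu; st$mu[b$j] <- prop
               lpd <- stats::dnorm(prop, 0, sd0, TRUE) -
                      stats::dnorm(cur[1], 0, sd0, TRUE) },
        cuts = { old <- st$cuts; st$cuts <- c(0, cumsum(prop)) },
        beta1 = { old1 <- st$beta1; old2 <- st$b2free; oldB2 <- st$B2
                  st$beta1 <- prop
                  st$b2free <- st$phi - prop[lmap]
                  st$B2 <- expand_B2(design, st$b2free)
                  lpd <- sum(stats::dnorm(prop, 0, sd0, TRUE)) -
                         sum(stats::dnorm(cur, 0, sd0, TRUE)) +
                         sum(stats::dnorm(st$b2free, 0, sd0, TRUE)) -
                         sum(stats::dnorm(old2, 0, sd0, TRUE)) },
        phi = { oldphi <- st$phi; old2 <- st$b2free; oldB2 <- st$B2
                st$phi[b$idx] <- prop
                st$b2free[b$idx] <- prop - st$beta1[lmap[b$idx]]
                st$B2 <- expand_B2(design, st$b2free)
                lpd <- sum(stats::dnorm(st$b2free[b$idx], 0, sd0, TRUE)) -
                       sum(stats::dnorm(old2[b$idx], 0, sd0, TRUE)) },
        eff = { old <- st$theta_eff; oldeff <- st$eff
                st$theta_eff[b$e] <- prop
                st$eff[b$units] <- prop
                lpd <- stats::dnorm(prop, 0, sd0, TRUE) -
                       stats::dnorm(cur[1], 0, sd0, TRUE) },
        delta = { old <- st$delta; oldeff <- st$eff
                  st$delta[b$ids] <- prop
                  st$eff[b$units] <- prop
                  mn <- re_mean()[b$ids]
                  lpd <- re_lpdf_fast(prop - mn, st$tau) -
                         re_lpdf_fast(cur - mn, st$tau) },
        trtjoint = {
          old_te <- st$theta_eff; old_mu <- st$mu; oldeff <- st$eff
          st$theta_eff[b$e] <- prop[1]
          st$mu[b$js] <- prop[-1]
          st$eff[b$uk] <- prop[1]
          lpd <- sum(stats::dnorm(prop, 0, sd0, TRUE)) -
                 sum(stats::dnorm(cur, 0, sd0, TRUE))
        },
        studyjoint = {
          old_mu <- st$mu; old_delta <- st$delta; oldeff <- st$eff
          st$mu[b$j] <- prop[1]
          st$delta[b$ids] <- prop[-1]
          st$eff[re$nd_units[b$ids]] <- prop[-1]
          mn <- re_mean()[b$ids]
          lpd <- stats::dnorm(prop[1], 0, sd0, TRUE) -
                 stats::dnorm(cur[1], 0, sd0, TRUE) +
                 re_lpdf_fast(prop[-1] - mn, st$tau) -
                 re_lpdf_fast(cur[-1] - mn, st$tau)
        },
        global = {
          old_mu <- st$mu; old_cuts <- st$cuts; oldeff <- st$eff
          old_te <- st$theta_eff
          old_delta <- if (random) st$delta
          st$mu <- prop[seq_len(J)]
          if (C > 2) st$cuts <- c(0, cumsum(prop[J + seq_len(C - 2)]))
          rest <- prop[(J + C - 1L):length(prop)]
          lpd <- sum(stats::dnorm(st$mu, 0, sd0, TRUE)) -
                 sum(stats::dnorm(old_mu, 0, sd0, TRUE))
          if (random) {
            st$delta <- rest
            st$eff[re$nd_units] <- rest
            mn <- re_mean()
            lpd <- lpd + re_lprior_groups(rest, mn, st$tau) -
                   re_lprior_groups(old_delta, mn, st$tau)
          } else {
            st$theta_eff <- rest
            if (ume) {
              nd <- !design$unit_arm1
              st$eff[nd] <- rest[design$unit_pair[nd]]
            } else st$eff <- c(0, rest)[design$unit_trt]
            lpd <- lpd + sum(stats::dnorm(rest, 0, sd0, TRUE)) -
                   sum(stats::dnorm(old_te, 0, sd0, TRUE))
          }
        })
      new_ull <- ll_units(b$units)
      lalpha <- sum(new_ull) - sum(old_ull) + lpd
      if (is.finite(lalpha) && log(stats::runif(1)) < lalpha) {
        st$ull[b$units] <- new_ull
        b$n_acc <- b$n_acc + 1
      } else {
        # roll back
        switch(b$kind,
          mu = { st$mu <- old },
          cuts = { st$cuts <- old },
          beta1 = { st$beta1 <- old1; st$b2free <- old2; st$B2 <- oldB2 },
          phi = { st$phi <- oldphi; st$b2free <- old2; st$B2 <- oldB2 },
          eff = { st$theta_eff <- old; st$eff <- oldeff },
          delta = { st$delta <- old; st$eff <- oldeff },
          trtjoint = { st$theta_eff <- old_te; st$mu <- old_mu
                       st$eff <- oldeff },
          studyjoint = { st$mu <- old_mu; st$delta <- old_delta
                         st$eff <- oldeff },
          global = { st$mu <- old_mu; st$cuts <- old_cuts; st$eff <- oldeff
                     st$theta_eff <- old_te
                     if (random) st$delta <- old_delta })
        lalpha <- if (is.finite(lalpha)) lalpha else -Inf
      }
    } else lalpha <- -Inf
    b$n_try <- b$n_try + 1
    if (adapt) {
      acc <- min(1, exp(lalpha))
      eta <- min(0.9, 5 * t^-0.7)
      b$lambda <- b$lambda * exp(eta * (acc - b$target))
      if (dim > 1) {
        val <- switch(b$kind, cuts = diff(st$cuts), beta1 = st$beta1,
                      phi = st$phi[b$idx],
                      delta = st$delta[b$ids],
                      trtjoint = c(st$theta_eff[b$e], st$mu[b$js]),
                      studyjoint = c(st$mu[b$j], st$delta[b$ids]),
                      global = c(st$mu, if (C > 2) diff(st$cuts),
                                 if (random) st$delta else st$theta_eff))
        b$count <- b$count + 1
        w <- 1 / (b$count + 5)
        dmean <- val - b$mean
        b$mean <- b$mean + w * dmean
        b$cov <- (1 - w) * b$cov + w * tcrossprod(dmean)
        if (b$count > 2 * dim && b$count %% 25 == 0) {
          ch <- tryCatch(chol(b$cov / mean(diag(b$cov)) + diag(1e-6, dim)),
                         error = function(e) NULL)
          if (!is.null(ch)) b$chol <- ch
        }
      }
    }
    b
  }

  gibbs_eff <- function() {
    # theta_eff | delta, tau: conjugate multivariate normal
    prec <- diag(1 / sd0^2, re$n_eff)
    bvec <- rep(0, re$n_eff)
    for (ids in re$groups) {
      m <- length(ids)
      Mi <- re$M[ids, , drop = FALSE]
      Sinv <- (2 * diag(m) - 2 / (m + 1)) / st$tau^2
      prec <- prec + t(Mi) %*% Sinv %*% Mi
      bvec <- bvec + as.numeric(t(Mi) %*% Sinv %*% st$delta[ids])
    }
    ch <- chol(prec)
    mean <- backsolve(ch, backsolve(ch, bvec, transpose = TRUE))
    st$theta_eff <- mean + backsolve(ch, stats::rnorm(re$n_eff))
  }

  tau_b <- list(lambda = 0.3, n_acc = 0, n_try = 0)
  update_tau <- function(adapt, t) {
    lt <- log(st$tau)
    ltp <- lt + tau_b$lambda * stats::rnorm(1)
    taup <- exp(ltp)
    mn <- re_mean()
    la <- (half_normal_lpdf(taup, priors$tau_scale) + ltp +
             re_lprior_groups(st$delta, mn, taup)) -
          (half_normal_lpdf(st$tau, priors$tau_scale) + lt +
             re_lprior_groups(st$delta, mn, st$tau))
    if (is.finite(la) && log(stats::runif(1)) < la) {
      st$tau <- taup
      tau_b$n_acc <<- tau_b$n_acc + 1
    }
    tau_b$n_try <<- tau_b$n_try + 1
    if (adapt) {
      acc <- min(1, exp(if (is.finite(la)) la else -Inf))
      tau_b$lambda <<- tau_b$lambda * exp(min(0.9, 5 * t^-0.7) * (acc - 0.44))
    }
  }

  # ---- report layout ------------------------------------------------------
  parnames <- c(paste0("mu[", design$studies, "]"),
                if (C > 2) paste0("cut[", 2:(C - 1), "]"),
                if (p > 0) paste0("beta1[", design$covs, "]"),
                if (m2 > 0) paste0("beta2[", design$ia$labels, "]"),
                paste0(if (ume) "d[" else "gamma[", eff_lab, "]"),
                if (random) paste0("delta[",
                  design$studies[design$unit_study[re$nd_units]], ":",
                  design$trts[design$unit_trt[re$nd_units]], "]"),
                if (random) "tau",
                if (report_lp) "loglik__")
  draws <- matrix(NA_real_, n_iter, length(parnames),
                  dimnames = list(NULL, parnames))

  # map sampled (grand-mean-centered) parameters back to the user frame:
  # eta = mu~ + (x - xbar)'(b1 + B2k) + eff~ = mu + x'(b1 + B2k) + eff
  snapshot <- function() {
    shift <- if (p > 0) as.numeric(xbar %*% st$B2) else numeric(K)
    b1s <- if (p > 0) sum(xbar * st$beta1) else 0
    mu_rep <- if (random || ume)
      st$mu - b1s - shift[design$arm1] else st$mu - b1s
    theta_rep <- if (ume) st$theta_eff - (shift[pair_k] - shift[pair_a1])
                 else st$theta_eff - shift[-1]
    delta_rep <- if (random)
      st$delta - (shift[design$unit_trt[re$nd_units]] -
                  shift[design$arm1[re$delta_study]])
    c(mu_rep,
      if (C > 2) st$cuts[-1],
      if (p > 0) st$beta1,
      if (m2 > 0) st$b2free,
      theta_rep,
      if (random) delta_rep,
      if (random) st$tau,
      if (report_lp) sum(st$ull))
  }

  total <- n_warmup + n_iter
  for (t in seq_len(total)) {
    adapt <- t <= n_warmup
    for (bi in seq_along(blocks)) blocks[[bi]] <- update_block(blocks[[bi]], adapt, t)
    if (random) {
      gibbs_eff()
      update_tau(adapt, t)
      # refresh RE-prior-dependent cached logliks are unaffected (prior only)
    }
    if (t > n_warmup) draws[t - n_warmup, ] <- snapshot()
  }
  acc <- vapply(blocks, function(b) b$n_acc / max(b$n_try, 1), 0)
  names(acc) <- vapply(blocks, `[[`, "", "name")
  if (random) acc <- c(acc, tau = tau_b$n_acc / max(tau_b$n_try, 1))
  list(draws = draws, accept = acc)
}
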