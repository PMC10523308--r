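# Independent oracles used across the suite. These are deliberately naive
# implementations (loops, enumeration, grids) kept separate from the
# package's code paths.

# Cox partial log-likelihood, Breslow ties (test data keeps times distinct
# so Breslow == Efron), plain loops over risk sets
oracle_cox_loglik <- function(beta, x, time, event) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# full Newton-Raphson with analytic gradient/Hessian, written independently
oracle_cox_newton <- function(x, time, event, tol = 1e-12, max_iter = 100) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    g <- rep(0, p)
    H <- matrix(0, p, p)
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      w <- exp(eta[risk])
      s0 <- sum(w)
      s1 <- colSums(x[risk, , drop = FALSE] * w)
      xbar <- s1 / s0
      g <- g + x[i, ] - xbar
      s2 <- crossprod(x[risk, , drop = FALSE] * sqrt(w))
      H <- H + s2 / s0 - tcrossprod(xbar)
    }
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(H))))
}

# exhaustive IPCW case/control pair enumeration for the horizon AUC
oracle_ipcw_auc <- function(marker, time, event, horizon) {
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    s <- 1
    for (k in seq_along(cens_fit$time)) {
      if (cens_fit$time[k] <= t) s <- cens_fit$surv[k]
    }
    s
  }
  Gminus <- function(t) {
    s <- 1
    for (k in seq_along(cens_fit$time)) {
      if (cens_fit$time[k] < t) s <- cens_fit$surv[k]
    }
    s
  }
  num <- den <- 0
  for (i in seq_along(time)) {
    if (!(time[i] <= horizon && event[i] == 1)) next
    wi <- 1 / Gminus(time[i])
    for (j in seq_along(time)) {
      if (!(time[j] > horizon)) next
      wj <- 1 / G(horizon)
      conc <- if (marker[i] > marker[j]) 1
              else if (marker[i] == marker[j]) 0.5 else 0
      num <- num + wi * wj * conc
      den <- den + wi * wj
    }
  }
  num / den
}

# adjusted Rand index between two partitions
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# small separable three-subtype expression matrix: block genes carry
# opposite shifts in Types 1 and 3; Type 2 gets its own orthogonal
# pattern so all three classes are separated in pattern space; plus
# pure-noise genes
make_blob_cohort <- function(n_per = 30, n_block = 8, n_noise = 12,
                             delta = 3, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per
  subtype <- factor(rep(paste("Type", 1:3), each = n_per),
                    levels = paste("Type", 1:3))
  dirs <- rep_len(c(1, -1), n_block)
  shift <- c(-1, 0, 1)[as.integer(subtype)] * delta
  block <- outer(shift, dirs) + matrix(rnorm(n * n_block), n, n_block)
  noise <- matrix(rnorm(n * n_noise), n, n_noise)
  # Type 2 carries its own pattern on four non-block genes so all three
  # classes are separated in pattern space
  noise[, 1:4] <- noise[, 1:4] +
    outer(delta * (subtype == "Type 2"), c(1, -1, 1, -1))
  x <- cbind(block, noise)
  colnames(x) <- sprintf("G%03d", seq_len(ncol(x)))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  list(x = x, subtype = subtype, block_genes = colnames(x)[seq_len(n_block)],
       directions = dirs)
}
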