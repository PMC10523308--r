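#' Batch univariate Cox regression across many covariates
#'
#' Fits, for every column of `x` separately, the one-covariate Cox
#' proportional hazards model by Newton-Raphson on the partial likelihood
#' with Efron handling of tied event times. An optional per-sample offset
#' carries previously extracted latent components into the fit, which is the
#' weight-estimation step of partial Cox regression and the per-gene ranking
#' step of the ensemble selection procedure; vectorising over covariates is
#' what makes repeated per-round ranking of thousands of genes feasible.
#'
#' @param x numeric matrix, samples in rows, covariates (genes) in columns.
#' @param time positive follow-up times in months.
#' @param event 0/1 event indicator (1 = recurrence/progression).
#' @param offset optional per-sample linear-predictor offset (default 0).
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the per-covariate log partial
#'   likelihood change.
#' @return list with per-covariate vectors: `coefficients`, `se`
#'   (from the observed information), `wald` (squared z, `(beta/se)^2`),
#'   `loglik`, `loglik_null`, `converged`, plus `n_events`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' f <- cox_univariate_batch(x, rexp(20), rbinom(20, 1, 0.7))
#' f$coefficients
#' @export
cox_univariate_batch <- function(x, time, event, offset = NULL,
                                 max_iter = 50, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(time) == n, length(event) == n)
  if (any(!is.finite(x))) stop("covariates must be finite")
  if (any(time <= 0)) stop("times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  n_events <- sum(event)
  if (n_events == 0) stop("no events: Cox partial likelihood undefined")
  if (is.null(offset)) offset <- rep(0, n)

  ord <- order(time, -event)   # ascending time; within ties events first
  x <- x[ord, , drop = FALSE]
  time <- time[ord]
  event <- event[ord]
  offset <- offset[ord]

  # tied-time groups; risk set at an event time = all rows with time >= t
  grp <- match(time, unique(time))
  first_of_grp <- which(!duplicated(grp))
  ev_grp_ids <- sort(unique(grp[event == 1]))
  d_per_grp <- vapply(ev_grp_ids,
                      function(g) sum(event == 1 & grp == g), integer(1))
  G <- length(ev_grp_ids)
  risk_rows <- first_of_grp[ev_grp_ids]   # row index whose revcumsum = risk-set sum
  max_d <- max(d_per_grp)
  ev <- event == 1
  grp_ev <- grp[ev]

  revcumsum <- function(m) {
    # reverse cumulative sums down each column
    m <- apply(m[n:1, , drop = FALSE], 2, cumsum)
    m[n:1, , drop = FALSE]
  }
  x2 <- x * x
  sum_x_death <- rowsum(x[ev, , drop = FALSE], grp_ev)          # G x p
  # per-covariate partial log-likelihood pieces given eta = offset + x*beta
  plik_parts <- function(beta) {
    eta <- sweep(x, 2, beta, `*`) + offset
    eta <- pmin(eta, 500)                       # overflow guard
    e <- exp(eta)
    xe <- x * e
    x2e <- x2 * e
    S0R <- revcumsum(e)[risk_rows, , drop = FALSE]
    S1R <- revcumsum(xe)[risk_rows, , drop = FALSE]
    S2R <- revcumsum(x2e)[risk_rows, , drop = FALSE]
    S0D <- rowsum(e[ev, , drop = FALSE], grp_ev)
    S1D <- rowsum(xe[ev, , drop = FALSE], grp_ev)
    S2D <- rowsum(x2e[ev, , drop = FALSE], grp_ev)
    ll <- colSums(sweep(x[ev, , drop = FALSE], 2, beta, `*`)) +
      sum(offset[ev])
    gr <- colSums(sum_x_death)
    info <- rep(0, p)
    for (l in seq_len(max_d) - 1L) {
      act <- d_per_grp > l
      frac <- l / d_per_grp[act]
      phi0 <- S0R[act, , drop = FALSE] - frac * S0D[act, , drop = FALSE]
      phi1 <- S1R[act, , drop = FALSE] - frac * S1D[act, , drop = FALSE]
      phi2 <- S2R[act, , drop = FALSE] - frac * S2D[act, , drop = FALSE]
      ll <- ll - colSums(log(phi0))
      r1 <- phi1 / phi0
      gr <- gr - colSums(r1)
      info <- info + colSums(phi2 / phi0 - r1 * r1)
    }
    list(ll = ll, gr = gr, info = info)
  }

  beta <- rep(0, p)
  parts <- plik_parts(beta)
  loglik_null <- parts$ll[1]   # beta=0: identical across covariates up to offset
  ll_old <- parts$ll
  converged <- rep(FALSE, p)
  for (it in seq_len(max_iter)) {
    step <- ifelse(parts$info > 1e-12, parts$gr / pmax(parts$info, 1e-12), 0)
    step <- pmax(pmin(step, 5), -5)             # cap wild steps
    beta_new <- beta + ifelse(converged, 0, step)
    parts_new <- plik_parts(beta_new)
    # step-halving for covariates whose likelihood decreased
    bad <- !converged & (parts_new$ll < ll_old - 1e-12)
    half <- 0
    while (any(bad) && half < 10) {
      beta_new[bad] <- (beta[bad] + beta_new[bad]) / 2
      parts_new <- plik_parts(beta_new)
      bad <- !converged & (parts_new$ll < ll_old - 1e-12)
      half <- half + 1
    }
    newly <- !converged & (abs(parts_new$ll - ll_old) < tol)
    beta <- beta_new
    ll_old <- parts_new$ll
    parts <- parts_new
    converged <- converged | newly
    if (all(converged)) break
  }
  se <- ifelse(parts$info > 1e-12, 1 / sqrt(parts$info), NA_real_)
  wald <- ifelse(is.na(se), 0, (beta / se)^2)
  list(coefficients = beta, se = se, wald = wald,
       loglik = parts$ll, loglik_null = loglik_null,
       converged = converged, n_events = n_events)
}
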