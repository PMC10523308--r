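#' Partial Cox regression (PLS-style latent survival components)
#'
#' Fits the latent-component survival model in the style of Li and Gui's
#' partial Cox regression. Genes are standardised (centre, unit SD), then
#' components are extracted sequentially: for component k the per-gene
#' weight is the univariate Cox coefficient of the current (deflated)
#' covariate with the scores of components 1..k-1 entered as a fixed
#' offset; the component score is the weight-combined covariates scaled to
#' unit sample variance; covariates are then deflated by their least-squares
#' projection on the new score. A final Cox fit on the K component scores
#' gives the component coefficients, and back-substitution through the
#' deflation recursion yields a composite per-gene coefficient vector so
#' that the risk score is a single linear predictor over standardised
#' expression.
#'
#' @param x expression matrix, samples in rows, genes in columns
#'   (log-scale normalised values).
#' @param time positive follow-up times in months.
#' @param event 0/1 recurrence indicator.
#' @param ncomp number of latent components K (>= 1); silently truncated
#'   with a warning if it exceeds the rank of `x`.
#' @return object of class `partial_cox`: `gene_ids`, `center`, `scale`,
#'   `comp_weights` (genes x K, unit-norm per-component weights on the
#'   deflated covariates), `xweights` (genes x K, weights expressed on the
#'   original standardised covariates so scores = Z %*% xweights),
#'   `comp_coef` (Cox coefficients on the scores), `composite`
#'   (per-gene composite coefficients), `scores`, `cox`, `ncomp`.
#' @seealso [choose_ncomp()] for cross-validated selection of K.
#' @export
partial_cox <- function(x, time, event, ncomp = 3) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  stopifnot(ncomp >= 1)
  if (sum(event) < 2) stop("need at least 2 events")
  n <- nrow(x)
  p <- ncol(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1                      # constant genes contribute 0
  z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)

  kmax <- min(ncomp, n - 1, p)
  if (kmax < ncomp) warning("ncomp truncated to ", kmax, " (rank limit)")
  cur <- z
  offset <- rep(0, n)
  comp_w <- matrix(0, p, kmax)       # weights on deflated covariates
  xw <- matrix(0, p, kmax)           # weights on original standardised covariates
  scores <- matrix(0, n, kmax)
  loadings <- matrix(0, p, kmax)
  keep <- logical(kmax)
  for (k in seq_len(kmax)) {
    uni <- cox_univariate_batch(cur, time, event, offset = offset)
    w <- uni$coefficients
    if (sqrt(sum(w^2)) < 1e-10) break        # nothing left to extract
    w <- w / sqrt(sum(w^2))
    t_raw <- drop(cur %*% w)
    s <- stats::sd(t_raw)
    if (s < 1e-10) break
    t_k <- t_raw / s
    comp_w[, k] <- w
    # express t_k in the original standardised covariates:
    # t_k = cur %*% w / s and cur = z - scores[,<k] %*% t(loadings[,<k])
    r_k <- w / s
    if (k > 1) {
      prev <- which(keep)
      r_k <- r_k - xw[, prev, drop = FALSE] %*%
        crossprod(loadings[, prev, drop = FALSE], w) / s
    }
    xw[, k] <- r_k
    scores[, k] <- t_k
    loadings[, k] <- crossprod(cur, t_k) / sum(t_k^2)
    cur <- cur - tcrossprod(t_k, loadings[, k])
    keep[k] <- TRUE
    if (k < kmax) {
      # per-gene fits for the next component take the scores so far as a
      # fixed offset through a Cox fit on those scores
      fit_k <- fit_cox(scores[, seq_len(k), drop = FALSE], time, event)
      offset <- drop(scores[, seq_len(k), drop = FALSE] %*% fit_k$coefficients)
    }
  }
  kk <- which(keep)
  if (length(kk) == 0) stop("no informative component could be extracted")
  scores <- scores[, kk, drop = FALSE]
  comp_w <- comp_w[, kk, drop = FALSE]
  xw <- xw[, kk, drop = FALSE]
  if (length(kk) == 1) {
    # single component: the multivariable fit collapses to univariate Cox
    b <- cox_univariate_batch(scores, time, event)
    cox <- structure(list(coefficients = c(t1 = b$coefficients),
                          se = c(t1 = b$se), wald = c(t1 = b$wald),
                          loglik = b$loglik, loglik_null = b$loglik_null,
                          converged = b$converged, n = n,
                          n_events = b$n_events, ties = "efron"),
                     class = "cox_fit")
  } else {
    cox <- fit_cox(scores, time, event)
  }
  composite <- drop(xw %*% cox$coefficients)
  structure(list(gene_ids = colnames(x), center = ctr, scale = scl,
                 comp_weights = comp_w, xweights = xw,
                 comp_coef = cox$coefficients,
                 composite = stats::setNames(composite, colnames(x)),
                 scores = scores, cox = cox, ncomp = length(kk),
                 n = n, n_events = sum(event)),
            class = "partial_cox")
}

#' @export
print.partial_cox <- function(x, ...) {
  cat("Partial Cox regression:", x$ncomp, "component(s),",
      length(x$gene_ids), "genes,", x$n, "samples,", x$n_events, "events\n")
  cat("Component Cox coefficients:", format(x$comp_coef, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.partial_cox <- function(object, type = c("composite", "components"), ...) {
  type <- match.arg(type)
  if (type == "composite") object$composite else object$comp_coef
}

#' Predict risk scores from a partial Cox model
#'
#' @param object fitted [partial_cox()] model.
#' @param newdata matrix with samples in rows; must contain every model
#'   gene (by column name).
#' @param standardize `"training"` (default) scales new samples with the
#'   training per-gene mean/SD; `"cohort"` re-standardises with the new
#'   cohort's own statistics, the convention used when scoring an
#'   externally quantified cohort; `"none"` uses the values as given.
#' @param ... unused.
#' @return numeric linear predictor, higher = higher hazard.
#' @export
predict.partial_cox <- function(object, newdata,
                                standardize = c("training", "cohort", "none"),
                                ...) {
  standardize <- match.arg(standardize)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$gene_ids))
      stop("newdata has no column names and the wrong number of columns")
    colnames(newdata) <- object$gene_ids
  }
  miss <- setdiff(object$gene_ids, colnames(newdata))
  if (length(miss) > 0)
    stop("missing model genes: ", paste(miss, collapse = ", "))
  z <- newdata[, object$gene_ids, drop = FALSE]
  if (standardize == "training") {
    z <- sweep(sweep(z, 2, object$center), 2, object$scale, `/`)
  } else if (standardize == "cohort") {
    ctr <- colMeans(z)
    scl <- apply(z, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    z <- sweep(sweep(z, 2, ctr), 2, scl, `/`)
  }
  drop(z %*% object$composite)
}

# Verweij-van Houwelingen cross-validated partial likelihood contribution
# of held-out folds for a model with a fixed linear predictor lp:
# l_full(lp) - l_train(lp_train)
cv_partial_loglik <- function(lp, time, event, fold, f) {
  ll <- function(lp, time, event) {
    if (length(lp) == 0 || sum(event) == 0) return(0)
    b <- cox_univariate_batch(matrix(0, length(lp), 1), time, event,
                              offset = lp, max_iter = 1)
    b$loglik_null
  }
  tr <- fold != f
  ll(lp, time, event) - ll(lp[tr], time[tr], event[tr])
}

#' Choose the number of latent components by cross-validation
#'
#' Maximises the Verweij-van Houwelingen cross-validated partial
#' log-likelihood over K = 0..`k_max` (K = 0 is the null model); ties are
#' broken toward smaller K. Deterministic given `(data, seed)`.
#'
#' @inheritParams partial_cox
#' @param k_max largest K considered.
#' @param folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @return list with `k` (selected), `cvpl` (named vector over K = 0..k_max).
#' @export
choose_ncomp <- function(x, time, event, k_max = 5, folds = 5, seed = 1) {
  stopifnot(k_max >= 1)
  x <- as.matrix(x)
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # event-stratified folds so every training fold keeps events
  fold <- integer(n)
  for (g in unique(event)) {
    idx <- which(event == g)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  cvpl <- stats::setNames(numeric(k_max + 1), 0:k_max)
  for (f in seq_len(folds)) {
    tr <- fold != f
    cvpl["0"] <- cvpl["0"] +
      cv_partial_loglik(rep(0, n), time, event, fold, f)
    fit_max <- tryCatch(
      partial_cox(x[tr, , drop = FALSE], time[tr], event[tr], ncomp = k_max),
      error = function(e) NULL)
    for (k in seq_len(k_max)) {
      lp <- rep(0, n)
      if (!is.null(fit_max) && k <= fit_max$ncomp) {
        sub <- fit_max
        sub$composite <- drop(sub$xweights[, 1:k, drop = FALSE] %*%
          fit_cox(sub$scores[, 1:k, drop = FALSE],
                  time[tr], event[tr])$coefficients)
        lp <- predict.partial_cox(sub, x, standardize = "training")
      }
      cvpl[as.character(k)] <- cvpl[as.character(k)] +
        cv_partial_loglik(lp, time, event, fold, f)
    }
  }
  list(k = as.integer(names(cvpl)[which.max(cvpl)]), cvpl = cvpl)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
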