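#' Configuration for the ensemble prognostic-gene selection run
#'
#' Defaults follow the published procedure where it states them: 20
#' resampling rounds of virtual cohorts each holding at least 70% of
#' patients, consistency judged against the top 200 ranks, and a Wald floor
#' of 4.7 (the half-maximum Wald statistic in the original training set;
#' dataset-specific, hence configurable). Quantities the procedure leaves
#' open (the consistency quantifier, combination size, combinations per
#' round) are explicit knobs.
#'
#' @param n_rounds number of resampling rounds.
#' @param subsample_fraction fraction of patients per virtual cohort.
#' @param combination_size genes per combination in the multi-gene layer.
#' @param combinations_per_round combinations fitted per round; must give
#'   every gene a chance to be covered at least once per round.
#' @param top_k rank cutoff defining "top ranked" within a round.
#' @param consistency_fraction minimum fraction of rounds a gene must rank
#'   in the top `top_k` to count as consistent.
#' @param wald_fraction selected genes need median Wald above this fraction
#'   of the maximum median Wald.
#' @param wald_floor absolute lower bound on the median Wald (squared-z
#'   scale, chi-square 1 df).
#' @param min_follow_up months of follow-up required for a censored case to
#'   count as a definitive non-recurrence in the second pass.
#' @param stratify_by `NULL` or `"event"` to draw virtual cohorts
#'   preserving the event rate.
#' @param ncomp latent components per multi-gene partial Cox fit.
#' @param seed integer master seed.
#' @return list of class `highlifer_config`.
#' @export
highlifer_config <- function(n_rounds = 20, subsample_fraction = 0.7,
                             combination_size = 50,
                             combinations_per_round = 200,
                             top_k = 200, consistency_fraction = 0.9,
                             wald_fraction = 0.5, wald_floor = 4.7,
                             min_follow_up = 36, stratify_by = NULL,
                             ncomp = 1, seed = 1) {
  stopifnot(n_rounds >= 1, subsample_fraction > 0, subsample_fraction <= 1,
            combination_size >= 2, combinations_per_round >= 1,
            top_k >= 1, consistency_fraction > 0, consistency_fraction <= 1,
            wald_fraction >= 0, wald_floor >= 0, min_follow_up >= 0)
  if (!is.null(stratify_by)) stopifnot(identical(stratify_by, "event"))
  structure(as.list(environment()), class = "highlifer_config")
}

#' Draw virtual cohorts
#'
#' Each round's virtual cohort is a fresh subset of `ceiling(fraction * n)`
#' samples drawn without replacement, independently across rounds;
#' optionally stratified on the event indicator so every cohort preserves
#' the observed event rate.
#'
#' @param n number of samples.
#' @param config [highlifer_config()].
#' @param event 0/1 vector, required when `config$stratify_by == "event"`.
#' @return list of `n_rounds` integer index vectors.
#' @export
make_virtual_cohorts <- function(n, config, event = NULL) {
  size <- ceiling(config$subsample_fraction * n)
  if (size < 10) stop("virtual cohorts would have fewer than 10 samples")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  lapply(seq_len(config$n_rounds), function(r) {
    if (identical(config$stratify_by, "event")) {
      stopifnot(!is.null(event), length(event) == n)
      idx1 <- which(event == 1)
      idx0 <- which(event == 0)
      k1 <- round(size * length(idx1) / n)
      sort(c(sample(idx1, k1), sample(idx0, size - k1)))
    } else {
      sort(sample.int(n, size))
    }
  })
}

# draw B gene combinations of size m covering every gene at least once:
# a random permutation is chopped into blocks (guaranteed coverage), the
# remaining combinations are uniform draws
draw_combinations <- function(p, m, B) {
  m <- min(m, p)
  n_cover <- ceiling(p / m)
  if (B < n_cover)
    stop("combinations_per_round too small to cover every gene (need >= ",
         n_cover, ")")
  perm <- sample.int(p)
  cover <- split(perm, ceiling(seq_along(perm) / m))
  cover <- lapply(cover, function(ix) {
    if (length(ix) < m) unique(c(ix, sample.int(p, m)))[1:m] else ix
  })
  extra <- lapply(seq_len(B - n_cover), function(b) sample.int(p, m))
  c(cover, extra)
}

#' Rank genes within one virtual cohort round
#'
#' Each gene's round-level Wald statistic is its univariate Cox Wald
#' (squared z) within the cohort; the round rank is the descending order of
#' these Wald values with ties broken by gene id. On top of that, the round
#' fits a partial Cox model to each of `combinations_per_round` random
#' gene combinations (coverage-guaranteed) and records per-gene composite
#' coefficient magnitudes as a stability layer.
#'
#' @param x expression matrix (samples x genes).
#' @param time,event survival outcome.
#' @param cohort integer sample indices for this round's virtual cohort.
#' @param config [highlifer_config()].
#' @param round_seed integer seed for this round's combination draws.
#' @return list: `wald`, `rank` (permutation of 1..p), `mean_abs_coef`
#'   (average |composite coefficient| over combinations containing the
#'   gene), `n_failed` (combinations that failed to converge and were
#'   skipped).
#' @export
rank_genes_in_round <- function(x, time, event, cohort, config, round_seed) {
  xs <- x[cohort, , drop = FALSE]
  ts <- time[cohort]
  es <- event[cohort]
  if (sum(es) < 2) stop("virtual cohort has fewer than 2 events")
  p <- ncol(x)
  uni <- cox_univariate_batch(xs, ts, es)
  wald <- uni$wald
  ord <- order(-wald, colnames(x))
  rk <- integer(p)
  rk[ord] <- seq_len(p)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(round_seed)
  combos <- draw_combinations(p, config$combination_size,
                              config$combinations_per_round)
  coef_sum <- numeric(p)
  coef_n <- numeric(p)
  n_failed <- 0L
  for (cb in combos) {
    fit <- tryCatch(
      partial_cox(xs[, cb, drop = FALSE], ts, es, ncomp = config$ncomp),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    coef_sum[cb] <- coef_sum[cb] + abs(fit$composite)
    coef_n[cb] <- coef_n[cb] + 1
  }
  list(wald = stats::setNames(wald, colnames(x)),
       rank = stats::setNames(rk, colnames(x)),
       mean_abs_coef = stats::setNames(
         ifelse(coef_n > 0, coef_sum / coef_n, NA_real_), colnames(x)),
       n_failed = n_failed)
}

#' Aggregate per-round gene records into a ranking summary
#'
#' @param round_records list of results from [rank_genes_in_round()].
#' @param top_k rank cutoff used for the consistency fraction.
#' @return data.frame with one row per gene: `gene_id`, `median_rank`,
#'   `top_k_fraction`, `median_wald`, `mean_abs_coef`, `rounds_observed`.
#' @export
aggregate_rounds <- function(round_records, top_k = 200) {
  stopifnot(length(round_records) >= 1)
  ranks <- sapply(round_records, `[[`, "rank")
  walds <- sapply(round_records, `[[`, "wald")
  coefs <- sapply(round_records, `[[`, "mean_abs_coef")
  if (is.null(dim(ranks))) {
    ranks <- matrix(ranks, nrow = 1); walds <- matrix(walds, nrow = 1)
    coefs <- matrix(coefs, nrow = 1)
  }
  data.frame(gene_id = names(round_records[[1]]$rank),
             median_rank = apply(ranks, 1, stats::median),
             top_k_fraction = rowMeans(ranks <= top_k),
             median_wald = apply(walds, 1, stats::median),
             mean_abs_coef = rowMeans(coefs, na.rm = TRUE),
             rounds_observed = ncol(ranks),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the consistency and Wald selection criteria
#'
#' A gene is selected iff it ranked within the top `top_k` in at least
#' `consistency_fraction` of rounds, and its median Wald statistic exceeds
#' `max(wald_fraction * max(median Wald over genes), wald_floor)` — the
#' half-maximum-Wald rule with an absolute floor.
#'
#' @param summary data.frame from [aggregate_rounds()].
#' @param config [highlifer_config()].
#' @return `summary` with a logical `selected` column, plus attribute
#'   `wald_cutoff`.
#' @export
select_prognostic_genes <- function(summary, config) {
  stopifnot(nrow(summary) > 0)
  cutoff <- max(config$wald_fraction * max(summary$median_wald),
                config$wald_floor)
  summary$selected <- summary$top_k_fraction >= config$consistency_fraction &
    summary$median_wald > cutoff
  attr(summary, "wald_cutoff") <- cutoff
  summary
}

#' Restrict to samples with definitive 36-month outcomes
#'
#' Keeps samples with an observed recurrence (any time), or censored with
#' at least `min_follow_up` months of follow-up; drops early-censored
#' samples whose outcome is unknown.
#'
#' @param time,event survival outcome.
#' @param min_follow_up months (default 36).
#' @return logical keep vector.
#' @export
filter_definitive_outcomes <- function(time, event, min_follow_up = 36) {
  event == 1 | time >= min_follow_up
}

#' Ensemble prognostic gene selection (two-pass union)
#'
#' Runs the full resampling selection twice — once on all samples and once
#' on the definitive-outcome subset (recurrences plus censored cases with
#' at least `min_follow_up` months of follow-up, which removes the dilution
#' from early-censored unknowns) — and returns the union of the two
#' selections with provenance flags. A composite partial Cox scoring model
#' is fitted on the selected genes.
#'
#' @inheritParams rank_genes_in_round
#' @param config [highlifer_config()].
#' @return object of class `highlifer`: `summary` (per-gene table with
#'   `selected` and `pass` in `{"pass1", "pass2", "both"}` or `NA`),
#'   `selected_genes`, `config`, `pass1`, `pass2` (per-pass summaries),
#'   `model` (composite [partial_cox()] on the selected genes, or `NULL`
#'   if the selection is empty), `n_failed`.
#' @export
highlifer <- function(x, time, event, config = highlifer_config()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time), length(time) == length(event))

  run_pass <- function(idx, seed_shift) {
    xs <- x[idx, , drop = FALSE]
    ts <- time[idx]
    es <- event[idx]
    cohorts <- make_virtual_cohorts(length(idx), config, event = es)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed + seed_shift)
    round_seeds <- sample.int(.Machine$integer.max - 1, config$n_rounds)
    recs <- lapply(seq_len(config$n_rounds), function(r) {
      rank_genes_in_round(xs, ts, es, cohorts[[r]], config, round_seeds[r])
    })
    smry <- aggregate_rounds(recs, top_k = config$top_k)
    list(summary = select_prognostic_genes(smry, config),
         n_failed = sum(vapply(recs, `[[`, integer(1), "n_failed")))
  }

  pass1 <- run_pass(seq_len(nrow(x)), 0L)
  keep <- filter_definitive_outcomes(time, event, config$min_follow_up)
  pass2 <- run_pass(which(keep), 1L)

  sel1 <- pass1$summary$gene_id[pass1$summary$selected]
  sel2 <- pass2$summary$gene_id[pass2$summary$selected]
  selected <- union(sel1, sel2)
  smry <- pass1$summary
  smry$selected <- smry$gene_id %in% selected
  smry$pass <- ifelse(smry$gene_id %in% intersect(sel1, sel2), "both",
                 ifelse(smry$gene_id %in% sel1, "pass1",
                   ifelse(smry$gene_id %in% sel2, "pass2", NA_character_)))
  model <- NULL
  if (length(selected) >= 2) {
    model <- partial_cox(x[, selected, drop = FALSE], time, event,
                         ncomp = min(config$ncomp + 2, length(selected)))
  }
  structure(list(summary = smry, selected_genes = selected, config = config,
                 pass1 = pass1$summary, pass2 = pass2$summary,
                 model = model,
                 n_failed = pass1$n_failed + pass2$n_failed),
            class = "highlifer")
}

#' @export
print.highlifer <- function(x, ...) {
  cat("Ensemble prognostic gene selection\n")
  cat("  genes scored:   ", nrow(x$summary), "\n")
  cat("  rounds per pass:", x$config$n_rounds, "\n")
  cat("  selected:       ", length(x$selected_genes),
      sprintf(" (pass1 %d, pass2 %d, both %d)\n",
              sum(x$summary$pass %in% "pass1"),
              sum(x$summary$pass %in% "pass2"),
              sum(x$summary$pass %in% "both")), sep = "")
  invisible(x)
}

#' @export
summary.highlifer <- function(object, ...) {
  s <- object$summary[object$summary$selected, ]
  s[order(s$median_rank), ]
}

#' Predict composite risk scores from a selection run
#'
#' @param object a [highlifer()] result with a fitted scoring model.
#' @param newdata expression matrix covering the selected genes.
#' @param ... passed to [predict.partial_cox()].
#' @export
predict.highlifer <- function(object, newdata, ...) {
  if (is.null(object$model)) stop("no scoring model: selection was empty")
  predict(object$model, newdata, ...)
}
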