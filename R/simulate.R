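#' Configuration for the synthetic PTC cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' three molecular subtypes drawn from the combined-cohort prevalences
#' (25.0% / 47.3% / 27.7%), a correlated planted gene block whose genes
#' carry a direction: "up" genes are shifted +delta in Type 3 and -delta
#' in Type 1 and "down" genes the reverse, so the Type 1 expression
#' pattern is the inverse of Type 3 and the pattern (not just the level)
#' separates subtypes, recurrence
#' times from a proportional-hazards exponential model driven by the
#' planted genes plus an advanced-stage clinical effect, uniform
#' administrative censoring, nodal status with the subtype-specific N1
#' rates observed clinically (17.5% / 50.2% / 58.3%), log-normal tumor
#' sizes, and an ATA label drawn independently of outcome (an
#' uninformative baseline by construction).
#'
#' @param n_samples cohort size.
#' @param n_genes total genes p.
#' @param planted_block_size number of planted prognostic genes.
#' @param block_shift delta, subtype mean shift of block genes in SD units.
#' @param log_hazard_ratios per planted gene log hazard ratio magnitude
#'   per SD (recycled to the block size); the sign follows the gene's
#'   block direction, so "up" genes are hazard-increasing and "down"
#'   genes protective.
#' @param block_cor within-block correlation rho.
#' @param baseline_hazard lambda, events/month for a reference sample.
#' @param censor_window months; censoring uniform on (0, window].
#' @param subtype_priors probabilities of Types 1/2/3 (sum 1).
#' @param n1_prob_by_subtype P(N1) for Types 1/2/3.
#' @param size_meanlog,size_sdlog log-normal tumor size parameters (cm).
#' @param advanced_log_hr additional log hazard for advanced tumors.
#' @param ata_probs marginal probabilities of ATA low/intermediate/high.
#' @param weibull_shape shape of the baseline event-time distribution
#'   (1 = exponential).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 500, n_genes = 1000,
                              planted_block_size = 10, block_shift = 1.5,
                              log_hazard_ratios = 0.05, block_cor = 0.6,
                              baseline_hazard = 0.001, censor_window = 120,
                              subtype_priors = c(0.250, 0.473, 0.277),
                              n1_prob_by_subtype = c(0.175, 0.502, 0.583),
                              size_meanlog = log(2), size_sdlog = 0.55,
                              advanced_log_hr = 2.5,
                              ata_probs = c(0.65, 0.19, 0.16),
                              weibull_shape = 1, seed = 1) {
  stopifnot(abs(sum(subtype_priors) - 1) < 1e-8, block_shift >= 0,
            baseline_hazard > 0, censor_window > 0,
            length(subtype_priors) == 3, length(n1_prob_by_subtype) == 3,
            block_cor >= 0, block_cor < 1, weibull_shape > 0)
  if (planted_block_size > n_genes)
    stop("planted_block_size exceeds n_genes")
  log_hazard_ratios <- rep_len(log_hazard_ratios, planted_block_size)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a synthetic PTC cohort with known ground truth
#'
#' @param config [simulation_config()].
#' @return object of class `simulated_cohort`: `expression` (samples x
#'   genes), `time`, `event`, `clinical` (data.frame with `sample_id`,
#'   `tumor_size_cm`, `n_stage`, `m_stage`, `ata_risk`), `true_subtype`
#'   (factor), `true_prognostic_genes`, `block_direction` (+1/-1 per
#'   planted gene), `true_log_hr` (signed per-gene log hazard ratios),
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_genes
  m <- config$planted_block_size
  gene_ids <- sprintf("G%04d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))

  subtype <- factor(paste("Type", sample(1:3, n, replace = TRUE,
                                         prob = config$subtype_priors)),
                    levels = paste("Type", 1:3))
  shift <- c(-1, 0, 1)[as.integer(subtype)] * config$block_shift

  expr <- matrix(stats::rnorm(n * p), n, p,
                 dimnames = list(sample_ids, gene_ids))
  direction <- rep_len(c(1, -1), m)       # up/down genes alternate
  beta <- direction * config$log_hazard_ratios
  if (m > 0) {
    rho <- config$block_cor
    f <- stats::rnorm(n)                      # shared block factor
    blk <- outer(sqrt(rho) * f + shift, direction) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
    expr[, seq_len(m)] <- blk
  }

  n1 <- stats::rbinom(n, 1, config$n1_prob_by_subtype[as.integer(subtype)])
  size <- stats::rlnorm(n, config$size_meanlog, config$size_sdlog)
  advanced <- size > 4 | n1 == 1
  ata <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                prob = config$ata_probs)

  lp <- drop(expr[, seq_len(m), drop = FALSE] %*% beta) +
    config$advanced_log_hr * advanced
  # Weibull with shape k and PH rate scaling: T = (E / (lambda * e^lp))^(1/k)
  e_std <- stats::rexp(n)
  t_event <- (e_std / (config$baseline_hazard * exp(lp)))^
    (1 / config$weibull_shape)
  t_cens <- stats::runif(n, 0, config$censor_window)
  time <- unname(pmax(pmin(t_event, t_cens), 1e-6))
  event <- unname(as.integer(t_event <= t_cens))

  clinical <- data.frame(sample_id = sample_ids,
                         tumor_size_cm = size,
                         n_stage = ifelse(n1 == 1, "N1", "N0"),
                         m_stage = "M0",
                         ata_risk = ata,
                         stringsAsFactors = FALSE)
  structure(list(expression = expr, time = time, event = event,
                 clinical = clinical, true_subtype = subtype,
                 true_prognostic_genes = gene_ids[seq_len(m)],
                 block_direction = stats::setNames(direction,
                                                   gene_ids[seq_len(m)]),
                 true_log_hr = stats::setNames(beta, gene_ids[seq_len(m)]),
                 config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Synthetic PTC cohort:", length(x$time), "samples,",
      ncol(x$expression), "genes,", sum(x$event), "events\n")
  print(table(x$true_subtype))
  invisible(x)
}

#' Simulate a global-null cohort
#'
#' As [simulate_cohort()] but with the block shift and every log hazard
#' ratio (gene and clinical) set to zero: expression, subtype and clinical
#' covariates carry no survival information.
#'
#' @param config [simulation_config()].
#' @return `simulated_cohort` (with `true_prognostic_genes` empty).
#' @export
simulate_null_cohort <- function(config = simulation_config()) {
  config$block_shift <- 0
  config$log_hazard_ratios <- rep(0, config$planted_block_size)
  config$advanced_log_hr <- 0
  cohort <- simulate_cohort(config)
  cohort$true_prognostic_genes <- character(0)
  cohort
}

#' Write a simulated cohort to pipeline-format text files
#'
#' Writes `expression.tsv` (first column `gene_id`, one column per
#' sample), `survival.tsv` (`sample_id`, `time_months`, `event` plus the
#' clinical columns) and `truth.json` (true subtype per sample, planted
#' prognostic gene ids, generator configuration). A round-trip through
#' [read_cohort()] reproduces the in-memory objects.
#'
#' @param cohort [simulate_cohort()] result.
#' @param dir writable output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  surv_path <- file.path(dir, "survival.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_expression_tsv(cohort$expression, expr_path)
  surv <- data.frame(sample_id = cohort$clinical$sample_id,
                     time_months = cohort$time, event = cohort$event,
                     cohort$clinical[, setdiff(names(cohort$clinical),
                                               "sample_id"), drop = FALSE],
                     stringsAsFactors = FALSE)
  utils::write.table(surv, surv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(true_subtype = stats::setNames(as.character(cohort$true_subtype),
                                        cohort$clinical$sample_id),
         true_prognostic_genes = cohort$true_prognostic_genes,
         config = unclass(cohort$config)),
    truth_path, auto_unbox = TRUE, digits = NA)
  c(expression = expr_path, survival = surv_path, truth = truth_path)
}

#' Read cohort files written by [write_fixture_files()]
#'
#' @param dir directory containing `expression.tsv`, `survival.tsv` and
#'   optionally `truth.json`.
#' @return list: `expression` (samples x genes), `survival` (data.frame),
#'   `truth` (list or `NULL`).
#' @export
read_cohort <- function(dir) {
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  surv <- utils::read.table(file.path(dir, "survival.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::fromJSON(truth_path)
           else NULL
  list(expression = expr, survival = surv, truth = truth)
}

#' Expression TSV I/O
#'
#' The on-disk orientation is genes x samples (first column `gene_id`);
#' in memory the package works with samples x genes matrices.
#'
#' @param x samples x genes matrix with dimnames.
#' @param path TSV path.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = colnames(x), t(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$gene_id
  m
}
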