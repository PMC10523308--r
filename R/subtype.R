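#' Unsupervised clustering of samples on selected genes
#'
#' Hierarchical clustering of sample expression profiles with distance
#' 1 - Pearson correlation and Ward linkage, cut at `k` clusters.
#' Correlation distance matches the "expression pattern" semantics of the
#' subtype definition (two samples with proportional profiles are close
#' regardless of overall level).
#'
#' @param x expression matrix over the selected genes (samples x genes).
#' @param k number of clusters (default 3).
#' @return object of class `subtype_clusters`: `assignments` (integer per
#'   sample), `centroids` (k x genes mean expression), `hclust`, `k`.
#' @export
cluster_samples <- function(x, k = 3) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of samples")
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(n))
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  centroids <- rowsum(x, cl) / as.vector(table(cl))
  structure(list(assignments = cl, centroids = centroids, hclust = hc, k = k),
            class = "subtype_clusters")
}

#' @export
print.subtype_clusters <- function(x, ...) {
  cat("Hierarchical clustering (1 - Pearson, Ward), k =", x$k, "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Correlated gene blocks
#'
#' All gene pairs with Pearson correlation above `r_threshold` (self-pairs
#' excluded) and the connected components ("blocks") of the resulting gene
#' graph. Mirrors the observation that the most highly intercorrelated
#' prognostic genes (r > 0.75) form a proliferation block.
#'
#' @param x expression matrix (samples x genes).
#' @param r_threshold correlation cutoff (default 0.75).
#' @return list: `pairs` (data.frame gene_a, gene_b, r), `blocks` (list of
#'   gene-id vectors, connected components of size >= 2).
#' @export
correlated_gene_blocks <- function(x, r_threshold = 0.75) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  cm <- stats::cor(x)
  p <- ncol(x)
  adj <- cm > r_threshold
  diag(adj) <- FALSE
  ut <- which(upper.tri(cm) & adj, arr.ind = TRUE)
  pairs <- data.frame(gene_a = colnames(x)[ut[, 1]],
                      gene_b = colnames(x)[ut[, 2]],
                      r = cm[ut], stringsAsFactors = FALSE)
  # connected components by breadth-first search
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  blocks <- split(colnames(x), comp)
  blocks <- unname(blocks[lengths(blocks) >= 2])
  list(pairs = pairs, blocks = blocks)
}

#' Label clusters as molecular Types 1, 2 and 3
#'
#' Type 3 is the cluster with the highest centroid mean over the
#' hazard-increasing correlated block (the connected r > 0.75 block whose
#' genes mostly carry positive risk coefficients); Type 1 is the cluster
#' whose centroid over the selected genes is most anti-correlated with the
#' Type 3 centroid (the inverse-pattern rule); Type 2 is the remaining
#' cluster.
#'
#' @param model [cluster_samples()] result with `k = 3`.
#' @param x expression matrix over the selected genes used for clustering.
#' @param gene_effects named per-gene risk direction (e.g. composite
#'   partial Cox coefficients or univariate Cox coefficients); positive
#'   means hazard-increasing. Used to orient the risk block. If no
#'   correlated block exists, the block falls back to the genes with
#'   positive effects.
#' @param r_threshold correlation cutoff for the block search.
#' @return list: `type_of_cluster` (integer vector mapping cluster index
#'   to type), `subtype` (factor per sample with levels "Type 1", "Type 2",
#'   "Type 3"), `risk_block` (gene ids used for orientation).
#' @export
assign_subtype_labels <- function(model, x, gene_effects,
                                  r_threshold = 0.75) {
  if (model$k != 3) stop("subtype labeling requires k = 3")
  x <- as.matrix(x)
  stopifnot(!is.null(colnames(x)), !is.null(names(gene_effects)))
  gene_effects <- gene_effects[colnames(x)]
  blocks <- correlated_gene_blocks(x, r_threshold)$blocks
  if (length(blocks) > 0) {
    # among blocks, prefer those oriented with increasing hazard; take the
    # largest such, falling back to the largest block overall
    pos_frac <- vapply(blocks, function(b) mean(gene_effects[b] > 0),
                       numeric(1))
    cand <- which(pos_frac > 0.5)
    pick <- if (length(cand) > 0) cand[which.max(lengths(blocks)[cand])]
            else which.max(lengths(blocks))
    risk_block <- blocks[[pick]]
  } else {
    risk_block <- names(gene_effects)[gene_effects > 0]
    if (length(risk_block) == 0) stop("no hazard-increasing genes to orient on")
  }
  block_mean <- rowMeans(model$centroids[, risk_block, drop = FALSE])
  if (anyDuplicated(block_mean))
    stop("tie in block centroid means; supply labels manually")
  type3 <- which.max(block_mean)
  others <- setdiff(seq_len(3), type3)
  anti <- vapply(others, function(cl) {
    stats::cor(model$centroids[type3, ], model$centroids[cl, ])
  }, numeric(1))
  if (anyDuplicated(anti))
    stop("tie in centroid anti-correlation; supply labels manually")
  type1 <- others[which.min(anti)]
  type2 <- setdiff(others, type1)
  type_of_cluster <- integer(3)
  type_of_cluster[c(type1, type2, type3)] <- c(1L, 2L, 3L)
  subtype <- factor(paste("Type", type_of_cluster[model$assignments]),
                    levels = paste("Type", 1:3))
  list(type_of_cluster = type_of_cluster, subtype = subtype,
       risk_block = risk_block)
}

std_params <- function(x) {
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = colMeans(x), scale = scl)
}

apply_std <- function(x, prm) {
  sweep(sweep(x, 2, prm$center), 2, prm$scale, `/`)
}

#' Train the two-step random forest subtype classifier
#'
#' Step 1 separates Type 3 from the rest on all samples; step 2 separates
#' Type 1 from Type 2 and is trained only on non-Type-3 samples. Features
#' are z-scored with the training cohort's per-gene mean/SD. Random
#' forests use 500 trees and the default sqrt(p) features per split.
#'
#' @param x expression matrix over the classifier genes (samples x genes).
#' @param subtype factor with levels "Type 1", "Type 2", "Type 3".
#' @param n_trees trees per forest.
#' @param seed integer seed (forest growth is randomised).
#' @return object of class `two_step_classifier`.
#' @export
two_step_classifier <- function(x, subtype, n_trees = 500, seed = 1) {
  x <- as.matrix(x)
  subtype <- factor(subtype, levels = paste("Type", 1:3))
  if (any(is.na(subtype))) stop("subtype labels must be Type 1/2/3")
  if (nlevels(droplevels(subtype)) < 3) stop("all three subtypes required")
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  prm <- std_params(x)
  z <- apply_std(x, prm)
  y1 <- factor(ifelse(subtype == "Type 3", "Type3", "rest"),
               levels = c("rest", "Type3"))
  non3 <- subtype != "Type 3"
  y2 <- droplevels(factor(subtype[non3], levels = paste("Type", 1:2)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rf1 <- randomForest::randomForest(z, y1, ntree = n_trees)
  rf2 <- randomForest::randomForest(z[non3, , drop = FALSE], y2,
                                    ntree = n_trees)
  structure(list(step1 = rf1, step2 = rf2, gene_ids = colnames(x),
                 center = prm$center, scale = prm$scale,
                 n_trees = n_trees, seed = seed),
            class = "two_step_classifier")
}

#' @export
print.two_step_classifier <- function(x, ...) {
  cat("Two-step random forest subtype classifier:",
      length(x$gene_ids), "genes,", x$n_trees, "trees per step\n")
  invisible(x)
}

#' Predict molecular subtypes
#'
#' Applies step 1 (Type 3 vs rest) and, for samples not called Type 3,
#' step 2 (Type 1 vs Type 2). By default a new cohort is z-scored with its
#' own per-gene mean/SD — the scaled-input convention for externally
#' quantified cohorts; use `standardize = "training"` to reuse the
#' training parameters (appropriate for held-out samples from the same
#' normalisation batch).
#'
#' @param object [two_step_classifier()].
#' @param newdata expression matrix containing every classifier gene.
#' @param standardize `"cohort"` (default), `"training"`, or `"none"`.
#' @param ... unused.
#' @return data.frame: `subtype` (factor), `step1_score` (P(Type 3)),
#'   `step2_score` (P(Type 1); reported for every sample but entering the
#'   decision path only when step 1 does not call Type 3).
#' @export
predict.two_step_classifier <- function(object, newdata,
                                        standardize = c("cohort", "training",
                                                        "none"), ...) {
  standardize <- match.arg(standardize)
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$gene_ids, colnames(newdata))
  if (length(miss) > 0)
    stop("missing classifier genes: ", paste(miss, collapse = ", "))
  z <- newdata[, object$gene_ids, drop = FALSE]
  if (standardize == "training") {
    z <- apply_std(z, list(center = object$center, scale = object$scale))
  } else if (standardize == "cohort") {
    z <- apply_std(z, std_params(z))
  }
  p3 <- stats::predict(object$step1, z, type = "prob")[, "Type3"]
  p1 <- stats::predict(object$step2, z, type = "prob")[, "Type 1"]
  is3 <- p3 > 0.5
  subtype <- ifelse(is3, "Type 3", ifelse(p1 > 0.5, "Type 1", "Type 2"))
  data.frame(subtype = factor(subtype, levels = paste("Type", 1:3)),
             step1_score = p3,
             step2_score = p1,
             row.names = rownames(newdata))
}

#' Stratified 10-fold cross-validation of the two-step classifier
#'
#' Folds are stratified by subtype. Step 1 accuracy is measured on all
#' held-out samples (Type 3 vs rest); step 2 accuracy only on held-out
#' samples that are truly Type 1 or Type 2.
#'
#' @inheritParams two_step_classifier
#' @param folds number of folds (default 10).
#' @return object of class `cv_report`: `step1_acc`, `step2_acc`
#'   (per-fold), `mean_step1`, `mean_step2`.
#' @export
cross_validate_two_step <- function(x, subtype, folds = 10, n_trees = 500,
                                    seed = 1) {
  x <- as.matrix(x)
  subtype <- factor(subtype, levels = paste("Type", 1:3))
  n <- nrow(x)
  if (min(table(subtype)) < folds)
    stop("a subtype has fewer samples than folds; stratification impossible")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(subtype)) {
    idx <- which(subtype == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  acc1 <- acc2 <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    clf <- two_step_classifier(x[tr, , drop = FALSE], subtype[tr],
                               n_trees = n_trees, seed = seed + f)
    pred <- predict(clf, x[!tr, , drop = FALSE], standardize = "training")
    truth <- subtype[!tr]
    acc1[f] <- mean((pred$subtype == "Type 3") == (truth == "Type 3"))
    non3 <- truth != "Type 3"
    step2_call <- ifelse(pred$step2_score > 0.5, "Type 1", "Type 2")
    acc2[f] <- mean(step2_call[non3] == as.character(truth[non3]))
  }
  structure(list(step1_acc = acc1, step2_acc = acc2,
                 mean_step1 = mean(acc1), mean_step2 = mean(acc2),
                 folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: step 1 (Type 3 vs rest) accuracy %.3f; step 2 (Type 1 vs 2) accuracy %.3f\n",
              x$folds, x$mean_step1, x$mean_step2))
  invisible(x)
}
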