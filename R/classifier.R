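# Extract per-tree structure from a randomForest ensemble: node depths,
# first-split depth per variable, and internal-node counts per depth.
.tree_depth_stats <- function(rf, k) {
  tr <- randomForest::getTree(rf, k, labelVar = FALSE)
  n <- nrow(tr)
  depth <- rep(NA_real_, n)
  depth[1] <- 0
  split_node <- tr[, "status"] == 1
  for (i in seq_len(n)) {
    if (!split_node[i] || is.na(depth[i])) next
    depth[tr[i, "left daughter"]] <- depth[i] + 1
    depth[tr[i, "right daughter"]] <- depth[i] + 1
  }
  ints <- which(split_node & !is.na(depth))
  if (!length(ints))
    return(list(first_depth = numeric(0), nodes_at_depth = integer(0),
                max_depth = 0))
  vd <- tapply(depth[ints], tr[ints, "split var"], min)
  list(first_depth = stats::setNames(as.numeric(vd), names(vd)),
       nodes_at_depth = table(depth[ints]),
       max_depth = max(depth[ints]))
}

#' Fit a random forest on a binary gene-mutation matrix
#'
#' Wraps [randomForest::randomForest()] with a fixed seed and records, per
#' tree, the depth of each variable's first split (its "minimal depth") and
#' the number of split nodes per depth level. These records drive
#' [minimal_depth_select()]. OOB (out-of-bag) class-vote fractions are kept
#' as the discovery-set scores, preventing optimism in discovery-set ROC
#' evaluation.
#'
#' @param x a [gene_matrix()] (patients are taken from columns) or a
#'   patients-by-genes 0/1 matrix.
#' @param labels factor of two classes per patient; defaults to
#'   `factor(gm$cohort)` for a gene_matrix input.
#' @param seed integer seed; the fit is deterministic given it.
#' @param n_trees number of trees (default 1000).
#' @param positive label treated as the positive class for scores
#'   (default: last factor level).
#' @return object of class `crc_forest`.
#' @export
fit_forest <- function(x, labels = NULL, seed = 1L, n_trees = 1000L,
                       positive = NULL) {
  if (inherits(x, "gene_matrix")) {
    if (is.null(labels)) labels <- factor(x$cohort)
    x <- t(x$mat)
  }
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (min(table(labels)) < 2) stop("need >= 2 patients per class")
  if (is.null(positive)) positive <- levels(labels)[2]
  colnames(x) <- make.names(colnames(x))  # randomForest-safe names
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = n_trees)
  stats_list <- lapply(seq_len(n_trees), function(k) .tree_depth_stats(rf, k))
  p <- ncol(x)
  depth_sum <- rep(0, p)
  rel_sum <- rep(0, p)
  for (st in stats_list) {
    pen <- st$max_depth + 1
    d <- rep(pen, p)
    idx <- as.integer(names(st$first_depth))
    d[idx] <- st$first_depth
    depth_sum <- depth_sum + d
    rel_sum <- rel_sum + d / pen   # relative depth: penalty scales to 1
  }
  min_depth <- stats::setNames(depth_sum / n_trees, colnames(x))
  structure(list(
    rf = rf, seed = seed, n_trees = n_trees,
    genes = colnames(x), labels = labels, positive = positive,
    x = x,
    min_depth = min_depth,
    min_depth_rel = stats::setNames(rel_sum / n_trees, colnames(x)),
    tree_stats = lapply(stats_list, function(s)
      list(nodes_at_depth = s$nodes_at_depth, max_depth = s$max_depth)),
    oob_scores = rf$votes[, positive],
    oob_error = unname(rf$err.rate[n_trees, "OOB"])
  ), class = "crc_forest")
}

#' @export
print.crc_forest <- function(x, ...) {
  cat("random forest:", x$n_trees, "trees,", length(x$genes), "genes,",
      length(x$labels), "patients\n")
  cat(sprintf("  OOB error %.3f (positive class: %s)\n", x$oob_error,
              x$positive))
  invisible(x)
}

# Null distribution of a single uninformative variable's minimal depth in
# one observed tree: each of the n_d split nodes at depth d picks the
# variable with probability 1/p, independently; a variable never picked
# takes the penalty depth max_depth + 1.
.null_depth_probs <- function(nodes_at_depth, max_depth, p) {
  depths <- as.numeric(names(nodes_at_depth))
  miss <- (1 - 1 / p)^as.numeric(nodes_at_depth)
  surv <- cumprod(c(1, miss))
  probs <- surv[seq_along(depths)] * (1 - miss)
  list(values = c(depths, max_depth + 1),
       probs = c(probs, surv[length(surv)]))
}

#' Minimal-depth variable selection
#'
#' A variable's minimal depth in a tree is the depth of its first split;
#' small forest-averaged minimal depth indicates importance. Variables at
#' or below a threshold derived from the null distribution of minimal
#' depth for an uninformative variable are selected. Three threshold rules
#' are available:
#'
#' * `"permutation"` (default): the forest is refit `n_perm` times on
#'   label-permuted data and the per-variable mean relative minimal depths
#'   (depth scaled by each tree's penalty depth, so forests of different
#'   tree sizes are comparable) are pooled; the threshold is their `q`-th
#'   quantile. This null preserves the carrier-count structure of the
#'   matrix, so chance gene-label association is part of the null — the
#'   analytic rules below ignore it and run anti-conservative on
#'   gene-by-patient panels.
#' * `"mean"`: the mean of the analytic null of minimal depth in random
#'   recursive trees of the forest's observed sizes (each split node picks
#'   a given variable with probability 1/p; never picked costs the
#'   penalty depth).
#' * `"quantile"`: the `q`-th quantile of the Monte-Carlo null of the
#'   forest-averaged minimal depth — a stricter mapping of a `q`-level
#'   significance rule onto the same analytic null.
#'
#' @param model a [fit_forest()] result.
#' @param rule threshold rule (see Details).
#' @param q quantile level for the permutation and quantile rules.
#' @param n_perm label-permuted refits for the permutation rule.
#' @param n_null Monte Carlo replicates for the quantile rule.
#' @return list: `selected` (gene names), `threshold`, `depths`
#'   (per-variable mean minimal depth on the rule's scale), `rule`.
#' @export
minimal_depth_select <- function(model,
                                 rule = c("permutation", "mean", "quantile"),
                                 q = 0.05, n_perm = 3L, n_null = 2000L) {
  rule <- match.arg(rule)
  if (is.null(model$tree_stats)) stop("model lacks depth records")
  p <- length(model$genes)
  if (rule == "permutation") {
    if (is.null(model$x)) stop("model lacks the training matrix")
    pooled <- unlist(lapply(seq_len(n_perm), function(k) {
      set.seed(model$seed + 7919L * k)
      yk <- sample(model$labels)
      fit_forest(model$x, yk, seed = model$seed + 7919L * k,
                 n_trees = model$n_trees,
                 positive = model$positive)$min_depth_rel
    }))
    threshold <- unname(stats::quantile(pooled, q))
    sel <- names(model$min_depth_rel)[model$min_depth_rel <= threshold]
    return(list(selected = sel, threshold = threshold,
                depths = model$min_depth_rel, rule = rule))
  }
  nulls <- lapply(model$tree_stats, function(s)
    .null_depth_probs(s$nodes_at_depth, s$max_depth, p))
  if (rule == "mean") {
    per_tree_mean <- vapply(nulls, function(nl) sum(nl$values * nl$probs),
                            numeric(1))
    threshold <- mean(per_tree_mean)
  } else {
    set.seed(model$seed + 1709L)
    tot <- rep(0, n_null)
    for (nl in nulls)
      tot <- tot + sample(nl$values, n_null, replace = TRUE, prob = nl$probs)
    threshold <- unname(stats::quantile(tot / length(nulls), q))
  }
  sel <- names(model$min_depth)[model$min_depth <= threshold]
  list(selected = sel, threshold = threshold, depths = model$min_depth,
       rule = rule)
}

#' Refit the forest on a selected gene subset
#'
#' @param x data as in [fit_forest()].
#' @param selected non-empty character vector of gene names.
#' @inheritParams fit_forest
#' @return a `crc_forest` restricted to the selected genes.
#' @export
reduced_model <- function(x, selected, labels = NULL, seed = 1L,
                          n_trees = 1000L, positive = NULL) {
  if (!length(selected)) stop("empty gene selection")
  if (inherits(x, "gene_matrix")) {
    if (is.null(labels)) labels <- factor(x$cohort)
    x <- t(x$mat)
  }
  x <- as.matrix(x)
  colnames(x) <- make.names(colnames(x))
  selected <- make.names(selected)
  miss <- setdiff(selected, colnames(x))
  if (length(miss)) stop("selected genes absent from matrix: ",
                         paste(miss, collapse = ", "))
  fit_forest(x[, selected, drop = FALSE], labels, seed = seed,
             n_trees = n_trees, positive = positive)
}

# Rank-statistic AUC; ties contribute 0.5 via midranks. Equals the
# all-pairs concordance count.
.auc_rank <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) stop("evaluation set must contain both classes")
  r <- rank(scores)
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

# Area under the precision-recall curve by step integration over unique
# score thresholds (average precision).
.aucpr <- function(scores, is_pos) {
  np <- sum(is_pos)
  if (np == 0 || all(is_pos)) stop("evaluation set must contain both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- is_pos[o]
  # thresholds at the last index of each tied score block
  last_of_block <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last_of_block]
  fp <- cumsum(!y)[last_of_block]
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a fitted forest (AUC, AUCPR, OOB error)
#'
#' On the discovery set (`newdata = NULL`) scores are the OOB vote
#' fractions stored in the model; on a validation set they are plain vote
#' fractions from [predict()].
#'
#' @param model a `crc_forest`.
#' @param newdata optional validation data ([gene_matrix()] or
#'   patients-by-genes matrix covering the model's genes).
#' @param labels class labels for `newdata`.
#' @param dataset tag stored in the report.
#' @return object of class `eval_report`: `auc`, `aucpr`, `oob_error`
#'   (`NA` for validation sets), `dataset`.
#' @export
evaluate <- function(model, newdata = NULL, labels = NULL,
                     dataset = if (is.null(newdata)) "discovery" else "validation") {
  if (is.null(newdata)) {
    scores <- model$oob_scores
    is_pos <- model$labels == model$positive
    oob <- model$oob_error
  } else {
    if (inherits(newdata, "gene_matrix")) {
      if (is.null(labels)) labels <- factor(newdata$cohort)
      newdata <- t(newdata$mat)
    }
    newdata <- as.matrix(newdata)
    colnames(newdata) <- make.names(colnames(newdata))
    miss <- setdiff(model$genes, colnames(newdata))
    if (length(miss)) stop("newdata lacks model genes: ",
                           paste(miss, collapse = ", "))
    if (is.null(labels)) stop("labels required for validation data")
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) < 2) stop("evaluation set must contain both classes")
    scores <- stats::predict(model$rf,
                             newdata[, model$genes, drop = FALSE],
                             type = "prob")[, model$positive]
    is_pos <- labels == model$positive
    oob <- NA_real_
  }
  structure(list(auc = .auc_rank(scores, is_pos),
                 aucpr = .aucpr(scores, is_pos),
                 oob_error = oob, dataset = dataset,
                 scores = scores, is_pos = is_pos),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation (%s): AUC %.3f, AUCPR %.3f%s\n", x$dataset,
              x$auc, x$aucpr,
              if (!is.na(x$oob_error))
                sprintf(", OOB error %.3f", x$oob_error) else ""))
  invisible(x)
}
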