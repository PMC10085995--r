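#' Build a sample x feature matrix from enriched features
#'
#' Restricts proportion-stage abundance tables to the features selected by a
#' sphere model (the union of sphere member terms and of linked host species)
#' or to an explicit feature list. Three variants mirror the biome-classifier
#' experiment: GO terms only, species only, or both.
#'
#' @param tables named list with elements `terms` and/or `species`, each an
#'   [abundance_table()] at stage `"proportion"` sharing one sample set.
#' @param model a `sphere_model`, or a list with elements `term_ids` and
#'   `species_ids` giving explicit features.
#' @param features which feature sources to use: `"both"`, `"go"` or
#'   `"species"`.
#' @return object of class `feature_matrix`: matrix `x` (samples x
#'   features; a feature absent from a sample is 0), factor `y` of biome
#'   labels, and per-column `feature_type`.
#' @export
build_feature_matrix <- function(tables, model, features = c("both", "go", "species")) {
  features <- match.arg(features)
  term_ids <- species_ids <- character(0)
  if (inherits(model, "sphere_model")) {
    term_ids <- sort(unique(unlist(lapply(model$spheres, `[[`, "members"))))
    species_ids <- sort(unique(unlist(lapply(model$spheres, function(s)
      s$host_species$species_id))))
  } else if (is.list(model)) {
    term_ids <- sort(unique(as.character(model$term_ids %||% character(0))))
    species_ids <- sort(unique(as.character(model$species_ids %||% character(0))))
  } else {
    stop("`model` must be a sphere_model or a list of explicit feature ids")
  }
  if (features == "go") species_ids <- character(0)
  if (features == "species") term_ids <- character(0)
  blocks <- list()
  meta <- NULL
  add_block <- function(tab, ids, type) {
    if (length(ids) == 0 || is.null(tab)) return(NULL)
    stopifnot(inherits(tab, "abundance_table"))
    if (tab$stage != "proportion") stop("feature tables must be at stage 'proportion'")
    m <- matrix(0, nrow = ncol(tab$values), ncol = length(ids),
                dimnames = list(colnames(tab$values), ids))
    present <- intersect(ids, rownames(tab$values))
    m[, present] <- t(tab$values[present, , drop = FALSE])
    list(x = m, type = rep(type, length(ids)), meta = tab$meta)
  }
  b1 <- add_block(tables$terms, term_ids, "go_term")
  b2 <- add_block(tables$species, species_ids, "species")
  blocks <- Filter(Negate(is.null), list(b1, b2))
  if (length(blocks) == 0) stop("zero enriched features selected; nothing to train on")
  if (length(blocks) == 2) {
    if (!identical(rownames(blocks[[1]]$x), rownames(blocks[[2]]$x))) {
      stop("terms and species tables must share an identical sample set")
    }
  }
  x <- do.call(cbind, lapply(blocks, `[[`, "x"))
  meta <- blocks[[1]]$meta
  y <- factor(meta$biome)
  if (nlevels(y) < 2) stop("need >= 2 biome classes")
  structure(
    list(x = x, y = y, sample_ids = meta$sample_id,
         feature_type = unlist(lapply(blocks, `[[`, "type"))),
    class = "feature_matrix"
  )
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, keeping per-fold class counts within one sample.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

fit_forest <- function(x, y, trees, mtry, max_depth, seed) {
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = trees, mtry = mtry, max.depth = max_depth,
    probability = TRUE, num.threads = 1, seed = seed,
    respect.unordered.factors = TRUE
  )
}

predict_probs <- function(fit, x) {
  p <- stats::predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
  p
}

#' Stability selection over random-forest importance
#'
#' Repeatedly draws stratified half-samples, fits a forest, and records the
#' `top_q` features by impurity importance. Features whose selection
#' frequency reaches `threshold` are selected. Deterministic given `seed`.
#'
#' @param matrix a [build_feature_matrix()] result.
#' @param subsamples number of half-sample draws (>= 2; default 50).
#' @param top_q features kept per draw (must be < number of features;
#'   default 20).
#' @param threshold selection-frequency cutoff in (0, 1] (default 0.6).
#' @param trees trees per forest (default 100).
#' @param seed integer seed.
#' @return data.frame (feature, frequency, selected), ordered by decreasing
#'   frequency then feature id.
#' @export
stability_select <- function(matrix, subsamples = 50, top_q = 20, threshold = 0.6,
                             trees = 100, seed = 1) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (subsamples < 2) stop("subsamples must be >= 2")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  p <- ncol(matrix$x)
  if (top_q >= p) stop("top_q must be smaller than the number of features")
  seeds <- derive_seeds(seed, subsamples)
  hits <- stats::setNames(rep(0, p), colnames(matrix$x))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(subsamples)) {
      idx <- unlist(lapply(levels(matrix$y), function(cl) {
        cl_idx <- which(matrix$y == cl)
        sample(cl_idx, max(1, floor(length(cl_idx) / 2)))
      }))
      fit <- ranger::ranger(
        x = as.data.frame(matrix$x[idx, , drop = FALSE]),
        y = droplevels(matrix$y[idx]),
        num.trees = trees, importance = "impurity",
        num.threads = 1, seed = seeds[r]
      )
      imp <- fit$variable.importance
      top <- names(sort(imp, decreasing = TRUE))[seq_len(top_q)]
      hits[top] <- hits[top] + 1
    }
  })
  freq <- hits / subsamples
  out <- data.frame(feature = names(freq), frequency = unname(freq),
                    selected = unname(freq >= threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Train and evaluate the biome classifier
#'
#' Random forest with stratified k-fold cross-validation. Within each
#' training fold, an inner 3-fold grid search picks the tree depth
#' (unlimited, 8 or 16) and the features-per-split rule (`sqrt` or `log2`)
#' by inner accuracy. Out-of-fold class-probability estimates are pooled to
#' compute per-class one-vs-rest ROC/AUC plus micro-averaged (pooling all
#' sample x class decisions) and macro-averaged (unweighted mean over
#' classes) summaries; accuracy and F1 come from pooled out-of-fold hard
#' predictions. Fully seeded and reproducible.
#'
#' @param matrix a [build_feature_matrix()] result.
#' @param trees number of trees (default 100).
#' @param folds outer folds (default 10); every class needs >= `folds`
#'   samples.
#' @param seed integer seed.
#' @return object of class `classifier_report`.
#' @export
train_evaluate <- function(matrix, trees = 100, folds = 10, seed = 1) {
  stopifnot(inherits(matrix, "feature_matrix"))
  y <- matrix$y
  x <- matrix$x
  counts <- table(y)
  if (any(counts < folds)) {
    stop(sprintf("class '%s' has %d samples, fewer than %d folds; use fewer folds",
                 names(counts)[which.min(counts)], min(counts), folds))
  }
  classes <- levels(y)
  grid <- expand.grid(max_depth = c(0, 8, 16), mtry_rule = c("sqrt", "log2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mtry_of <- function(rule, p) max(1L, if (rule == "sqrt") floor(sqrt(p)) else floor(log2(p)))
  seeds <- derive_seeds(seed, folds * (nrow(grid) * 3 + 1) + 1)
  si <- 0
  next_seed <- function() { si <<- si + 1; seeds[si] }
  oof_prob <- matrix(NA_real_, nrow = length(y), ncol = length(classes),
                     dimnames = list(matrix$sample_ids, classes))
  chosen <- vector("list", folds)
  fold_of <- NULL
  withr::with_seed(as.integer(seed), {
    fold_of <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f)
      te <- which(fold_of == f)
      # inner 3-fold grid search on the training part
      inner <- stratified_folds(droplevels(y[tr]), 3)
      acc <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        correct <- 0
        for (inf in 1:3) {
          itr <- tr[inner != inf]; ite <- tr[inner == inf]
          fit <- fit_forest(x[itr, , drop = FALSE], droplevels(y[itr]), trees,
                            mtry_of(grid$mtry_rule[g], ncol(x)),
                            grid$max_depth[g], next_seed())
          pr <- predict_probs(fit, x[ite, , drop = FALSE])
          pred <- colnames(pr)[max.col(pr, ties.method = "first")]
          correct <- correct + sum(pred == as.character(y[ite]))
        }
        acc[g] <- correct / length(tr)
      }
      best <- which.max(acc) # first maximum: deterministic tie-break by grid order
      chosen[[f]] <- list(max_depth = grid$max_depth[best],
                          mtry_rule = grid$mtry_rule[best])
      fit <- fit_forest(x[tr, , drop = FALSE], droplevels(y[tr]), trees,
                        mtry_of(grid$mtry_rule[best], ncol(x)),
                        grid$max_depth[best], next_seed())
      pr <- predict_probs(fit, x[te, , drop = FALSE])
      oof_prob[te, colnames(pr)] <- pr
    }
  })
  pred <- factor(classes[max.col(oof_prob, ties.method = "first")], levels = classes)
  accuracy <- mean(pred == y)
  per_class <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & y == cl)
    fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    list(class = cl, precision = precision, recall = recall, f1 = f1,
         auc = auc_binary(y == cl, oof_prob[, cl]))
  })
  macro_f1 <- mean(vapply(per_class, `[[`, 0, "f1"))
  aucs <- vapply(per_class, `[[`, 0, "auc")
  micro_truth <- as.vector(vapply(classes, function(cl) y == cl, logical(length(y))))
  micro_score <- as.vector(oof_prob[, classes])
  # micro-averaged precision/recall in single-label multiclass both equal accuracy
  structure(
    list(
      classes = classes,
      accuracy = accuracy,
      per_class = per_class,
      macro_f1 = macro_f1,
      macro_auc = mean(aucs, na.rm = TRUE),
      micro_auc = auc_binary(micro_truth, micro_score),
      micro_precision = accuracy,
      micro_recall = accuracy,
      fold_assignments = fold_of,
      oof_predictions = data.frame(sample_id = matrix$sample_ids,
                                   truth = as.character(y),
                                   predicted = as.character(pred),
                                   stringsAsFactors = FALSE),
      parameters = list(trees = trees, folds = folds, seed = as.integer(seed),
                        grid = list(max_depth = c("unlimited", "8", "16"),
                                    mtry_rule = c("sqrt", "log2")),
                        chosen = chosen)
    ),
    class = "classifier_report"
  )
}

# One-vs-rest AUC; a constant score vector scores 0.5 by the tie convention.
auc_binary <- function(truth, score) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2) return(NA_real_)
  if (length(unique(score)) < 2) return(0.5)
  r <- suppressMessages(pROC::roc(response = truth, predictor = score,
                                  levels = c(FALSE, TRUE), direction = "<",
                                  quiet = TRUE))
  as.numeric(pROC::auc(r))
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: accuracy %.3f, macro-F1 %.3f, micro-AUC %.3f, macro-AUC %.3f\n",
              x$accuracy, x$macro_f1, x$micro_auc, x$macro_auc))
  for (pc in x$per_class) {
    cat(sprintf("  %-12s P %.3f R %.3f F1 %.3f AUC %s\n", pc$class, pc$precision,
                pc$recall, pc$f1,
                if (is.na(pc$auc)) "NA" else sprintf("%.3f", pc$auc)))
  }
  invisible(x)
}
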