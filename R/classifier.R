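# Feed-forward neural classifier: five-layer network (input, three hidden
# ReLU layers, output) trained with Adam on the five normalized
# sympathovagal features; binary AD detection or four-class stimulus
# discrimination.

#' Training configuration
#'
#' The network has five layers in total: an input layer (one neuron per
#' feature), three rectified-linear hidden layers, and an output layer (one
#' sigmoid neuron for the binary task; one softmax neuron per class for the
#' multiclass task). Data are split 70/15/15 into stratified train, test and
#' validation sets; 10-fold cross-validation gauges performance.
#'
#' @param hidden_layers neuron counts of the hidden layers.
#' @param task `"binary"` (AD vs non-AD) or `"multiclass"`.
#' @param train_frac,test_frac,val_frac stratified split fractions
#'   (must sum to 1).
#' @param cv_folds folds for cross-validation.
#' @param seed integer seed for shuffling and weight initialization.
#' @param max_epochs full-batch Adam epochs.
#' @param learning_rate Adam step size.
#' @param l2 L2 weight penalty.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) when a validation set is supplied.
#' @param class_weights use inverse-frequency class weights.
#' @return list of class `train_config`.
#' @export
train_config <- function(hidden_layers = c(32, 16, 8),
                         task = c("binary", "multiclass"),
                         train_frac = 0.70, test_frac = 0.15,
                         val_frac = 0.15, cv_folds = 10L, seed = 1L,
                         max_epochs = 300L, learning_rate = 0.01,
                         l2 = 1e-4, patience = 30L,
                         class_weights = FALSE) {
  task <- match.arg(task)
  if (abs(train_frac + test_frac + val_frac - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(hidden_layers = hidden_layers, task = task,
                 train_frac = train_frac, test_frac = test_frac,
                 val_frac = val_frac, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, l2 = l2,
                 patience = as.integer(patience),
                 class_weights = isTRUE(class_weights)),
            class = "train_config")
}

#' Stratified 70/15/15 split
#'
#' Exact partition into train/validation/test with per-class counts within
#' one window of exact stratification (largest-remainder allocation, so the
#' global sizes are exactly `round(n * frac)`), seeded and reproducible.
#'
#' @param labels class label per window.
#' @param config a [train_config()].
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_stratified <- function(labels, config = train_config()) {
  labels <- as.factor(labels)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < 3L))
    stop(sprintf("class '%s' has < 3 windows; cannot stratify into 3 sets",
                 names(counts)[which.min(counts)]), call. = FALSE)
  alloc <- function(class_n, frac, total) {
    ideal <- class_n * frac
    base <- floor(ideal)
    extra <- total - sum(base)
    if (extra > 0) {
      o <- order(-(ideal - base), -class_n)
      base[o[seq_len(extra)]] <- base[o[seq_len(extra)]] + 1L
    }
    base
  }
  n_train_tot <- round(n * config$train_frac)
  n_val_tot <- round(n * config$val_frac)
  tr_c <- alloc(as.numeric(counts), config$train_frac, n_train_tot)
  rem_c <- as.numeric(counts) - tr_c
  va_c <- pmin(rem_c, alloc(as.numeric(counts), config$val_frac, n_val_tot))
  # top up if caps bound any class
  short <- n_val_tot - sum(va_c)
  while (short > 0) {
    room <- which(rem_c - va_c > 0)
    va_c[room[1]] <- va_c[room[1]] + 1L
    short <- short - 1L
  }
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (ci in seq_along(counts)) {
    idx <- which(labels == names(counts)[ci])
    idx <- with_seed(derive_seed(config$seed, 77, ci), sample(idx))
    out$train <- c(out$train, idx[seq_len(tr_c[ci])])
    out$val <- c(out$val, idx[tr_c[ci] + seq_len(va_c[ci])])
    out$test <- c(out$test, idx[-seq_len(tr_c[ci] + va_c[ci])])
  }
  lapply(out, sort)
}

# ---- network internals -----------------------------------------------------

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(layer_sizes, seed) {
  with_seed(seed, {
    L <- length(layer_sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      W[[l]] <- matrix(rnorm(fan_in * layer_sizes[l + 1L],
                             sd = sqrt(2 / fan_in)),
                       fan_in, layer_sizes[l + 1L])
      b[[l]] <- rep(0, layer_sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, x, task) {
  L <- length(par$W)
  A <- list(x)
  Z <- vector("list", L)
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) relu(Z[[l]]) else Z[[l]]
  }
  out <- if (task == "binary") 1 / (1 + exp(-A[[L + 1L]])) else
    softmax_rows(A[[L + 1L]])
  list(A = A, Z = Z, out = out)
}

mlp_loss <- function(out, ytab, w, par, l2) {
  eps <- 1e-12
  ll <- if (ncol(out) == 1L) {
    -(ytab * log(out + eps) + (1 - ytab) * log(1 - out + eps))
  } else {
    -rowSums(ytab * log(out + eps))
  }
  mean(w * ll) + l2 * sum(vapply(par$W, function(m) sum(m^2), numeric(1)))
}

mlp_grad <- function(par, fw, ytab, w, l2, task) {
  L <- length(par$W)
  n <- nrow(ytab)
  dZ <- (fw$out - ytab) * (w / n)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], dZ) + 2 * l2 * par$W[[l]]
    gb[[l]] <- colSums(dZ)
    if (l > 1L) dZ <- (dZ %*% t(par$W[[l]])) * (fw$Z[[l - 1L]] > 0)
  }
  list(W = gW, b = gb)
}

#' Train the feed-forward AD classifier
#'
#' Full-batch Adam with He initialization; when a validation set is given,
#' training keeps the weights with the best validation loss and stops after
#' `patience` epochs without improvement.
#'
#' @param x numeric matrix of normalized features (rows = windows).
#' @param y class labels (factor or character). For the binary task the
#'   positive class is `positive`.
#' @param config a [train_config()].
#' @param x_val,y_val optional validation set for early stopping.
#' @param positive positive-class label for the binary task.
#' @return object of class `ad_mlp`.
#' @export
train_model <- function(x, y, config = train_config(), x_val = NULL,
                        y_val = NULL, positive = "ad") {
  x <- as.matrix(x)
  if (!all(is.finite(x))) {
    bad <- which(!apply(x, 1L, function(r) all(is.finite(r))))
    stop("non-finite feature values in windows: ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  y <- as.factor(y)
  if (config$task == "binary") {
    ytab <- matrix(as.numeric(y == positive), ncol = 1L)
    classes <- c(paste0("non_", positive), positive)
  } else {
    classes <- levels(y)
    ytab <- outer(y, classes, `==`) * 1
  }
  out_dim <- ncol(ytab)
  sizes <- c(ncol(x), config$hidden_layers, out_dim)
  par <- mlp_init(sizes, derive_seed(config$seed, 11))
  w <- rep(1, nrow(x))
  if (config$class_weights) {
    memb <- if (config$task == "binary") as.character(ytab[, 1L]) else
      as.character(y)
    cw <- length(memb) / (length(unique(memb)) * table(memb))
    w <- as.numeric(cw[memb])
  }
  has_val <- !is.null(x_val)
  if (has_val) {
    x_val <- as.matrix(x_val)
    yv <- as.factor(y_val)
    ytab_val <- if (config$task == "binary")
      matrix(as.numeric(yv == positive), ncol = 1L) else
        outer(yv, classes, `==`) * 1
  }
  # Adam state
  mW <- lapply(par$W, function(m) m * 0); vW <- mW
  mb <- lapply(par$b, function(v) v * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  best <- list(par = par, loss = Inf, epoch = 0L)
  stall <- 0L
  history <- numeric(0)
  for (ep in seq_len(config$max_epochs)) {
    fw <- mlp_forward(par, x, config$task)
    gr <- mlp_grad(par, fw, ytab, w, config$l2, config$task)
    for (l in seq_along(par$W)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gr$W[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gr$W[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gr$b[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gr$b[[l]]^2
      mh <- mW[[l]] / (1 - b1^ep); vh <- vW[[l]] / (1 - b2^ep)
      par$W[[l]] <- par$W[[l]] - lr * mh / (sqrt(vh) + eps)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    if (has_val) {
      fv <- mlp_forward(par, x_val, config$task)
      vloss <- mlp_loss(fv$out, ytab_val, rep(1, nrow(x_val)), par,
                        config$l2)
      history <- c(history, vloss)
      if (vloss < best$loss - 1e-7) {
        best <- list(par = par, loss = vloss, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  if (has_val && is.finite(best$loss)) par <- best$par
  structure(list(par = par, layer_sizes = sizes, task = config$task,
                 classes = classes, positive = positive,
                 feature_names = colnames(x), config = config,
                 val_history = history,
                 best_epoch = if (has_val) best$epoch else NA_integer_),
            class = "ad_mlp")
}

#' @export
print.ad_mlp <- function(x, ...) {
  cat(sprintf("<ad_mlp> %s, layers %s\n", x$task,
              paste(x$layer_sizes, collapse = "-")))
  invisible(x)
}

#' Predict from a trained classifier
#'
#' @param object an `ad_mlp`.
#' @param x feature matrix.
#' @param type `"prob"` for scores, `"class"` for hard labels (binary
#'   decision threshold 0.5; multiclass argmax).
#' @param ... unused.
#' @return matrix of class probabilities or character vector of labels.
#' @export
predict.ad_mlp <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  out <- mlp_forward(object$par, as.matrix(x), object$task)$out
  if (object$task == "binary") {
    p <- cbind(1 - out[, 1L], out[, 1L])
    colnames(p) <- object$classes
  } else {
    p <- out
    colnames(p) <- object$classes
  }
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

# ---- evaluation ------------------------------------------------------------

#' Metrics from a confusion matrix
#'
#' @param confusion square count matrix, rows = truth, columns = predicted.
#' @param positive name (or index) of the positive class for
#'   sensitivity/specificity/F1.
#' @return list: `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `per_class_precision`, `per_class_recall`.
#' @export
metrics_from_confusion <- function(confusion, positive = 2L) {
  confusion <- as.matrix(confusion)
  cls <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  pi <- if (is.character(positive)) match(positive, cls) else positive
  acc <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / colSums(confusion)
  tp <- confusion[pi, pi]
  fn <- sum(confusion[pi, ]) - tp
  fp <- sum(confusion[, pi]) - tp
  tn <- sum(confusion) - tp - fn - fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1,
       per_class_precision = setNames(precision, cls),
       per_class_recall = setNames(recall, cls))
}

#' Evaluate a trained classifier on a held-out set
#'
#' Reports accuracy, sensitivity (true-positive rate), specificity
#' (true-negative rate), F1, AUC-ROC (binary only), and the confusion
#' matrix. A single-class test set leaves sensitivity/specificity `NA` with
#' a warning rather than silently zero.
#'
#' @param model an `ad_mlp`.
#' @param x,y held-out features and labels (disjoint from training data).
#' @return list of class `eval_report`.
#' @export
evaluate <- function(model, x, y) {
  y <- as.character(y)
  if (model$task == "binary")
    y <- ifelse(y == model$positive, model$positive,
                paste0("non_", model$positive))
  pred <- predict(model, x, type = "class")
  cls <- model$classes
  confusion <- table(factor(y, levels = cls), factor(pred, levels = cls))
  confusion <- matrix(as.numeric(confusion), nrow = length(cls),
                      dimnames = list(truth = cls, predicted = cls))
  single <- length(unique(y)) < 2L
  if (single)
    warning("single-class test set: sensitivity/specificity undefined")
  m <- metrics_from_confusion(confusion,
                              positive = if (model$task == "binary")
                                model$positive else cls[1L])
  auc <- NA_real_
  if (model$task == "binary" && !single) {
    score <- predict(model, x, type = "prob")[, model$positive]
    r <- pROC::roc(response = y, predictor = score,
                   levels = c(paste0("non_", model$positive),
                              model$positive),
                   direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
  }
  structure(list(
    task = model$task,
    accuracy = m$accuracy,
    sensitivity = if (single) NA_real_ else m$sensitivity,
    specificity = if (single) NA_real_ else m$specificity,
    f1 = m$f1, auc_roc = auc, confusion = confusion,
    per_class_precision = m$per_class_precision,
    per_class_recall = m$per_class_recall,
    n = length(y)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: acc %.3f, sens %.3f, spec %.3f, F1 %.3f, AUC %s (n=%d)\n",
              x$task, x$accuracy, x$sensitivity, x$specificity, x$f1,
              if (is.na(x$auc_roc)) "-" else sprintf("%.3f", x$auc_roc),
              x$n))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' @param x feature matrix.
#' @param y labels.
#' @param config a [train_config()] (`cv_folds`, `seed`, network settings).
#' @param positive positive class for the binary task.
#' @return list: `cv_mean`, `cv_sd`, `fold_accuracy`, aggregate `confusion`,
#'   `per_class_recall`, `fold_assignment`.
#' @export
cross_validate <- function(x, y, config = train_config(), positive = "ad") {
  x <- as.matrix(x)
  y <- as.factor(y)
  k <- config$cv_folds
  if (any(table(y) < k))
    stop("need >= cv_folds windows per class", call. = FALSE)
  fold <- integer(length(y))
  for (ci in seq_along(levels(y))) {
    idx <- which(y == levels(y)[ci])
    idx <- with_seed(derive_seed(config$seed, 55, ci), sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  cls <- if (config$task == "binary")
    c(paste0("non_", positive), positive) else levels(y)
  agg <- matrix(0, length(cls), length(cls),
                dimnames = list(truth = cls, predicted = cls))
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 56, f)
    model <- train_model(x[tr, , drop = FALSE], y[tr], cfg,
                         positive = positive)
    rep_f <- suppressWarnings(
      evaluate(model, x[!tr, , drop = FALSE], y[!tr]))
    accs[f] <- rep_f$accuracy
    agg <- agg + rep_f$confusion
  }
  m <- metrics_from_confusion(agg, positive = cls[1L])
  list(cv_mean = mean(accs), cv_sd = sd(accs), fold_accuracy = accs,
       confusion = agg, per_class_recall = m$per_class_recall,
       fold_assignment = fold)
}

# ---- persistence -----------------------------------------------------------

#' Save / load a trained model as a JSON weight bundle
#'
#' @param model an `ad_mlp`.
#' @param path output JSON file.
#' @return `path` (save) or the restored `ad_mlp` (load).
#' @export
save_model <- function(model, path) {
  obj <- list(
    layer_sizes = model$layer_sizes, task = model$task,
    classes = model$classes, positive = model$positive,
    feature_names = model$feature_names,
    weights = lapply(model$par$W, function(m)
      list(dim = dim(m), values = as.numeric(m))),
    biases = model$par$b
  )
  write_json_file(obj, path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  W <- lapply(obj$weights, function(wl)
    matrix(as.numeric(unlist(wl$values)), as.integer(wl$dim[[1]]),
           as.integer(wl$dim[[2]])))
  b <- lapply(obj$biases, function(v) as.numeric(unlist(v)))
  structure(list(par = list(W = W, b = b),
                 layer_sizes = as.numeric(unlist(obj$layer_sizes)),
                 task = obj$task, classes = as.character(unlist(obj$classes)),
                 positive = obj$positive,
                 feature_names = as.character(unlist(obj$feature_names)),
                 config = NULL, val_history = NULL,
                 best_epoch = NA_integer_),
            class = "ad_mlp")
}
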