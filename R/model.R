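# Elastic-net logistic classification of insertion sites versus genomic
# controls. The penalized-likelihood model is
#   -loglik + lambda * (alpha * |beta|_1 + (1 - alpha)/2 * |beta|_2^2)
# fit by coordinate descent (glmnet); lambda is chosen on a 50-value grid
# spanning four decades below lambda_max at minimum cross-validated deviance.
# Features arrive min-max standardized to [0, 1]; no internal restandardization
# is applied so coefficients remain comparable across blocks.

#' Fit an elastic-net logistic classifier with cross-validation
#'
#' @param fm a `tn5_feature_matrix` (see [assemble_matrix()]).
#' @param alpha L1/L2 mixing parameter in \[0, 1\] (0.5 by default).
#' @param folds number of CV folds (10 by default, >= 2).
#' @param seed seed for the fold assignment.
#' @return a `tn5_fit`: named `coefficients` (incl. `(Intercept)`), `alpha`,
#'   `lambda`, `cv_accuracy` (prevalidated, threshold 0.5), `cv_metrics`
#'   (TP/TN/FP/FN), `col_info`, `bounds`, `folds`, `seed`.
#' @export
fit_elastic_net <- function(fm, alpha = 0.5, folds = 10L, seed = 1L) {
  stopifnot(inherits(fm, "tn5_feature_matrix"), folds >= 2,
            alpha >= 0, alpha <= 1)
  y <- fm$labels
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  x <- fm$x
  if (!inherits(x, "sparseMatrix") && any(!is.finite(x)))
    stop("non-finite feature values")
  n <- length(y)
  # fully degenerate design: intercept-only fit (majority-rate classifier)
  rng <- if (inherits(x, "sparseMatrix")) range(x@x, 0) else range(x)
  if (diff(rng) == 0) {
    beta <- stats::setNames(c(stats::qlogis(mean(y)), rep(0, ncol(x))),
                            c("(Intercept)", colnames(x)))
    pred <- rep(as.integer(mean(y) > 0.5), n)
    cm <- .confusion(y, pred)
    return(structure(list(coefficients = beta, alpha = alpha, lambda = Inf,
                          cv_accuracy = cm$accuracy, cv_metrics = cm,
                          col_info = fm$col_info, bounds = fm$bounds,
                          folds = folds, seed = seed),
                     class = "tn5_fit"))
  }
  foldid <- with_seed(child_seed(seed, "folds"),
                      sample(rep_len(seq_len(folds), n)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          foldid = foldid, type.measure = "deviance",
                          nlambda = 50, lambda.min.ratio = 1e-4,
                          standardize = FALSE, keep = TRUE)
  i_min <- which.min(cv$cvm)
  lambda <- cv$lambda[i_min]
  link <- cv$fit.preval[, i_min]
  pred <- as.integer(link > 0)  # link 0 == probability 0.5
  cm <- .confusion(y, pred)
  beta <- as.numeric(stats::coef(cv$glmnet.fit, s = lambda))
  names(beta) <- c("(Intercept)", colnames(x))
  structure(list(coefficients = beta, alpha = alpha, lambda = lambda,
                 cv_accuracy = cm$accuracy, cv_metrics = cm,
                 col_info = fm$col_info, bounds = fm$bounds,
                 folds = folds, seed = seed),
            class = "tn5_fit")
}

.confusion <- function(y, pred) {
  TP <- sum(pred == 1 & y == 1)
  TN <- sum(pred == 0 & y == 0)
  FP <- sum(pred == 1 & y == 0)
  FN <- sum(pred == 0 & y == 1)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       accuracy = (TP + TN) / (TP + TN + FP + FN))
}

#' @export
print.tn5_fit <- function(x, ...) {
  cat("tn5_fit: alpha", x$alpha, "lambda", signif(x$lambda, 4),
      "CV accuracy", round(x$cv_accuracy, 4), "\n")
  invisible(x)
}

#' Predicted insertion probability
#' @param object a `tn5_fit`.
#' @param newdata a `tn5_feature_matrix` assembled with the fit's bounds.
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.tn5_fit <- function(object, newdata, ...) {
  x <- newdata$x
  if (!identical(colnames(x), names(object$coefficients)[-1]))
    stop("feature columns do not match the fitted model")
  eta <- as.numeric(x %*% object$coefficients[-1]) + object$coefficients[1]
  stats::plogis(eta)
}

#' Evaluate a fit on a feature matrix
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)` with predictions thresholded
#' at probability 0.5. Held-out matrices must be assembled with the training
#' standardization bounds.
#'
#' @param fit a `tn5_fit`.
#' @param fm a `tn5_feature_matrix`.
#' @return list `TP`, `TN`, `FP`, `FN`, `accuracy`.
#' @export
evaluate <- function(fit, fm) {
  p <- predict(fit, fm)
  .confusion(fm$labels, as.integer(p > 0.5))
}

#' Compare classification accuracy across feature-vector designs
#'
#' Fits one CV model per named design on the same sites and controls,
#' including shuffled-sequence and shuffled-shape-table negative controls, and
#' reports CV accuracy per design.
#'
#' @param sites,controls site data frames shared by all designs.
#' @param genome a `tn5_genome`.
#' @param sets named list; each element is a list with `blocks` and optional
#'   `pwm`, `table`, `meth`, `shuffle_sequences`.
#' @param window window width.
#' @param alpha,folds,seed passed to [fit_elastic_net()].
#' @return data frame (`set`, `cv_accuracy`), ordered as given; fits attached
#'   as attribute `fits`.
#' @export
compare_vector_sets <- function(sites, controls, genome, sets, window = 51L,
                                alpha = 0.5, folds = 10L, seed = 1L) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  fits <- list()
  acc <- numeric(length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    fm <- assemble_matrix(sites, controls, genome,
                          blocks = s$blocks, pwm = s$pwm, table = s$table,
                          meth = s$meth, window = window,
                          shuffle_sequences = isTRUE(s$shuffle_sequences),
                          seed = seed)
    fits[[names(sets)[i]]] <- fit_elastic_net(fm, alpha = alpha,
                                              folds = folds, seed = seed)
    acc[i] <- fits[[i]]$cv_accuracy
  }
  out <- data.frame(set = names(sets), cv_accuracy = acc,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}

#' Cross-sample generalization matrix
#'
#' Trains on 70% of each sample's sites/controls and evaluates on the 30%
#' held-out split of every sample (including its own), applying the training
#' standardization bounds to the held-out encodings.
#'
#' @param samples named list; each element a list with `sites` and `controls`.
#' @param genome a `tn5_genome`.
#' @param blocks,pwm,table,window encoding arguments (see
#'   [assemble_matrix()]).
#' @param split training fraction (0.7 by default).
#' @param alpha,folds,seed model arguments.
#' @return numeric accuracy matrix (train sample x test sample).
#' @export
cross_sample_validation <- function(samples, genome, blocks = c("kmer2"),
                                    pwm = NULL, table = NULL, window = 51L,
                                    split = 0.7, alpha = 0.5, folds = 10L,
                                    seed = 1L) {
  stopifnot(length(samples) >= 2, !is.null(names(samples)))
  parts <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    n1 <- nrow(s$sites); n0 <- nrow(s$controls)
    if (min(n1, n0) < 10) {
      warning("sample ", names(samples)[i], " too small for splitting")
      return(NULL)
    }
    with_seed(child_seed(seed + i, "split"), {
      i1 <- sample.int(n1, floor(split * n1))
      i0 <- sample.int(n0, floor(split * n0))
      list(train = list(sites = s$sites[i1, , drop = FALSE],
                        controls = s$controls[i0, , drop = FALSE]),
           test = list(sites = s$sites[-i1, , drop = FALSE],
                       controls = s$controls[-i0, , drop = FALSE]))
    })
  })
  names(parts) <- names(samples)
  ok <- !vapply(parts, is.null, logical(1))
  parts <- parts[ok]
  nms <- names(parts)
  acc <- matrix(NA_real_, length(parts), length(parts),
                dimnames = list(train = nms, test = nms))
  for (i in seq_along(parts)) {
    tr <- parts[[i]]$train
    fm_tr <- assemble_matrix(tr$sites, tr$controls, genome, blocks = blocks,
                             pwm = pwm, table = table, window = window,
                             seed = seed)
    fit <- fit_elastic_net(fm_tr, alpha = alpha, folds = folds, seed = seed)
    for (j in seq_along(parts)) {
      te <- parts[[j]]$test
      fm_te <- assemble_matrix(te$sites, te$controls, genome, blocks = blocks,
                               pwm = pwm, table = table, window = window,
                               seed = seed, bounds = fm_tr$bounds)
      acc[i, j] <- evaluate(fit, fm_te)$accuracy
    }
  }
  acc
}

#' Coefficient importance map
#'
#' Reshapes fitted coefficients to a parameter x window-position matrix of
#' absolute-coefficient sums; total parameter importance and position
#' importance are its row and column sums. Comparable across parameters
#' because features were standardized to [0, 1].
#'
#' @param fit a `tn5_fit`.
#' @return a `tn5_importance`: `matrix`, `row_importance`,
#'   `column_importance`.
#' @export
importance_map <- function(fit) {
  ci <- fit$col_info
  beta <- abs(fit$coefficients[-1])
  params <- unique(ci$param)
  positions <- sort(unique(ci$position))
  m <- matrix(NA_real_, length(params), length(positions),
              dimnames = list(params, positions))
  agg <- rowsum(beta, paste(ci$param, ci$position, sep = "\r"))
  keys <- strsplit(rownames(agg), "\r", fixed = TRUE)
  for (i in seq_along(keys)) {
    m[keys[[i]][1], keys[[i]][2]] <- agg[i, 1]
  }
  structure(list(matrix = m,
                 row_importance = rowSums(m, na.rm = TRUE),
                 column_importance = colSums(m, na.rm = TRUE)),
            class = "tn5_importance")
}

#' @export
print.tn5_importance <- function(x, ...) {
  cat("tn5_importance:", nrow(x$matrix), "parameters x", ncol(x$matrix),
      "positions; top parameter:",
      names(sort(x$row_importance, decreasing = TRUE))[1], "\n")
  invisible(x)
}

#' Serialize a fit as structured text
#' @param fit a `tn5_fit`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  hdr <- sprintf("# alpha=%g lambda=%g folds=%d seed=%d cv_accuracy=%g",
                 fit$alpha, fit$lambda, fit$folds, fit$seed, fit$cv_accuracy)
  df <- data.frame(feature = names(fit$coefficients),
                   coefficient = as.numeric(fit$coefficients))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
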