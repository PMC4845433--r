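# Weighted sparse representation classification (WSRC).
#
# A test vector y is reconstructed as a sparse linear combination of the
# training columns: alpha-hat = argmin ||W alpha||_1 subject to
# ||y - X alpha||_2 <= epsilon, where diag(W) holds the Gaussian kernel
# similarities between y and each training sample (the locality weights).
# The sample is assigned to the class whose coefficients alone reconstruct
# it with the smallest Euclidean residual.

#' Gaussian locality weights
#'
#' Kernel similarity between a test vector and every training sample:
#' `w_i = exp(-||y - x_i||^2 / (2 sigma^2))`, in (0, 1], equal to 1 exactly
#' when `y == x_i`. Weights are floored at `exp(-700)` so that extreme
#' distances never underflow to an exact zero (the l1 weights must stay
#' positive).
#'
#' @param y Numeric test vector (length m).
#' @param x Numeric training matrix, samples in rows (n x m).
#' @param sigma Kernel width, > 0; default 1.5.
#' @return Numeric vector of n positive weights.
#' @export
gaussian_weights <- function(y, x, sigma = 1.5) {
  stopifnot(sigma > 0)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (length(y) != ncol(x)) {
    stop(sprintf("dimension mismatch: y has length %d, training samples have %d features",
                 length(y), ncol(x)))
  }
  d2 <- rowSums(sweep(x, 2L, y)^2)
  exp(pmax(-d2 / (2 * sigma^2), -700))
}

#' Solve the weighted l1 reconstruction problem
#'
#' Finds `argmin ||W alpha||_1 subject to ||y - X alpha||_2 <= epsilon` for a
#' diagonal weight matrix W with positive entries, by the lasso homotopy
#' (LARS with drops) on the transformed variables `beta = W alpha`: the
#' exact piecewise-linear solution path of the equivalent penalized problem
#' is tracked from the empty model downwards and stopped exactly where the
#' residual norm first reaches epsilon (the crossing inside a path segment
#' is solved in closed form). This is the standard solver family of the
#' sparse-representation classification literature, and — unlike penalized
#' approximations with a shrinking penalty — it resolves the weighted
#' l1-minimal reconstruction even when epsilon is far below the data scale.
#'
#' When epsilon is smaller than the least-squares residual of y on the
#' training span, the constraint is infeasible; the path then terminates at
#' its minimum-residual end and that terminal solution is returned with
#' `feasible = FALSE` and a warning, so a noisy query degrades gracefully
#' instead of aborting.
#'
#' Weights are used relatively: they are rescaled to a maximum of 1 and
#' floored at 1e-100 of the largest, since a column more than a hundred
#' orders of magnitude cheaper than another is already effectively
#' unpenalized and more extreme ratios have no numerical meaning.
#'
#' @param x Training matrix, samples in rows (n x m).
#' @param y Test vector (length m).
#' @param weights Positive l1 weight per training sample (length n); default
#'   unweighted.
#' @param epsilon Reconstruction tolerance, > 0.
#' @param max_steps Cap on homotopy path steps; default `10 * nrow(x) + 100`.
#' @param ridge Relative diagonal regularization of the active-set Gram
#'   system, guarding the direction solve on near-collinear designs;
#'   default 1e-10.
#' @param warn_infeasible Emit a warning when the constraint cannot be met;
#'   default TRUE.
#' @return List with `alpha` (length n), `lambda` (the penalty level at the
#'   stopping point, on the scale of the original weights), `residual`
#'   (`||y - X alpha||`), `objective` (`sum(weights * |alpha|)`), `feasible`,
#'   and `iterations` (path steps taken).
#' @export
solve_weighted_l1 <- function(x, y, weights = NULL, epsilon = 5e-5,
                              max_steps = NULL, ridge = 1e-10,
                              warn_infeasible = TRUE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n <- nrow(x); m <- ncol(x)
  if (length(y) != m) stop("dimension mismatch between x and y")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length must equal nrow(x)")
  if (any(weights <= 0) || anyNA(weights)) stop("all l1 weights must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (is.null(max_steps)) max_steps <- 10L * n + 100L

  w_max <- max(weights)
  w_eff <- pmax(weights / w_max, 1e-100)
  B <- x / w_eff                     # beta = w_eff * alpha
  fit <- .homotopy_cpp(B, as.numeric(y), epsilon, as.integer(max_steps),
                       ridge)
  alpha <- as.numeric(fit$beta) / w_eff
  if (!fit$feasible && warn_infeasible) {
    warning(sprintf(
      "reconstruction constraint infeasible (best residual %.3g > epsilon %.3g); returning the minimum-residual path solution",
      fit$residual, epsilon))
  }
  list(alpha = alpha,
       lambda = fit$lambda / w_max,
       residual = fit$residual,
       objective = sum(weights * abs(alpha)),
       feasible = fit$feasible,
       iterations = fit$steps)
}

#' Per-class reconstruction residuals
#'
#' For each class c, zeroes every coefficient outside class c and reports the
#' Euclidean residual `r_c = ||y - X delta_c(alpha)||`.
#'
#' @param x Training matrix (samples in rows).
#' @param y Test vector.
#' @param alpha Sparse coefficient vector, one per training sample.
#' @param labels Class label per training sample.
#' @return Named numeric vector of residuals, one per class level (sorted).
#' @export
class_residuals <- function(x, y, alpha, labels) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  stopifnot(length(alpha) == nrow(x), length(labels) == nrow(x))
  lev <- sort(unique(labels))
  res <- vapply(lev, function(cl) {
    a_c <- ifelse(labels == cl, alpha, 0)
    sqrt(sum((y - as.numeric(crossprod(x, a_c)))^2))
  }, numeric(1))
  names(res) <- as.character(lev)
  res
}

#' Fit (assemble) a weighted sparse representation classifier
#'
#' WSRC is instance-based: fitting stores the training matrix, labels and
#' hyperparameters; all computation happens at prediction time.
#'
#' @param x Numeric training matrix, samples in rows.
#' @param labels Class label per row (any two or more classes).
#' @param sigma Gaussian kernel width for the locality weights; default 1.5.
#' @param epsilon Reconstruction tolerance of the l1 problem; default 5e-5.
#' @param weight_mode `"inverse_similarity"` (default) penalizes each
#'   training sample by the reciprocal of its Gaussian kernel similarity to
#'   the query, so distant samples are expensive and the reconstruction
#'   prefers the query's neighborhood — the locality principle the weighted
#'   classifier is built on. `"similarity"` places the similarities
#'   themselves on the penalty (the literal published form), which penalizes
#'   near samples more and inverts predictions on well-separated data; it is
#'   retained for comparison.
#' @param normalize_columns Scale every training sample to unit Euclidean
#'   norm (and test samples at prediction time), as is common in the sparse
#'   representation literature; default FALSE.
#' @return Object of class `"wsrc"`.
#' @export
wsrc_fit <- function(x, labels, sigma = 1.5, epsilon = 5e-5,
                     weight_mode = c("inverse_similarity", "similarity"),
                     normalize_columns = FALSE) {
  weight_mode <- match.arg(weight_mode)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need at least 2 training samples")
  if (length(labels) != nrow(x)) stop("labels length must match rows of x")
  if (anyNA(x) || anyNA(labels)) stop("missing values are not supported")
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("training data must contain at least 2 classes")
  if (sigma <= 0 || epsilon <= 0) stop("sigma and epsilon must be > 0")
  if (normalize_columns) {
    scales <- sqrt(rowSums(x^2))
    if (any(scales == 0)) stop("cannot normalize an all-zero training sample")
    x <- x / scales
  }
  structure(list(
    x = x, labels = labels, levels = lev,
    sigma = sigma, epsilon = epsilon,
    weight_mode = weight_mode, normalize_columns = normalize_columns
  ), class = "wsrc")
}

#' @export
print.wsrc <- function(x, ...) {
  cat("Weighted sparse representation classifier\n")
  cat(sprintf("  training samples: %d (%s)\n", nrow(x$x),
              paste(sprintf("class %s: %d", x$levels,
                            tabulate(match(x$labels, x$levels))),
                    collapse = ", ")))
  cat(sprintf("  features: %d\n", ncol(x$x)))
  cat(sprintf("  sigma = %g, epsilon = %g, weight_mode = %s, normalize_columns = %s\n",
              x$sigma, x$epsilon, x$weight_mode, x$normalize_columns))
  invisible(x)
}

#' Predict interaction classes with a WSRC model
#'
#' For each query: computes Gaussian locality weights against the training
#' set, solves the weighted l1 reconstruction, and assigns the class with the
#' minimum per-class residual (ties broken toward the lowest class label).
#' The continuous decision score for a 2-class model is the residual margin
#' `r_first - r_second` of the two class levels — for 0/1 PPI labels this is
#' `r_0 - r_1`, larger meaning more likely interacting.
#'
#' @param object A `"wsrc"` model.
#' @param newdata Numeric matrix of query samples in rows (or one vector).
#' @param ... Unused.
#' @return `data.frame` with one row per query: `class`, one `r_<level>`
#'   residual column per class, `feasible` (whether the epsilon constraint
#'   could be met), and `score` (2-class models only).
#' @export
predict.wsrc <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) {
    return(data.frame(class = object$levels[0]))
  }
  if (ncol(newdata) != ncol(object$x)) {
    stop(sprintf("query has %d features; model expects %d",
                 ncol(newdata), ncol(object$x)))
  }
  lev <- object$levels
  n_infeasible <- 0L
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    y <- as.numeric(newdata[i, ])
    if (object$normalize_columns) {
      ny <- sqrt(sum(y^2))
      if (ny > 0) y <- y / ny
    }
    w <- gaussian_weights(y, object$x, object$sigma)
    if (object$weight_mode == "inverse_similarity") w <- 1 / w
    sol <- withCallingHandlers(
      solve_weighted_l1(object$x, y, weights = w, epsilon = object$epsilon),
      warning = function(cnd) {
        n_infeasible <<- n_infeasible + 1L
        invokeRestart("muffleWarning")
      })
    r <- class_residuals(object$x, y, sol$alpha, object$labels)
    # which.min returns the first minimum, i.e. the lowest class level on ties
    list(residuals = r, cls_idx = which.min(r), feasible = sol$feasible)
  })
  res_mat <- do.call(rbind, lapply(rows, `[[`, "residuals"))
  colnames(res_mat) <- paste0("r_", lev)
  out <- data.frame(
    class = lev[vapply(rows, `[[`, integer(1), "cls_idx")],
    res_mat,
    feasible = vapply(rows, `[[`, logical(1), "feasible"),
    stringsAsFactors = FALSE
  )
  if (length(lev) == 2L) out$score <- res_mat[, 1L] - res_mat[, 2L]
  if (n_infeasible > 0L) {
    warning(sprintf(
      "epsilon constraint infeasible for %d of %d queries; minimum-residual solutions used",
      n_infeasible, nrow(newdata)))
  }
  rownames(out) <- rownames(newdata)
  out
}

#' Save / load a WSRC model as a flat text archive
#'
#' The model is stored as three plain-text files in a directory: the feature
#' matrix (`x.csv`), the labels (`labels.csv`) and the hyperparameters
#' (`params.json`).
#'
#' @param model A `"wsrc"` object.
#' @param dir Directory to create/populate.
#' @return `wsrc_save` invisibly returns `dir`; `wsrc_load` returns the
#'   restored `"wsrc"` model.
#' @export
wsrc_save <- function(model, dir) {
  stopifnot(inherits(model, "wsrc"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(model$x, file.path(dir, "x.csv"))
  utils::write.csv(data.frame(label = model$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(sigma = model$sigma, epsilon = model$epsilon,
         weight_mode = model$weight_mode,
         normalize_columns = model$normalize_columns),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname wsrc_save
#' @export
wsrc_load <- function(dir) {
  x <- read_feature_matrix(file.path(dir, "x.csv"))$x
  labels <- utils::read.csv(file.path(dir, "labels.csv"))$label
  p <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  wsrc_fit(x, labels, sigma = as.numeric(p$sigma),
           epsilon = as.numeric(p$epsilon),
           weight_mode = p$weight_mode,
           normalize_columns = isTRUE(p$normalize_columns))
}
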