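#' Parameters for the FARKA estimator
#'
#' @param alignment_space A [mean_spec()] choosing the centroid space for
#'   per-subject alignment, or `"none"` to skip alignment (ablation).
#' @param kernel A [kernel_spec()].
#' @param mu Damping factor for the spectrum QP, `>= 1`. `1.5` is the value
#'   at which cross-subject accuracy peaks in the reference experiments.
#' @param eta SVM penalty (the `C` of a soft-margin SVM), `> 0`; default 10.
#' @param r_max Maximum retained eigen-system rank (`NULL` = `min(n_s, n_t)`).
#' @param train_on `"reconstructed"` trains the SVM on the adapted source
#'   block `K_s_tilde` (default); `"actual"` trains on the raw `K_s`.
#' @return An object of class `farka_params`.
#' @examples
#' farka_params(mu = 2, eta = 5)
#' @export
farka_params <- function(alignment_space = mean_spec("riemannian"),
                         kernel = kernel_spec("rbf"),
                         mu = 1.5, eta = 10, r_max = NULL,
                         train_on = c("reconstructed", "actual")) {
  train_on <- match.arg(train_on)
  if (!identical(alignment_space, "none")) {
    stopifnot(inherits(alignment_space, "mean_spec"))
  }
  stopifnot(inherits(kernel, "kernel_spec"),
            is.numeric(mu), mu >= 1, is.numeric(eta), eta > 0)
  structure(
    list(alignment_space = alignment_space, kernel = kernel, mu = mu,
         eta = eta, r_max = r_max, train_on = train_on),
    class = "farka_params"
  )
}

#' @export
print.farka_params <- function(x, ...) {
  al <- if (identical(x$alignment_space, "none")) "none" else x$alignment_space$space
  cat(sprintf("<farka_params> align = %s, kernel = %s, mu = %g, eta = %g, train_on = %s\n",
              al, x$kernel$family, x$mu, x$eta, x$train_on))
  invisible(x)
}

# clip tiny negative eigenvalues so the Gram matrix fed to the SVM is PSD
.psd_clip <- function(K) {
  e <- .sym_eig(K)
  if (e$values[length(e$values)] >= 0) return(.symmetrize(K))
  v <- pmax(e$values, 0)
  .symmetrize(e$vectors %*% (v * t(e$vectors)))
}

#' Pool several subjects' tangent features into one field
#'
#' Row-binds feature matrices and concatenates labels, e.g. to form the
#' multi-source field of an M2S task. All sets must share the feature
#' dimension and weighting.
#'
#' @param feature_list A list of [tangent_features()] objects.
#' @param subject_id Identifier for the pooled set.
#' @return A [tangent_features()] object.
#' @export
pool_features <- function(feature_list, subject_id = "pooled") {
  stopifnot(is.list(feature_list), length(feature_list) >= 1L,
            all(vapply(feature_list, inherits, logical(1), "tangent_features")))
  dims <- vapply(feature_list, function(f) ncol(f$vectors), integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all feature sets must share the feature dimension", call. = FALSE)
  }
  tangent_features(
    subject_id,
    do.call(rbind, lapply(feature_list, `[[`, "vectors")),
    unlist(lapply(feature_list, `[[`, "labels")),
    feature_list[[1]]$reference,
    feature_list[[1]]$weighting
  )
}

#' Fit the FARKA estimator
#'
#' Runs knowledge kernel adaptation between the labelled source field and
#' the unlabelled target field, then trains a binary soft-margin SVM on the
#' source block of the field-agnostic kernel (the adapted `K_s_tilde` by
#' default). The fit is fully deterministic given its inputs.
#'
#' Labels are mapped internally to -1/+1 with the smaller of the two input
#' labels as -1; prediction applies the learned dual coefficients to the
#' target-source cross block of the union kernel and thresholds the decision
#' value at zero, ties going to the positive (larger-label) class.
#'
#' @param source A [tangent_features()] object (or list of them, pooled)
#'   with exactly two classes.
#' @param target A [tangent_features()] object; its labels, if any, are
#'   ignored at fit time.
#' @param params A [farka_params()] (`alignment_space` is not consulted
#'   here: alignment happens upstream, see [run_plan()]).
#' @return An object of class `farka_model`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40, -1), 10), matrix(rnorm(40, 1), 10))
#' f <- tangent_features("s", X, rep(1:2, each = 10), diag(4))
#' m <- farka_fit(f, f, farka_params(kernel = kernel_spec("linear"), mu = 1))
#' mean(predict(m) == f$labels)
#' @export
farka_fit <- function(source, target, params = farka_params()) {
  if (is.list(source) && !inherits(source, "tangent_features")) {
    source <- pool_features(source)
  }
  stopifnot(inherits(source, "tangent_features"),
            inherits(target, "tangent_features"),
            inherits(params, "farka_params"))
  if (nrow(target$vectors) == 0L) stop("target field is empty", call. = FALSE)
  if (ncol(source$vectors) != ncol(target$vectors)) {
    stop("source and target feature dimensions differ", call. = FALSE)
  }
  classes <- sort(unique(source$labels))
  if (length(classes) != 2L) {
    stop(sprintf("source field must contain exactly 2 classes (got %d)",
                 length(classes)), call. = FALSE)
  }

  bundle <- kka(source$vectors, target$vectors, kernel = params$kernel,
                mu = params$mu, r_max = params$r_max)

  K_train <- if (params$train_on == "reconstructed") bundle$K_s_tilde
             else bundle$K_s
  K_train <- .psd_clip(K_train)

  # +1 = larger label, -1 = smaller label
  ypm <- ifelse(source$labels == classes[2], 1, -1)
  y <- factor(source$labels, levels = classes)
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K_train), y,
                     type = "C-svc", C = params$eta)
  sv <- kernlab::SVindex(m)
  coefs <- unlist(kernlab::coef(m))
  b0 <- kernlab::b(m)
  theta_y <- numeric(length(ypm))
  theta_y[sv] <- coefs
  # orient kernlab's internal label coding to ours: decision > 0 <=> +1 class
  d_train <- drop(K_train %*% theta_y) - b0
  orient <- if (sum(d_train * ypm) >= 0) 1 else -1
  theta_y <- orient * theta_y
  intercept <- -orient * b0

  structure(
    list(theta_y = theta_y, b = intercept, classes = classes,
         bundle = bundle, params = params,
         source_labels = source$labels,
         n_s = bundle$n_s, n_t = bundle$n_t,
         n_support = length(sv),
         source_id = source$subject_id, target_id = target$subject_id),
    class = "farka_model"
  )
}

#' @export
print.farka_model <- function(x, ...) {
  cat(sprintf("<farka_model> %s -> %s: n_s = %d, n_t = %d, %d support vectors, rank %d\n",
              x$source_id, x$target_id, x$n_s, x$n_t, x$n_support,
              length(x$bundle$delta_star)))
  invisible(x)
}

#' Decision values for the target field
#'
#' The target-row by source-column block of the field-agnostic union kernel
#' applied to the signed dual coefficients, plus the intercept.
#'
#' @param model A fitted `farka_model`.
#' @return Numeric vector of length `n_t`; positive values vote for the
#'   larger class label.
#' @export
decision_values <- function(model) {
  stopifnot(inherits(model, "farka_model"))
  n_s <- model$n_s
  K_ts <- model$bundle$K_union[n_s + seq_len(model$n_t), seq_len(n_s),
                               drop = FALSE]
  drop(K_ts %*% model$theta_y) + model$b
}

#' Predict target-field labels
#'
#' @param object A fitted `farka_model`.
#' @param ... Unused.
#' @return Integer labels of length `n_t`, in the target field's epoch
#'   order. Decision values of exactly zero go to the larger class label.
#' @method predict farka_model
#' @export
predict.farka_model <- function(object, ...) {
  d <- decision_values(object)
  ifelse(d >= 0, object$classes[2], object$classes[1])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the dual solution of a fitted FARKA model
#'
#' @param x A `farka_model`.
#' @param ... Unused.
#' @return A tibble with one row per source epoch: `epoch`, `label`,
#'   `dual_coef` (signed alpha * y), `support_vector`.
#' @export
tidy.farka_model <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$theta_y),
    label = x$source_labels,
    dual_coef = x$theta_y,
    support_vector = x$theta_y != 0
  )
}

#' One-row model summary
#'
#' @param x A `farka_model`.
#' @param ... Unused.
#' @return A tibble with `n_s`, `n_t`, `n_support`, `rank`, `mu`, `eta`,
#'   `kernel`, `gamma`, `train_on`.
#' @export
glance.farka_model <- function(x, ...) {
  tibble::tibble(
    n_s = x$n_s, n_t = x$n_t, n_support = x$n_support,
    rank = length(x$bundle$delta_star),
    mu = x$params$mu, eta = x$params$eta,
    kernel = x$params$kernel$family,
    gamma = if (x$params$kernel$family == "linear") NA_real_
            else x$bundle$kernel$gamma,
    train_on = x$params$train_on
  )
}

#' Classification accuracy
#'
#' Fraction of exact matches between predicted and true labels.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return A scalar in `[0, 1]`.
#' @examples
#' accuracy_score(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
accuracy_score <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have the same length", call. = FALSE)
  }
  mean(predicted == truth)
}
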