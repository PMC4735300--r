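#' Train an RBF-kernel regression SVM on a descriptor subspace
#'
#' Fits an epsilon-regression support vector machine with a radial basis
#' function kernel (via e1071/libsvm) to per-molecule activity values in the
#' selected, scaled descriptor subspace. The returned model stores its own
#' support-vector expansion, the selected descriptor names and the training
#' scaling reference, so it can score raw screening matrices reproducibly
#' and survive a text serialization round trip bitwise.
#'
#' @param m A scaled `descriptor_matrix` (training panel).
#' @param subset A `descriptor_subset` or character vector of descriptor
#'   names.
#' @param targets Numeric activity per molecule (spikes/s increase above
#'   spontaneous firing), finite, length `nrow(m$values)`.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width; default `1 / length(subset)`.
#' @param epsilon Epsilon-insensitive band (default 0.1).
#' @param tolerance libsvm termination tolerance; tightened from libsvm's
#'   0.001 so the fit (and hence every downstream score) is insensitive to
#'   training row order to ~1e-9.
#' @return An object of class `orn_svm`: hyperparameters, `descriptors`,
#'   `scaling` (training reference), support vectors `SV`, `coefs`, `rho`,
#'   training-set `fingerprint`, and `fitted` training scores.
#' @examples
#' sim <- gen_training_set(chem_sim_config(n_descriptors = 40, seed = 1))
#' m <- scale_matrix(clean_matrix(sim$matrix))
#' fit <- train_svm(m, sim$truth$informative, sim$compounds$activity)
#' head(predict(fit, m))
#' @export
train_svm <- function(m, subset, targets, cost = 1, gamma = NULL,
                      epsilon = 0.1, tolerance = 1e-10) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (inherits(subset, "descriptor_subset")) subset <- subset$selected
  miss <- setdiff(subset, colnames(m$values))
  if (length(miss)) stopf("matrix lacks selected descriptor(s): %s",
                          paste(miss, collapse = ", "))
  X <- m$values[, subset, drop = FALSE]
  if (nrow(X) < 3L) stopf("need at least 3 molecules to train (got %d)", nrow(X))
  targets <- as.numeric(targets)
  if (length(targets) != nrow(X) || any(!is.finite(targets)))
    stopf("targets must be finite and one per molecule")
  if (is.null(gamma)) gamma <- 1 / length(subset)
  fit <- e1071::svm(X, targets, type = "eps-regression", kernel = "radial",
                    cost = cost, gamma = gamma, epsilon = epsilon,
                    tolerance = tolerance, scale = FALSE)
  scaling <- if (!is.null(m$scaling))
    list(center = m$scaling$center[subset], spread = m$scaling$spread[subset])
  model <- structure(list(
    kernel = "rbf",
    cost = cost, gamma = gamma, epsilon = epsilon,
    descriptors = subset,
    scaling = scaling,
    SV = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    fingerprint = object_hash(X, targets, c(cost, gamma, epsilon)),
    format_version = 1L), class = "orn_svm")
  model$fitted <- decision_values(model, X)
  model
}

# RBF support-vector expansion: f(x) = sum_i coef_i K(sv_i, x) - rho.
# Matches e1071's internal predict to machine precision; used for all
# scoring so serialized models predict identically.
decision_values <- function(model, X) {
  sv <- model$SV
  sv_sq <- rowSums(sv^2)
  x_sq <- rowSums(X^2)
  d2 <- outer(sv_sq, x_sq, "+") - 2 * tcrossprod(sv, X)
  d2[d2 < 0] <- 0
  K <- exp(-model$gamma * d2)
  drop(crossprod(K, model$coefs)) - model$rho
}

#' @export
print.orn_svm <- function(x, ...) {
  cat(sprintf("orn_svm: RBF eps-regression, %d support vectors, %d descriptor(s)\n",
              nrow(x$SV), length(x$descriptors)))
  cat(sprintf("  C=%g gamma=%g epsilon=%g  fingerprint=%s\n",
              x$cost, x$gamma, x$epsilon, substr(x$fingerprint, 1, 8)))
  invisible(x)
}

#' Score molecules with a trained model
#'
#' Scores a descriptor matrix with an [train_svm()] model; higher scores
#' mean stronger predicted agonism. If `newdata` carries no scaling
#' metadata, the model's stored training scaling is applied first (the
#' screening-library path); an already scaled matrix is used as-is. Scores
#' are returned in input row order.
#'
#' @param object An `orn_svm` model.
#' @param newdata A `descriptor_matrix` containing every selected
#'   descriptor.
#' @param ... Unused.
#' @return Named numeric vector of predicted activity scores.
#' @export
predict.orn_svm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "descriptor_matrix"))
  miss <- setdiff(object$descriptors, colnames(newdata$values))
  if (length(miss)) stopf("matrix lacks selected descriptor(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(newdata$scaling) && !is.null(object$scaling))
    newdata <- apply_scaling(newdata, object$scaling)
  X <- newdata$values[, object$descriptors, drop = FALSE]
  setNames(decision_values(object, X), rownames(X))
}

#' Save / load a trained model as structured text
#'
#' The model file is plain text: a `key: value` header (hyperparameters,
#' descriptor names, scaling reference, training fingerprint, format
#' version) followed by a tab-separated numeric payload of support-vector
#' coefficients and coordinates. Numbers are written at full precision
#' (`%.17g`), so a load/save round trip reproduces scores bitwise.
#'
#' @param model An `orn_svm` model.
#' @param path File path.
#' @return `path` (save) or the restored `orn_svm` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "orn_svm"))
  hdr <- c("# orn_svm model",
           sprintf("format_version: %d", model$format_version),
           sprintf("kernel: %s", model$kernel),
           sprintf("cost: %s", fmt_num(model$cost)),
           sprintf("gamma: %s", fmt_num(model$gamma)),
           sprintf("epsilon: %s", fmt_num(model$epsilon)),
           sprintf("rho: %s", fmt_num(model$rho)),
           sprintf("fingerprint: %s", model$fingerprint),
           sprintf("descriptors: %s", paste(model$descriptors, collapse = "\t")),
           if (!is.null(model$scaling)) c(
             sprintf("center: %s", paste(fmt_num(model$scaling$center),
                                         collapse = "\t")),
             sprintf("spread: %s", paste(fmt_num(model$scaling$spread),
                                         collapse = "\t"))),
           sprintf("n_sv: %d", nrow(model$SV)),
           "payload:")
  rows <- apply(cbind(model$coefs, model$SV), 1,
                function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  descriptors <- strsplit(field("descriptors"), "\t")[[1]]
  scaling <- NULL
  if (!is.null(field("center"))) {
    scaling <- list(
      center = setNames(as.numeric(strsplit(field("center"), "\t")[[1]]),
                        descriptors),
      spread = setNames(as.numeric(strsplit(field("spread"), "\t")[[1]]),
                        descriptors))
  }
  start <- which(lines == "payload:") + 1L
  n_sv <- as.integer(field("n_sv"))
  payload <- do.call(rbind, lapply(lines[seq(start, start + n_sv - 1L)],
                                   function(l) as.numeric(strsplit(l, "\t")[[1]])))
  model <- structure(list(
    kernel = field("kernel"),
    cost = as.numeric(field("cost")),
    gamma = as.numeric(field("gamma")),
    epsilon = as.numeric(field("epsilon")),
    descriptors = descriptors,
    scaling = scaling,
    SV = payload[, -1, drop = FALSE],
    coefs = payload[, 1],
    rho = as.numeric(field("rho")),
    fingerprint = field("fingerprint"),
    format_version = as.integer(field("format_version"))), class = "orn_svm")
  model
}
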