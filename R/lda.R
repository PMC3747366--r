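#' Fit a two-class linear discriminant function
#'
#' Pooled-covariance two-class LDA with equal priors on the selected
#' descriptors, parameterized as a discriminant function
#' df = a0 + sum_i a_i d_i whose decision boundary sits at df = 0 with
#' substrates (label +1) scoring positive. Descriptor selection is done
#' beforehand by [stepwise_select] on the class dummy; the final coefficients
#' come from this LDA fit, so selection and coefficients come from different
#' fits by design. The overall F and p-value are those of the multiple linear
#' regression of the dummy on the selected descriptors (equivalent, for two
#' classes, to the discriminant-analysis F).
#'
#' @param X numeric training matrix restricted to the selected descriptors.
#' @param labels -1/+1 class labels (+1 substrate).
#' @param entry_tolerances optional named tolerances recorded at entry by
#'   [stepwise_select], stored on the model.
#' @param config the [selection_config] used (stored; its
#'   cases-per-predictor bound is re-asserted here).
#' @param pool_id optional identifier of the descriptor pool of origin.
#' @return object of class \code{discriminant_model}: \code{descriptors},
#'   \code{coefficients} (a_i), \code{intercept} (a0), \code{F},
#'   \code{p_value}, \code{tolerances}, \code{training} (confusion summary at
#'   the df = 0 cutoff, positives = nonsubstrates), \code{cases_per_predictor},
#'   \code{pool_id}, \code{config}.
#' @export
fit_lda <- function(X, labels, entry_tolerances = NULL,
                    config = selection_config(), pool_id = NA_character_) {
  stopifnot(is.matrix(X), ncol(X) >= 1, !is.null(colnames(X)),
            nrow(X) == length(labels), all(labels %in% c(-1, 1)))
  pos <- labels == 1; neg <- labels == -1
  if (sum(pos) < 2 || sum(neg) < 2)
    stop("need at least 2 compounds per class")
  n <- nrow(X); p <- ncol(X)
  cpp <- n / p
  if (cpp < config$min_cases_per_predictor)
    stop(sprintf("cases-per-predictor ratio %.1f below the configured minimum %d",
                 cpp, config$min_cases_per_predictor))
  mu1 <- colMeans(X[pos, , drop = FALSE])
  mu0 <- colMeans(X[neg, , drop = FALSE])
  S <- (crossprod(sweep(X[pos, , drop = FALSE], 2, mu1)) +
        crossprod(sweep(X[neg, , drop = FALSE], 2, mu0))) / (n - 2)
  qs <- qr(S)
  if (qs$rank < p) {
    bad <- colnames(X)[qs$pivot[(qs$rank + 1):p]]
    stop("singular pooled covariance; collinear descriptors: ",
         paste(bad, collapse = ", "))
  }
  w <- drop(solve(qs, mu1 - mu0))
  names(w) <- colnames(X)
  a0 <- -sum((mu1 + mu0) / 2 * w)
  # overall F from the MLR of the dummy on the selected descriptors
  fit <- stats::lm.fit(cbind(1, X), as.numeric(labels))
  rss <- sum(fit$residuals^2)
  tss <- sum((labels - mean(labels))^2)
  Fv <- ((tss - rss) / p) / (rss / (n - p - 1))
  pv <- stats::pf(Fv, p, n - p - 1, lower.tail = FALSE)
  model <- structure(list(descriptors = colnames(X), coefficients = w,
                          intercept = a0, F = Fv, p_value = pv,
                          tolerances = entry_tolerances,
                          cases_per_predictor = cpp, pool_id = pool_id,
                          config = config, n_train = n),
                     class = "discriminant_model")
  calls <- predict(model, X, type = "class")
  model$training <- confusion(calls, labels)
  model
}

#' Score compounds with a discriminant model
#'
#' Computes df = a0 + sum_i a_i d_i per row and, for \code{type = "class"},
#' the class call: substrate (+1) iff df > threshold. A df exactly equal to
#' the threshold is called nonsubstrate, the conservative choice for a filter
#' meant to discard substrates.
#'
#' @param object a \code{discriminant_model}.
#' @param newdata numeric matrix containing (at least) the model's descriptor
#'   columns.
#' @param type \code{"score"} for df values, \code{"class"} for -1/+1 calls,
#'   \code{"both"} for a data.frame of both.
#' @param threshold class-call cutoff on the df scale (default 0).
#' @param ... unused.
#' @export
predict.discriminant_model <- function(object, newdata, type = c("score", "class", "both"),
                                       threshold = 0, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  miss <- setdiff(object$descriptors, colnames(newdata))
  if (length(miss))
    stop("missing descriptor columns: ", paste(miss, collapse = ", "))
  df <- drop(object$intercept +
             newdata[, object$descriptors, drop = FALSE] %*% object$coefficients)
  if (type == "score") return(df)
  calls <- ifelse(df > threshold, 1L, -1L)
  if (type == "class") return(calls)
  data.frame(df = df, call = calls)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("Discriminant function (%d descriptors, %d training compounds, %.1f cases/predictor)\n",
              length(x$descriptors), x$n_train, x$cases_per_predictor))
  cat(sprintf("  df = %.4g %s\n", x$intercept,
              paste(sprintf("%+.4g*%s", x$coefficients, x$descriptors),
                    collapse = " ")))
  cat(sprintf("  F = %.2f, p = %.3g\n", x$F, x$p_value))
  if (!is.null(x$training))
    cat(sprintf("  Training (cutoff 0): Sp %.1f%%  Se %.1f%%  accuracy %.1f%%\n",
                100 * x$training$Sp, 100 * x$training$Se,
                100 * x$training$accuracy))
  invisible(x)
}

#' Serialize a discriminant model to JSON
#'
#' @param model a \code{discriminant_model}.
#' @param path file to write.
#' @export
write_model_json <- function(model, path) {
  obj <- list(descriptors = model$descriptors,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept, F = model$F,
              p_value = model$p_value,
              tolerances = as.list(model$tolerances),
              cases_per_predictor = model$cases_per_predictor,
              pool_id = model$pool_id,
              config = unclass(model$config), n_train = model$n_train,
              training = unclass(model$training))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Build one model from a descriptor pool: stepwise selection plus LDA
#'
#' @param X training matrix restricted to one descriptor pool.
#' @param labels -1/+1 class labels.
#' @param config a [selection_config].
#' @param pool_id identifier stored on the model.
#' @return a \code{discriminant_model}, or NULL if selection found nothing.
#' @export
build_model <- function(X, labels, config = selection_config(),
                        pool_id = NA_character_) {
  sel <- stepwise_select(X, labels, config)
  if (length(sel$selected) == 0) return(NULL)
  fit_lda(X[, sel$selected, drop = FALSE], labels,
          entry_tolerances = sel$tolerances, config = config,
          pool_id = pool_id)
}
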