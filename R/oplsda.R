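# Internal lean fit on a centered matrix X and centered +-1 dummy d.
# Orthogonal-projections scheme for a single response:
#   repeat n_ortho times:
#     w  <- X'd / |X'd|          (predictive direction candidate)
#     t  <- X w ; p <- X't / t't (loading)
#     wo <- p - (w'p) w          (part of p orthogonal to w)
#     to <- X wo ; po <- X'to / to'to ; X <- X - to po'
#   final predictive component from the deflated X.
# Deflation guarantees t'to = 0 exactly (X'to = 0 after deflation).
opls_core <- function(X, d, n_ortho) {
  m <- ncol(X)
  Wo <- matrix(0, m, 0); To <- matrix(0, nrow(X), 0); Po <- matrix(0, m, 0)
  ss_ortho <- numeric(0)
  tol <- 1e-12
  for (k in seq_len(n_ortho)) {
    w <- crossprod(X, d)
    nw <- sqrt(sum(w^2))
    if (nw < tol) stop("no covariance left between X and the class labels")
    w <- w / nw
    tt <- X %*% w
    p <- crossprod(X, tt) / sum(tt^2)
    wo <- p - c(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to) / sum(to^2)
    X <- X - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); To <- cbind(To, to); Po <- cbind(Po, po)
    ss_ortho <- c(ss_ortho, sum(to^2) * sum(po^2))
  }
  w <- crossprod(X, d)
  nw <- sqrt(sum(w^2))
  if (nw < tol) stop("no covariance between X and the class labels")
  w <- w / nw
  tt <- c(X %*% w)
  p <- c(crossprod(X, tt)) / sum(tt^2)
  cq <- sum(d * tt) / sum(tt^2)
  list(w = c(w), t = tt, p = p, c = cq,
       Wo = Wo, To = To, Po = Po,
       ss_pred = sum(tt^2) * sum(p^2), ss_ortho = ss_ortho,
       E = X - tcrossprod(tt, p))
}

# regression coefficients on the centered scale: b = M w * c where M is the
# product of the orthogonal filters (I - wo po') in application order
opls_coef <- function(fit) {
  v <- fit$w
  k <- ncol(fit$Wo)
  if (k > 0) for (j in rev(seq_len(k)))
    v <- v - fit$Wo[, j] * sum(fit$Po[, j] * v)
  v * fit$c
}

encode_class <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2)
    stop("OPLS-DA requires exactly 2 classes; got ",
         nlevels(f), " (", paste(levels(f), collapse = ", "), ")")
  if (any(table(f) < 2)) stop("each class needs at least 2 samples")
  d0 <- ifelse(f == levels(f)[2], 1, -1)
  list(d0 = d0, d = d0 - mean(d0), mean = mean(d0), levels = levels(f))
}

#' Fit an OPLS-DA model
#'
#' Two-class orthogonal projections to latent structures discriminant
#' analysis: the variation in `x` is split into one predictive component
#' (scores `t[1]`, correlated with the class) and `n_ortho` orthogonal
#' components (scores `to[k]`, class-uncorrelated within-group variation)
#' which are removed by deflation before the predictive component is
#' extracted. The class is coded as a centered plus/minus one dummy, so
#' results are invariant to relabelling. The fit is deterministic — no
#' random initialisation.
#'
#' @param x numeric matrix (samples x features) with no missing values
#'   (see [impute_half_min()]), or a `scaled_matrix` from [pareto_scale()].
#' @param y two-class factor/character/logical vector of group labels.
#' @param n_ortho number of orthogonal components (default 1). Extraction
#'   stops early if no orthogonal variation remains.
#' @param center center the columns of `x` (default `TRUE`; a no-op for
#'   already-centered input).
#' @param ... unused.
#'
#' @return An object of class `oplsda` with predictive weights/scores/
#'   loading (`weights`, `scores`, `loading`, `y_loading`), orthogonal
#'   counterparts (`ortho_weights`, `ortho_scores`, `ortho_loadings`),
#'   explained-variation summaries (`r2x_pred`, `r2x_ortho`, `r2x_cum`,
#'   `r2y`), the centering information, and the class coding.
#' @seealso [vip()], [cross_validate()], [permutation_test()]
#' @export
oplsda <- function(x, ...) UseMethod("oplsda")

#' @rdname oplsda
#' @export
oplsda.scaled_matrix <- function(x, y, n_ortho = 1, ...) {
  oplsda.default(x$values, y, n_ortho = n_ortho, center = FALSE, ...)
}

#' @rdname oplsda
#' @export
oplsda.default <- function(x, y, n_ortho = 1, center = TRUE, ...) {
  x <- as.matrix(x)
  if (anyNA(x))
    stop("x contains missing values; impute first (impute_half_min)")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  enc <- encode_class(y)
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  X <- sweep(x, 2, ctr, "-")
  ssx <- sum(X^2)
  if (ssx == 0) stop("x has no variation")
  fit <- opls_core(X, enc$d, n_ortho)
  fitted_d <- fit$t * fit$c
  r2y <- 1 - sum((enc$d - fitted_d)^2) / sum(enc$d^2)
  fid <- colnames(x) %||% paste0("F", seq_len(ncol(x)))
  names(fit$w) <- fid
  structure(list(
    weights = fit$w, scores = fit$t, loading = fit$p, y_loading = fit$c,
    ortho_weights = fit$Wo, ortho_scores = fit$To, ortho_loadings = fit$Po,
    n_ortho = ncol(fit$Wo),
    r2x_pred = fit$ss_pred / ssx,
    r2x_ortho = fit$ss_ortho / ssx,
    r2x_cum = (fit$ss_pred + sum(fit$ss_ortho)) / ssx,
    r2y = r2y, ss_x = ssx,
    ss_pred = fit$ss_pred, ss_ortho = fit$ss_ortho,
    residual_x = fit$E,
    x_center = ctr, feature_id = fid,
    class_levels = enc$levels, dummy = enc$d0, dummy_mean = enc$mean,
    n = nrow(x), call = match.call()
  ), class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat("OPLS-DA model:", x$class_levels[1], "vs", x$class_levels[2],
      sprintf("(n = %d, %d features)\n", x$n, length(x$weights)))
  cat(sprintf("  1 predictive + %d orthogonal component(s)\n", x$n_ortho))
  cat(sprintf("  R2X(cum) = %.3f  (pred %.3f%s)   R2Y = %.3f\n",
              x$r2x_cum, x$r2x_pred,
              if (x$n_ortho) paste0(", ortho ",
                                    paste(sprintf("%.3f", x$r2x_ortho),
                                          collapse = " + ")) else "",
              x$r2y))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  comp <- data.frame(
    component = c("t[1]", if (object$n_ortho)
      sprintf("to[%d]", seq_len(object$n_ortho))),
    type = c("predictive", rep("orthogonal", object$n_ortho)),
    r2x = c(object$r2x_pred, object$r2x_ortho)
  )
  out <- list(components = comp, r2x_cum = object$r2x_cum, r2y = object$r2y,
              classes = object$class_levels, n = object$n)
  class(out) <- "summary.oplsda"
  out
}

#' @export
print.summary.oplsda <- function(x, ...) {
  cat("OPLS-DA:", x$classes[1], "vs", x$classes[2], "- n =", x$n, "\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("R2X(cum) = %.4f   R2Y = %.4f\n", x$r2x_cum, x$r2y))
  invisible(x)
}

#' @export
coef.oplsda <- function(object, ...) {
  b <- opls_coef(list(w = object$weights, c = object$y_loading,
                      Wo = object$ortho_weights, Po = object$ortho_loadings))
  names(b) <- object$feature_id
  attr(b, "intercept") <- object$dummy_mean
  b
}

#' Predict from an OPLS-DA model
#'
#' New samples are centered with the training centers, stripped of the
#' orthogonal components in training order, and projected on the predictive
#' weights.
#'
#' @param object an [oplsda()] fit.
#' @param newdata matrix with the training features (default: training data).
#' @param type `"class"` (predicted label), `"response"` (value on the
#'   plus/minus-one dummy scale) or `"scores"` (list with `t` and `t_ortho`).
#' @param ... unused.
#' @export
predict.oplsda <- function(object, newdata = NULL,
                           type = c("class", "response", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    tnew <- object$scores
    tonew <- object$ortho_scores
  } else {
    X <- sweep(as.matrix(newdata), 2, object$x_center, "-")
    k <- object$n_ortho
    tonew <- matrix(0, nrow(X), k)
    if (k > 0) for (j in seq_len(k)) {
      tonew[, j] <- X %*% object$ortho_weights[, j]
      X <- X - tcrossprod(tonew[, j], object$ortho_loadings[, j])
    }
    tnew <- c(X %*% object$weights)
  }
  if (type == "scores") return(list(t = tnew, t_ortho = tonew))
  resp <- tnew * object$y_loading + object$dummy_mean
  if (type == "response") return(resp)
  object$class_levels[(resp > 0) + 1L]
}

#' @export
fitted.oplsda <- function(object, ...) {
  object$scores * object$y_loading + object$dummy_mean
}

#' @export
residuals.oplsda <- function(object, ...) {
  object$dummy - (object$scores * object$y_loading + object$dummy_mean)
}

#' Score plot for an OPLS-DA model
#'
#' Predictive score t\[1\] against the first orthogonal score to\[1\]
#' (or sample index when the model has no orthogonal component), coloured by
#' class — the standard between- vs within-group separation display.
#'
#' @param x an [oplsda()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.oplsda <- function(x, ...) {
  cls <- factor(x$dummy, labels = x$class_levels)
  if (x$n_ortho > 0) {
    yv <- x$ortho_scores[, 1]; ylab <- "to[1] (orthogonal score)"
  } else {
    yv <- seq_along(x$scores); ylab <- "sample index"
  }
  graphics::plot(x$scores, yv, col = as.integer(cls), pch = 19,
                 xlab = "t[1] (predictive score)", ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = levels(cls),
                   col = seq_len(2), pch = 19, bty = "n")
  invisible(x)
}

#' Serialize an OPLS-DA model to JSON
#'
#' Writes weights, loadings, scores and the explained-variation diagnostics.
#'
#' @param model an [oplsda()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "oplsda"))
  obj <- list(
    classes = model$class_levels, n = model$n, n_ortho = model$n_ortho,
    feature_id = model$feature_id,
    weights = unname(model$weights), loading = model$loading,
    y_loading = model$y_loading,
    ortho_weights = model$ortho_weights, ortho_loadings = model$ortho_loadings,
    scores = model$scores, ortho_scores = model$ortho_scores,
    r2x_pred = model$r2x_pred, r2x_ortho = model$r2x_ortho,
    r2x_cum = model$r2x_cum, r2y = model$r2y,
    x_center = unname(model$x_center)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
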