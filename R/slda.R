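#' Shrinkage-regularized linear discriminant analysis
#'
#' Fits a binary LDA whose pooled covariance is shrunk towards a scaled
#' identity: with class means mu1, mu2 and the class-mean-centered pooled
#' covariance S (1/(n-1) normalization), the shrinkage target is nu * I
#' with nu = trace(S)/d, the shrinkage intensity lambda is the analytic
#' (Ledoit-Wolf / Schaefer-Strimmer) estimator clamped to [0, 1], and
#'
#'   S_tilde = (1 - lambda) S + lambda nu I,
#'   w = S_tilde^{-1} (mu2 - mu1),  b = -w' (mu1 + mu2) / 2.
#'
#' The decision value w'x + b is positive for the second class (class
#' order = sorted unique labels). When n <= d the weight solve uses the
#' Woodbury identity on the n x n Gram matrix, so high-dimensional
#' window features (d = 330) stay cheap.
#'
#' @param x Numeric matrix, n trials x d features.
#' @param y Labels with exactly two classes.
#' @param lambda Optional fixed shrinkage intensity in [0, 1]; default
#'   analytic.
#' @return Object of class \code{slda}: weights \code{w}, bias \code{b},
#'   \code{lambda}, target level \code{nu}, class labels.
#' @export
fit_slda <- function(x, y, lambda = NULL) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("no features (d = 0)")
  cls <- sort(unique(as.character(y)))
  if (length(cls) != 2L) stop("need exactly two classes, got ", length(cls))
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 trials")
  i1 <- which(y == cls[1]); i2 <- which(y == cls[2])
  if (!length(i1) || !length(i2)) stop("one class is absent")
  d <- ncol(x)
  mu1 <- colMeans(x[i1, , drop = FALSE])
  mu2 <- colMeans(x[i2, , drop = FALSE])
  Xc <- x
  Xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2L, mu1)
  Xc[i2, ] <- sweep(x[i2, , drop = FALSE], 2L, mu2)

  G <- tcrossprod(Xc)                    # n x n Gram matrix
  trS <- sum(Xc^2) / (n - 1)
  nu <- trS / d
  if (is.null(lambda)) {
    fro2 <- sum(G^2) / (n - 1)^2         # ||S||_F^2
    diagS <- colSums(Xc^2) / (n - 1)
    denom <- fro2 - sum(diagS^2) + sum((diagS - nu)^2)
    r2 <- rowSums(Xc^2)
    ssw <- sum(r2^2) - sum(G^2) / n
    num <- n / (n - 1)^3 * ssw
    lambda <- if (denom <= 0) 1 else min(1, max(0, num / denom))
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  }

  delta <- mu2 - mu1
  ridge <- lambda * nu
  if (ridge <= 0) {
    # unshrunk covariance: direct solve (requires n > d in practice)
    S <- crossprod(Xc) / (n - 1)
    w <- solve(S, delta)
  } else if (n < d) {
    # Woodbury: (ridge I + c Xc'Xc)^{-1} with c = (1-lambda)/(n-1)
    cc <- (1 - lambda) / (n - 1)
    if (cc == 0) {
      w <- delta / ridge
    } else {
      M <- diag(ridge / cc, n) + G
      w <- (delta - crossprod(Xc, solve(M, Xc %*% delta))) / ridge
    }
  } else {
    S <- crossprod(Xc) / (n - 1)
    w <- solve((1 - lambda) * S + diag(ridge, d), delta)
  }
  w <- as.numeric(w)
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(list(w = w, b = b, lambda = lambda, nu = nu,
                 classes = cls, n = n, d = d),
            class = "slda")
}

#' @export
print.slda <- function(x, ...) {
  cat(sprintf("Shrinkage LDA: %s vs %s, d = %d, n = %d, lambda = %.4f, nu = %.4g\n",
              x$classes[1], x$classes[2], x$d, x$n, x$lambda, x$nu))
  invisible(x)
}

#' @export
coef.slda <- function(object, ...) c(bias = object$b, object$w)

#' Predict from a shrinkage-LDA model
#'
#' @param object An \code{slda} fit.
#' @param newdata Matrix n x d of feature vectors.
#' @param type \code{"class"} (default) or \code{"decision"} (signed
#'   affine decision value, positive for the second class).
#' @param ... Unused.
#' @return Character class labels or numeric decision values.
#' @export
predict.slda <- function(object, newdata, type = c("class", "decision"),
                         ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(newdata), ncol = object$d)
  dv <- as.numeric(newdata %*% object$w + object$b)
  if (type == "decision") return(dv)
  object$classes[1L + (dv > 0)]
}

#' One-vs-one multiclass ensemble of shrinkage-LDA models
#'
#' Fits one binary \code{slda} per unordered class pair (k classes give
#' k(k-1)/2 models). Prediction is by majority vote over pairwise
#' decisions; ties are broken by the largest sum of signed decision values
#' accumulated over the tied classes' models, then by the lowest class
#' index — fully deterministic.
#'
#' @param x Matrix n x d of features.
#' @param y Labels (k >= 2 classes).
#' @param lambda Optional fixed shrinkage passed to every pairwise fit.
#' @return Object of class \code{slda_ovo}.
#' @export
fit_slda_ovo <- function(x, y, lambda = NULL) {
  y <- as.character(y)
  cls <- sort(unique(y))
  k <- length(cls)
  if (k < 2L) stop("need at least two classes")
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    fit_slda(x[sel, , drop = FALSE], y[sel], lambda = lambda)
  })
  structure(list(models = models, classes = cls, pairs = pairs),
            class = "slda_ovo")
}

#' @export
print.slda_ovo <- function(x, ...) {
  cat(sprintf("One-vs-one shrinkage LDA: %d classes, %d pairwise models\n",
              length(x$classes), length(x$models)))
  invisible(x)
}

#' @describeIn fit_slda_ovo Majority-vote prediction with margin tie-break.
#' @param object An \code{slda_ovo} fit.
#' @param newdata Matrix n x d.
#' @param ... Unused.
#' @export
predict.slda_ovo <- function(object, newdata, ...) {
  cls <- object$classes
  newdata <- matrix(as.numeric(newdata), ncol = object$models[[1]]$d)
  n <- nrow(newdata)
  votes <- margin <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
  for (m in object$models) {
    dv <- predict(m, newdata, type = "decision")
    win2 <- dv > 0
    votes[, m$classes[1]] <- votes[, m$classes[1]] + !win2
    votes[, m$classes[2]] <- votes[, m$classes[2]] + win2
    margin[, m$classes[1]] <- margin[, m$classes[1]] - dv
    margin[, m$classes[2]] <- margin[, m$classes[2]] + dv
  }
  out <- character(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      best <- top[margin[i, top] == max(margin[i, top])]
      top <- best[1]                      # lowest class index among ties
    }
    out[i] <- cls[top]
  }
  out
}
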