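#' Gaussian-process regression with a linear kernel
#'
#' The per-region age predictor is a Gaussian process with kernel
#' `k(x, x') = sf2 * x.x'` plus white noise `sn2` (an RBF kernel is
#' available by configuration). Hyperparameters are set by maximising the
#' log marginal likelihood with L-BFGS-B over log-parameters from a fixed
#' set of starting points, so fits are deterministic. A linear kernel is
#' the standard choice for high-dimensional brain-age GPR: the posterior
#' mean is a regularised linear readout of the voxel features.
#'
#' For the linear kernel the Gram matrix is eigendecomposed once, after
#' which every marginal-likelihood evaluation and its gradient cost O(n):
#' with `K = sf2*U L U' + sn2*I` all spectra shift analytically.
#'
#' @param x training feature matrix (subjects x features).
#' @param y training targets (years).
#' @param kernel `"linear"` or `"rbf"`.
#' @param center subtract the training mean of `y` before fitting (added
#'   back at prediction). Disable only for cross-checks against external
#'   implementations that do not center.
#' @param optimize maximise the marginal likelihood; if `FALSE` the
#'   supplied `sf2`/`sn2` (and `ls2` for RBF) are used as-is.
#' @param sf2,sn2,ls2 signal variance, noise variance, and (RBF) squared
#'   length-scale.
#' @return a `gpr_fit` object.
#' @export
gpr_fit <- function(x, y, kernel = c("linear", "rbf"), center = TRUE,
                    optimize = TRUE, sf2 = 1, sn2 = 1, ls2 = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  n <- nrow(x)
  assert_that(n == length(y), "x and y must align")
  ym <- if (center) mean(y) else 0
  yc <- y - ym
  vy <- max(var(yc) * (n - 1) / n, 1e-8)
  if (kernel == "linear") {
    k0 <- tcrossprod(x)
    if (optimize) {
      eg <- eigen(k0, symmetric = TRUE)
      lam <- pmax(eg$values, 0)
      w <- as.vector(crossprod(eg$vectors, yc))
      neg_loglik <- function(th) {
        s <- exp(th[1]); v <- exp(th[2])
        d <- s * lam + v
        nll <- 0.5 * sum(w^2 / d) + 0.5 * sum(log(d)) + 0.5 * n * log(2 * pi)
        h <- (1 / d - w^2 / d^2)
        list(value = nll,
          grad = c(0.5 * sum(h * s * lam), 0.5 * sum(h * v)))
      }
      scale0 <- max(mean(lam), 1e-8)
      starts <- list(
        c(log(vy / scale0), log(vy / 10)),
        c(log(vy / scale0) + 2, log(vy / 2)),
        c(log(vy / scale0) - 2, log(vy))
      )
      # relative noise floor keeps the final system well-conditioned even
      # when the features are noiseless (rank-deficient Gram matrix)
      lower <- c(-30, log(vy) - 18)
      best <- optimize_nll(neg_loglik, starts, lower = lower)
      sf2 <- exp(best[1]); sn2 <- exp(best[2])
    }
    kk <- sf2 * k0 + diag(sn2, n)
    alpha <- solve(kk, yc)
  } else {
    d2 <- as.matrix(stats::dist(x))^2
    if (is.null(ls2)) {
      pos <- d2[d2 > 0]
      ls2 <- if (length(pos)) stats::median(pos) else 1
    }
    if (optimize) {
      neg_loglik <- function(th) {
        s <- exp(th[1]); v <- exp(th[2]); l <- exp(th[3])
        kf <- s * exp(-d2 / (2 * l))
        kk <- kf + diag(v, n)
        ch <- tryCatch(chol(kk), error = function(e) NULL)
        if (is.null(ch)) return(list(value = 1e10, grad = c(0, 0, 0)))
        a <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
        nll <- 0.5 * sum(yc * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
        wm <- tcrossprod(a) - chol2inv(ch)
        list(value = nll, grad = c(
          -0.5 * sum(wm * kf),
          -0.5 * sum(diag(wm)) * v,
          -0.5 * sum(wm * (kf * d2 / (2 * l)))))
      }
      starts <- list(c(log(vy), log(vy / 10), log(ls2)),
        c(log(vy) + 1, log(vy / 2), log(ls2) + 1))
      best <- optimize_nll(neg_loglik, starts)
      sf2 <- exp(best[1]); sn2 <- exp(best[2]); ls2 <- exp(best[3])
    }
    kk <- sf2 * exp(-d2 / (2 * ls2)) + diag(sn2, n)
    alpha <- solve(kk, yc)
  }
  structure(
    list(kernel = kernel, sf2 = sf2, sn2 = sn2, ls2 = ls2,
      x = x, alpha = alpha, y_mean = ym, center = center),
    class = "gpr_fit"
  )
}

# Deterministic multi-start L-BFGS-B over a cached value/gradient pair.
optimize_nll <- function(neg_loglik, starts, lower = NULL) {
  best <- NULL
  if (is.null(lower)) lower <- rep(-30, length(starts[[1]]))
  for (st in starts) {
    st <- pmax(st, lower)
    last <- NULL
    fn <- function(th) {
      last <<- neg_loglik(th)
      last$value
    }
    gr <- function(th) {
      if (is.null(last)) last <<- neg_loglik(th)
      last$grad
    }
    opt <- tryCatch(
      optim(st, fn, gr, method = "L-BFGS-B",
        lower = lower, upper = rep(30, length(st)),
        control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  assert_that(!is.null(best), "marginal-likelihood optimisation failed",
    class = "regionbag_model_fit_error")
  best$par
}

#' Posterior-mean prediction from a GPR fit
#'
#' @param object a `gpr_fit`.
#' @param newdata feature matrix with the same columns as the training
#'   matrix.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gpr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  assert_that(ncol(newdata) == ncol(object$x),
    "newdata has the wrong number of features")
  ks <- if (object$kernel == "linear") {
    object$sf2 * tcrossprod(newdata, object$x)
  } else {
    d2 <- outer(rowSums(newdata^2), rowSums(object$x^2), "+") -
      2 * tcrossprod(newdata, object$x)
    object$sf2 * exp(-pmax(d2, 0) / (2 * object$ls2))
  }
  as.vector(ks %*% object$alpha) + object$y_mean
}
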