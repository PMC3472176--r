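#' @export
print.greml <- function(x, digits = 4, ...) {
  cat("Variance components estimated by AI-REML\n")
  cat("  terms:", paste(x$terms, collapse = " + "), "+ weighted residual\n")
  est <- cbind(estimate = x$sigma2, SE = x$se)
  print(round(est, digits))
  cat(sprintf("  logLik %.4f after %d iterations (%s)\n", x$logLik,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  if (any(x$boundary))
    cat("  at lower boundary:", paste(names(x$boundary)[x$boundary],
                                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) {
  vr <- variance_ratio(object)
  props <- object$sigma2[object$terms] / sum(object$sigma2[object$terms])
  out <- list(object = object, VR = vr, genetic_proportions = props)
  class(out) <- "summary.greml"
  out
}

#' @export
print.summary.greml <- function(x, digits = 4, ...) {
  print(x$object, digits = digits)
  cat(sprintf("  variance ratio (VR at mean weight diagonal %.4f): %.4f\n",
              x$object$dbar, x$VR))
  if (length(x$genetic_proportions) > 1) {
    cat("  share of total genetic variance:\n")
    print(round(x$genetic_proportions, digits))
  }
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$fixef

#' @export
vcov.greml <- function(object, ...) object$vcov_fixef

#' @export
logLik.greml <- function(object, ...) {
  structure(object$logLik, df = length(object$sigma2),
            nobs = object$n, class = "logLik")
}

#' @export
fitted.greml <- function(object, ...) as.vector(object$X %*% object$fixef)

#' @export
residuals.greml <- function(object, ...) object$y - fitted(object)

#' Simulate responses from a fitted variance-component model
#'
#' Draws new response vectors from `N(X b, V)` at the fitted variance
#' components, with `V = sum_r sigma_r^2 Z_r K_r Z_r' + sigma_e^2 D`.
#'
#' @param object a fitted [greml] model.
#' @param nsim number of response vectors.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return data frame with `nsim` columns, one simulated response per column.
#' @export
simulate.greml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(object$B)
  V <- diag(object$sigma2[["residual"]] * object$dvec, object$n)
  for (r in seq_len(k)) V <- V + object$sigma2[[r]] * object$B[[r]]
  ch <- chol(V + diag(1e-10 * mean(diag(V)), object$n))
  mu <- fitted(object)
  out <- as.data.frame(
    mu + t(ch) %*% matrix(stats::rnorm(object$n * nsim), object$n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the REML iteration trace
#'
#' Shows the restricted log-likelihood over accepted iterations (left) and
#' the variance-component paths (right).
#'
#' @param x a fitted [greml] model.
#' @param ... further arguments passed to [plot()].
#' @export
plot.greml <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  it <- seq_len(nrow(x$trace)) - 1L
  plot(it, x$trace[, "logLik"], type = "b", xlab = "iteration",
       ylab = "restricted logLik", main = "REML trace", ...)
  np <- ncol(x$trace) - 1L
  graphics::matplot(it, x$trace[, seq_len(np), drop = FALSE], type = "b",
                    lty = 1, pch = 1, xlab = "iteration",
                    ylab = "variance estimate", main = "components")
  graphics::legend("topright", legend = colnames(x$trace)[seq_len(np)],
                   col = seq_len(np), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
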