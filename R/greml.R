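## Assemble the model structure shared by greml() and reml_loglik():
## response y, fixed-effect design X, per-term covariance blocks
## B_r = Z_r K_r Z_r' (built by indexing K with the record -> individual map),
## and the residual weight diagonal dvec (var(e_i) = sigma_e^2 * dvec_i).
.greml_build <- function(formula, data, random, weights = NULL, id = NULL) {
  if (!is.list(random) || length(random) == 0 || is.null(names(random)) ||
      any(names(random) == ""))
    stop("'random' must be a non-empty named list of relationship matrices")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric")
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  ids <- if (is.null(id)) {
    if (!is.null(data$id)) as.character(data$id) else rownames(data)
  } else if (is.character(id) && length(id) == 1 && id %in% names(data)) {
    as.character(data[[id]])
  } else {
    as.character(id)
  }
  if (length(ids) != n) stop("record ids do not match the number of records")
  B <- vector("list", length(random))
  names(B) <- names(random)
  for (r in names(random)) {
    K <- random[[r]]
    if (!is.matrix(K) || is.null(rownames(K)))
      stop("random term '", r, "' must be a matrix with individual ids as rownames")
    idx <- match(ids, rownames(K))
    if (anyNA(idx))
      stop("random term '", r, "': no matrix entry for record id(s) ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    B[[r]] <- unclass(K)[idx, idx, drop = FALSE]
  }
  w <- if (is.null(weights)) rep(1, n)
  else if (is.character(weights) && length(weights) == 1) data[[weights]]
  else weights
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stop("'weights' must be positive finite effective record counts, one per record")
  list(y = as.numeric(y), X = X, B = B, dvec = 1 / w, ids = ids, n = n)
}

## V, its Cholesky pieces and the REML projection quantities for one
## parameter vector; returns NULL if V (or X'V^{-1}X) is not positive definite
.greml_core <- function(st, sigma2) {
  k <- length(st$B)
  V <- diag(sigma2[k + 1] * st$dvec, st$n)
  for (r in seq_len(k)) V <- V + sigma2[r] * st$B[[r]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% st$X
  XtVinvX <- crossprod(st$X, VinvX)
  chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  P <- Vinv - VinvX %*% chol2inv(chx) %*% t(VinvX)
  Py <- as.vector(P %*% st$y)
  logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(st$y * Py))
  beta <- chol2inv(chx) %*% crossprod(VinvX, st$y)
  list(P = P, Py = Py, logL = logL, beta = as.vector(beta),
       vcov_beta = chol2inv(chx), cond = max(diag(V)) / max(min(diag(V)), 1e-300))
}

## scores and average-information matrix at the current point
.greml_derivs <- function(st, core) {
  k <- length(st$B)
  np <- k + 1L
  trPB <- numeric(np)
  BPy <- vector("list", np)
  for (r in seq_len(k)) {
    trPB[r] <- sum(core$P * st$B[[r]])
    BPy[[r]] <- as.vector(st$B[[r]] %*% core$Py)
  }
  trPB[np] <- sum(diag(core$P) * st$dvec)
  BPy[[np]] <- st$dvec * core$Py
  score <- numeric(np)
  PBPy <- vector("list", np)
  for (r in seq_len(np)) {
    score[r] <- -0.5 * (trPB[r] - sum(core$Py * BPy[[r]]))
    PBPy[[r]] <- as.vector(core$P %*% BPy[[r]])
  }
  AI <- matrix(0, np, np)
  for (r in seq_len(np))
    for (s in r:np)
      AI[r, s] <- AI[s, r] <- 0.5 * sum(BPy[[r]] * PBPy[[s]])
  list(score = score, AI = AI, trPB = trPB, yPBPy = vapply(
    seq_len(np), function(r) sum(core$Py * BPy[[r]]), numeric(1)))
}

#' Restricted log-likelihood of a weighted multi-kernel mixed model
#'
#' Evaluates the REML objective
#' `-1/2 [ log|V| + log|X'V^{-1}X| + y'Py ]` (up to the usual constant) for
#' the model `y = X b + sum_r Z_r u_r + e`, with `var(u_r) = K_r sigma_r^2`
#' and `var(e) = sigma_e^2 D`, `D = diag(1/w)`.
#'
#' @param formula model formula for the fixed part (typically `y ~ 1`, a
#'   general mean).
#' @param data data frame holding the response, ids and weights.
#' @param random named list of relationship matrices ([relmat] or plain
#'   matrices with id rownames); records are mapped to matrix rows by id.
#' @param sigma2 numeric vector of variances: one per random term, in the
#'   order of `random`, followed by the residual variance.
#' @param weights effective-record weights (column name or vector);
#'   `var(e_i) = sigma_e^2 / w_i`.  Default all 1.
#' @param id record-to-individual map: column name or vector; defaults to
#'   `data$id`.
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(formula, data, random, sigma2, weights = NULL,
                        id = NULL) {
  st <- .greml_build(formula, data, random, weights, id)
  np <- length(st$B) + 1L
  if (length(sigma2) != np)
    stop("'sigma2' must have ", np, " entries (random terms + residual)")
  if (any(sigma2 < 0)) stop("variances must be >= 0")
  core <- .greml_core(st, sigma2)
  if (is.null(core))
    stop("V (or X'V^{-1}X) is not positive definite at the supplied variances")
  core$logL
}

#' Fit variance components by average-information REML
#'
#' Restricted maximum likelihood for mixed models of the form
#' `y = X b + sum_r Z_r u_r + e` with `var(u_r) = K_r sigma_r^2` for
#' user-supplied relationship matrices `K_r` (pedigree, genomic,
#' chromosome-split, ...) and heterogeneous residual variance
#' `var(e_i) = sigma_e^2 / w_i` set by effective-record weights — the model
#' family used to partition additive genetic variance into genomic and
#' residual polygenic components.
#'
#' The optimizer takes average-information (AI) steps with step halving and
#' falls back to an EM update whenever the AI step fails or would decrease
#' the restricted likelihood, so the accepted log-likelihood trace is
#' non-decreasing.  Variances are constrained to at least
#' `1e-8 * var(y)`; parameters pinned at that floor at convergence are
#' flagged as boundary estimates.  Standard errors come from the inverse AI
#' matrix at convergence.
#'
#' @inheritParams reml_loglik
#' @param init optional starting variances (random terms then residual);
#'   default splits `var(y)` equally across all components.
#' @param max_iter maximum number of iterations.
#' @param tol_logl convergence threshold on the relative log-likelihood
#'   change.
#' @param tol_par convergence threshold on the maximum relative parameter
#'   change.
#' @param verbose print the iteration trace.
#' @return an object of class `greml` with components `sigma2` (named vector
#'   including `"residual"`), `se`, `logLik`, `fixef` and their covariance,
#'   `converged`, `boundary`, `trace` (iteration history), `dbar` (mean
#'   residual weight diagonal) and the model structure needed by methods.
#' @seealso [variance_ratio()], [fit_vc_model()]
#' @export
greml <- function(formula, data, random, weights = NULL, id = NULL,
                  init = NULL, max_iter = 200L, tol_logl = 1e-8,
                  tol_par = 1e-6, verbose = FALSE) {
  cl <- match.call()
  st <- .greml_build(formula, data, random, weights, id)
  k <- length(st$B)
  np <- k + 1L
  if (st$n < np + 1L)
    stop("greml: need at least ", np + 1L, " records to estimate ", np,
         " variance parameters")
  vy <- stats::var(st$y)
  if (!is.finite(vy) || vy <= 0)
    stop("greml: response has zero variance")
  floor_v <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / np, np) else {
    if (length(init) != np) stop("'init' must have ", np, " entries")
    pmax(init, floor_v)
  }
  core <- .greml_core(st, theta)
  if (is.null(core)) stop("greml: V singular at the starting values")
  trace <- matrix(NA_real_, 0, np + 1L)
  colnames(trace) <- c(names(st$B), "residual", "logLik")
  trace <- rbind(trace, c(theta, core$logL))
  converged <- FALSE
  step_types <- character(0)
  de <- NULL
  for (iter in seq_len(max_iter)) {
    de <- .greml_derivs(st, core)
    em_theta <- theta + theta^2 / st$n * (de$yPBPy - de$trPB)
    em_theta <- pmax(em_theta, floor_v)
    prop <- NULL
    type <- "EM"
    # active-set AI step: a parameter pinned at the floor whose score points
    # further down is held fixed, so the Newton step is taken in the interior
    # parameters only
    at_floor <- theta <= floor_v * (1 + 1e-8)
    active <- !(at_floor & de$score < 0)
    delta <- NULL
    if (any(active)) {
      sol <- tryCatch(solve(de$AI[active, active, drop = FALSE],
                            de$score[active]),
                      error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol))) {
        delta <- rep(0, np)
        delta[active] <- sol
      }
    }
    if (!is.null(delta)) {
      halve <- 1
      for (h in seq_len(12)) {
        cand <- pmax(theta + delta * halve, floor_v)
        cc <- .greml_core(st, cand)
        if (!is.null(cc) && is.finite(cc$logL) && cc$logL >= core$logL - 1e-10) {
          prop <- list(theta = cand, core = cc)
          type <- if (h == 1) "AI" else "AI-halved"
          break
        }
        halve <- halve / 2
      }
    }
    stalled <- FALSE
    if (is.null(prop)) {
      # EM fallback, still subject to the ascent check: halve towards the
      # current point if needed, and stop when no ascent remains
      frac <- 1
      for (h in seq_len(8)) {
        cand <- pmax(theta + frac * (em_theta - theta), floor_v)
        cc <- .greml_core(st, cand)
        if (!is.null(cc) && is.finite(cc$logL) && cc$logL >= core$logL - 1e-10) {
          prop <- list(theta = cand, core = cc)
          type <- "EM"
          break
        }
        frac <- frac / 2
      }
      if (is.null(prop)) {
        prop <- list(theta = theta, core = core)
        type <- "stall"
        stalled <- TRUE
      }
    }
    rel_l <- abs(prop$core$logL - core$logL) / (abs(core$logL) + 1e-10)
    # parameter change relative to its own size, with a floor at a small
    # fraction of var(y) so boundary-pinned components cannot stall the test
    rel_p <- max(abs(prop$theta - theta) / pmax(theta, 1e-3 * vy))
    theta <- prop$theta
    core <- prop$core
    step_types <- c(step_types, type)
    trace <- rbind(trace, c(theta, core$logL))
    if (verbose)
      message(sprintf("iter %3d [%9s] logL = %.6f  sigma2 = %s", iter, type,
                      core$logL, paste(signif(theta, 5), collapse = ", ")))
    if (stalled || (rel_l < tol_logl && rel_p < tol_par)) {
      converged <- TRUE
      break
    }
  }
  de <- .greml_derivs(st, core)
  se <- rep(NA_real_, np)
  aii <- tryCatch(solve(de$AI), error = function(e) NULL)
  if (!is.null(aii)) {
    dse <- diag(aii)
    se[dse > 0] <- sqrt(dse[dse > 0])
  }
  nm <- c(names(st$B), "residual")
  out <- list(call = cl,
              sigma2 = stats::setNames(theta, nm),
              se = stats::setNames(se, nm),
              logLik = core$logL,
              fixef = stats::setNames(core$beta, colnames(st$X)),
              vcov_fixef = core$vcov_beta,
              converged = converged,
              iterations = nrow(trace) - 1L,
              boundary = stats::setNames(theta <= floor_v * (1 + 1e-6), nm),
              trace = trace,
              step_types = step_types,
              terms = names(st$B),
              dbar = mean(st$dvec),
              n = st$n,
              y = st$y,
              X = st$X,
              B = st$B,
              dvec = st$dvec,
              ids = st$ids,
              floor = floor_v)
  class(out) <- "greml"
  if (!converged)
    warning("greml: not converged in ", max_iter, " iterations")
  out
}

#' Heritability-like variance ratio of a fitted model
#'
#' The ratio of total genetic variance to total variance of the record,
#' `VR = sum_r sigma_r^2 / (sum_r sigma_r^2 + dbar * sigma_e^2)`, where the
#' sum runs over the model's genetic terms and `dbar` is the arithmetic mean
#' diagonal of the residual weight matrix `D` — i.e. the heritability of a
#' deregressed proof evaluated at the average reliability of the animals.
#'
#' @param object a fitted [greml] model (or a [fit_vc_model()] result).
#' @param mean_weight_diag optional override for `dbar`; defaults to the mean
#'   of `1/w_i` over the fitted records.
#' @return the variance ratio (scalar in `[0, 1]`).
#' @export
variance_ratio <- function(object, mean_weight_diag = NULL) {
  if (inherits(object, "vc_model")) object <- object$fit
  stopifnot(inherits(object, "greml"))
  dbar <- if (is.null(mean_weight_diag)) object$dbar else mean_weight_diag
  sg <- sum(object$sigma2[object$terms])
  tot <- sg + dbar * object$sigma2[["residual"]]
  if (tot <= 0) stop("variance_ratio: total variance is zero")
  unname(sg / tot)
}
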