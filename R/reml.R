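#' REML control parameters
#'
#' @param max_iter maximum number of average-information iterations.
#' @param tol_ll absolute convergence tolerance on the restricted
#'   log-likelihood.
#' @param tol_par relative convergence tolerance on the parameter vector,
#'   measured as `max |delta| / (|theta| + 1)`.
#' @param floor_frac variance floor, as a fraction of the phenotypic variance;
#'   negative variance proposals are projected to this floor.
#' @param verbose print the likelihood trajectory.
#' @return a named list of control values.
#' @export
reml_control <- function(max_iter = 200, tol_ll = 1e-6, tol_par = 1e-5,
                         floor_frac = 1e-8, verbose = FALSE) {
  list(max_iter = max_iter, tol_ll = tol_ll, tol_par = tol_par,
       floor_frac = floor_frac, verbose = verbose)
}

# Generic average-information REML for V = sum_k theta_k M_k.
#
# Structures M_k are either full symmetric n x n matrices or numeric vectors
# (diagonal structures). One parameter (`within`) may additionally absorb a
# within-group residual sum of squares (sse_w on df_w degrees of freedom) that
# was projected out of the data before collapsing observations to group means;
# its contribution enters the restricted likelihood, the score and the
# information analytically.
#
# `lower0` marks variance-type parameters (floored at floor_frac * var(y));
# `psd_blocks` is a list of integer triples (i, j, k): parameters i and j are
# variances and k a covariance that must keep the 2x2 matrix PSD (enforced by
# bending the covariance).
#
# AI updates that leave the parameter space or decrease the restricted
# likelihood are step-halved toward the current point; the accepted
# trajectory is therefore non-decreasing in the restricted log-likelihood.
reml_ai <- function(y, X, K, lower0, theta_init = NULL, within = 0L,
                    df_w = 0, sse_w = 0, psd_blocks = NULL,
                    control = reml_control()) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, length(K) >= 1)
  nk <- length(K)
  if (length(lower0) != nk) stop("lower0 must match structures")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- max(mean(y^2), 1)
  floor_v <- control$floor_frac * vy

  is_diag <- vapply(K, is.vector, logical(1))
  if (is.null(theta_init)) {
    nv <- sum(lower0)
    theta_init <- ifelse(lower0, vy / max(nv, 1), 0)
  }
  theta <- pmax_floor(theta_init, lower0, floor_v)
  theta <- bend_psd(theta, psd_blocks)

  build_V <- function(th) {
    V <- matrix(0, n, n)
    for (k in seq_len(nk)) {
      if (is_diag[k]) {
        diag(V) <- diag(V) + th[k] * K[[k]]
      } else {
        V <- V + th[k] * K[[k]]
      }
    }
    V
  }

  # Evaluates restricted log-likelihood and the quantities reused by the
  # score/AI step; returns NULL for proposals outside the PD cone.
  evaluate <- function(th) {
    V <- build_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    XtViX_inv <- chol2inv(chX)
    P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
    Py <- drop(P %*% y)
    yPy <- sum(y * Py)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)
    if (within > 0L && df_w > 0) {
      ll <- ll - 0.5 * (df_w * log(th[within]) + sse_w / th[within])
    }
    if (!is.finite(ll)) return(NULL)
    list(ll = ll, Vi = Vi, ViX = ViX, XtViX_inv = XtViX_inv, P = P, Py = Py)
  }

  st <- evaluate(theta)
  if (is.null(st)) stop("initial variance components give a singular system")
  ll_trace <- st$ll
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(control$max_iter)) {
    # score and average information
    score <- numeric(nk)
    wlist <- vector("list", nk)
    dP <- diag(st$P)
    for (k in seq_len(nk)) {
      if (is_diag[k]) {
        trPK <- sum(dP * K[[k]])
        wlist[[k]] <- K[[k]] * st$Py
      } else {
        trPK <- sum(st$P * K[[k]])
        wlist[[k]] <- drop(K[[k]] %*% st$Py)
      }
      score[k] <- -0.5 * (trPK - sum(st$Py * wlist[[k]]))
    }
    AI <- matrix(0, nk, nk)
    Pw <- lapply(wlist, function(w) drop(st$P %*% w))
    for (k in seq_len(nk)) {
      for (l in k:nk) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(wlist[[k]] * Pw[[l]])
      }
    }
    if (within > 0L && df_w > 0) {
      tw <- theta[within]
      score[within] <- score[within] - 0.5 * (df_w / tw - sse_w / tw^2)
      AI[within, within] <- AI[within, within] + 0.5 * df_w / tw^2
    }

    # active set: parameters pinned at the variance floor whose score pulls
    # them outward stay fixed; the AI system is solved for the rest
    pinned <- lower0 & theta <= floor_v * (1 + 1e-6) & score < 0
    free <- which(!pinned)
    delta <- numeric(nk)
    if (length(free) > 0) {
      AIf <- AI[free, free, drop = FALSE]
      delta[free] <- tryCatch(
        solve(AIf + diag(1e-10 * max(diag(AIf), 1), length(free)),
              score[free]),
        error = function(e) score[free] * 1e-4)
    }
    # cap the Newton step: ill-conditioned AI matrices (near-collinear
    # structures) can propose astronomically large updates
    allowed <- 3 * (abs(theta) + 0.3 * vy)
    fac <- min(1, allowed / pmax(abs(delta), .Machine$double.xmin))
    delta <- delta * fac

    # step halving onto the constrained space; if the AI direction fails,
    # retry along the (projected) gradient
    try_direction <- function(delta) {
      for (h in 0:30) {
        prop <- theta + delta / 2^h
        prop <- pmax_floor(prop, lower0, floor_v)
        prop <- bend_psd(prop, psd_blocks)
        st_new <- evaluate(prop)
        if (!is.null(st_new) && st_new$ll >= st$ll - 1e-10) {
          return(list(prop = prop, st = st_new))
        }
      }
      NULL
    }
    hit <- try_direction(delta)
    if (is.null(hit)) {
      grad_dir <- score
      grad_dir[pinned] <- 0
      gscale <- 0.5 * (abs(theta) + 0.1 * vy) /
        pmax(max(abs(grad_dir)), .Machine$double.xmin)
      hit <- try_direction(grad_dir * gscale)
    }
    accepted <- !is.null(hit)
    if (accepted) {
      prop <- hit$prop
      st_new <- hit$st
    }
    if (!accepted) {
      converged <- length(ll_trace) >= 2 &&
        abs(ll_trace[length(ll_trace)] -
              ll_trace[length(ll_trace) - 1]) < control$tol_ll
      break
    }
    d_ll <- st_new$ll - st$ll
    d_par <- max(abs(prop - theta) / (abs(theta) + 1))
    theta <- prop
    st <- st_new
    ll_trace <- c(ll_trace, st$ll)
    if (control$verbose) {
      message(sprintf("iter %3d  logLik %.6f", iter, st$ll))
    }
    if (d_ll < control$tol_ll && d_par < control$tol_par) {
      converged <- TRUE
      break
    }
  }

  b_hat <- drop(st$XtViX_inv %*% crossprod(st$ViX, y))
  boundary <- any(lower0 & theta <= floor_v * (1 + 1e-6))
  list(theta = theta, loglik = st$ll, ll_trace = ll_trace,
       converged = converged, boundary = boundary, iterations = iter,
       b_hat = b_hat, Vi = st$Vi, ViX = st$ViX, XtViX_inv = st$XtViX_inv,
       P = st$P, Py = st$Py, floor = floor_v)
}

pmax_floor <- function(theta, lower0, floor_v) {
  theta[lower0] <- pmax(theta[lower0], floor_v)
  theta
}

# Bend covariance parameters so each declared 2x2 block stays PSD.
bend_psd <- function(theta, psd_blocks) {
  if (is.null(psd_blocks)) return(theta)
  for (b in psd_blocks) {
    bound <- sqrt(theta[b[1]] * theta[b[2]])
    if (abs(theta[b[3]]) > 0.999 * bound) {
      warning("genetic covariance bent onto the PSD boundary", call. = FALSE)
      theta[b[3]] <- sign(theta[b[3]]) * 0.999 * bound
    }
  }
  theta
}
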