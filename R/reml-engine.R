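# Average-information REML for linear mixed models
#   y = X b + sum_i u_i + e,   u_i ~ N(0, theta_i * V_i),  e ~ N(0, theta_e I)
# parameterized directly by the record-level covariance contributions V_i
# (i.e. Z_i K_i Z_i'). The first iteration is an EM step for stability; later
# iterations take AI (Fisher-scoring on the average information) steps with
# step-halving, falling back to EM when the AI update leaves the parameter
# space, and projecting components onto a small nonnegative bound. This
# follows the behaviour of the usual AI-REML implementations in animal
# breeding software.

# Evaluate restricted loglik, score and AI matrix at theta.
# Vlist: list of k record-level covariance matrices (residual appended
# internally as identity). Returns the pieces needed for updates and BLUP.
reml_eval <- function(y, X, Vlist, theta) {
  n <- length(y); k <- length(Vlist)
  V <- diag(rep(theta[k + 1L], n))
  for (i in seq_len(k)) V <- V + theta[i] * Vlist[[i]]
  cV <- tryCatch(chol(V), error = function(e) {
    abort("covariance matrix not positive definite at current estimates; consider a larger relationship-matrix ridge",
          class = "hapblup_numerical_error")
  })
  ldV <- 2 * sum(log(diag(cV)))
  Vinv <- chol2inv(cV)
  VinvX <- Vinv %*% X
  XtViX <- crossprod(X, VinvX)
  cX <- chol(XtViX)
  ldX <- 2 * sum(log(diag(cX)))
  XtViX_inv <- chol2inv(cX)
  P <- Vinv - VinvX %*% tcrossprod(XtViX_inv, VinvX)
  Py <- drop(P %*% y)
  ll <- -0.5 * (ldV + ldX + sum(y * Py))
  v <- vector("list", k + 1L)
  for (i in seq_len(k)) v[[i]] <- drop(Vlist[[i]] %*% Py)
  v[[k + 1L]] <- Py
  Pv <- lapply(v, function(z) drop(P %*% z))
  score <- numeric(k + 1L)
  AI <- matrix(0, k + 1L, k + 1L)
  for (i in seq_len(k + 1L)) {
    trPVi <- if (i <= k) sum(P * Vlist[[i]]) else sum(diag(P))
    yPViPy <- sum(Py * v[[i]])
    score[i] <- -0.5 * (trPVi - yPViPy)
    for (j in i:(k + 1L)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(v[[i]] * Pv[[j]])
    }
  }
  beta <- drop(XtViX_inv %*% crossprod(VinvX, y))
  list(ll = ll, P = P, Py = Py, score = score, AI = AI, beta = beta,
       XtViX_inv = XtViX_inv)
}

# qlev: effective level counts used by the EM step (one per random term,
# residual term last).
reml_engine <- function(y, X, Vlist, qlev, varcomp = NULL, init = NULL,
                        max_iter = 200L, ll_tol = 1e-8, par_tol = 1e-6,
                        verbose = FALSE) {
  n <- length(y); k <- length(Vlist)
  X <- as.matrix(X)
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) {
    abort("response has zero variance: variance components are unidentifiable",
          class = "hapblup_degenerate_error")
  }
  lb <- 1e-8 * vy
  fixed <- !is.null(varcomp)
  theta <- if (fixed) as.numeric(varcomp) else
    (init %||% rep(vy / (k + 1L), k + 1L))
  theta <- pmax(theta, lb)
  trajectory <- numeric(0)
  ev <- reml_eval(y, X, Vlist, theta)
  trajectory <- ev$ll
  converged <- fixed
  iters <- 0L
  if (!fixed) {
    for (it in seq_len(max_iter)) {
      iters <- it
      # components pinned at the lower bound whose score pushes them further
      # down are frozen out of this update (active-set treatment)
      free <- !(theta <= lb * (1 + 1e-6) & ev$score < 0)
      if (!any(free)) { converged <- TRUE; break }
      em_step <- function() {
        out <- theta
        out[free] <- theta[free] + theta[free]^2 * (2 * ev$score[free]) / qlev[free]
        out
      }
      if (it == 1L) {
        theta_new <- em_step()
      } else {
        delta_f <- tryCatch(
          solve(ev$AI[free, free, drop = FALSE], ev$score[free]),
          error = function(e) NULL)
        if (is.null(delta_f)) {
          theta_new <- em_step()
        } else {
          delta <- rep(0, length(theta)); delta[free] <- delta_f
          step <- 1
          repeat {
            theta_new <- theta + step * delta
            if (all(theta_new > 0) || step < 1e-4) break
            step <- step / 2
          }
          if (any(theta_new <= 0)) theta_new <- em_step()
        }
      }
      theta_new <- pmax(theta_new, lb)
      ev_new <- reml_eval(y, X, Vlist, theta_new)
      # step-halve an AI move that worsened the restricted likelihood
      tries <- 0L
      while (ev_new$ll < ev$ll - 1e-10 && tries < 10L) {
        theta_new <- pmax((theta + theta_new) / 2, lb)
        ev_new <- reml_eval(y, X, Vlist, theta_new)
        tries <- tries + 1L
      }
      d_ll <- abs(ev_new$ll - ev$ll) / (abs(ev$ll) + 1)
      d_th <- max(abs(theta_new - theta)) / vy
      theta <- theta_new; ev <- ev_new
      trajectory <- c(trajectory, ev$ll)
      if (verbose) message(sprintf("it %d ll %.6f theta %s", it, ev$ll,
                                   paste(signif(theta, 4), collapse = " ")))
      if (d_ll < ll_tol && d_th < par_tol) { converged <- TRUE; break }
    }
    if (!converged) {
      abort(paste0("REML did not converge in ", max_iter,
                   " iterations; restricted log-likelihood trajectory: ",
                   paste(signif(utils::tail(trajectory, 8), 6), collapse = " -> ")),
            class = "hapblup_convergence_error")
    }
  }
  at_bound <- theta <= lb * (1 + 1e-6)
  list(theta = theta, loglik = ev$ll, beta = ev$beta, P = ev$P, Py = ev$Py,
       XtViX_inv = ev$XtViX_inv, converged = converged, iterations = iters,
       trajectory = trajectory, at_bound = at_bound, lower_bound = lb)
}
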