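#' Maximum-likelihood discrepancy between sample and implied covariances
#'
#' `F_ML = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p`, the normal-theory
#' covariance-structure discrepancy. Non-negative, zero iff `Sigma = S`.
#'
#' @param S Sample covariance matrix (symmetric positive definite).
#' @param Sigma Model-implied covariance matrix (same dimension).
#' @return The scalar discrepancy.
#' @examples
#' S <- matrix(c(2, 1, 1, 2), 2)
#' fml(S, diag(2))   # 2 - log(3)
#' @export
fml <- function(S, Sigma) {
  p <- nrow(S)
  stopifnot(nrow(Sigma) == p)
  cS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite; check the data"))
  cSig <- tryCatch(chol(Sigma), error = function(e)
    stop("implied covariance is not positive definite"))
  ldetS <- 2 * sum(log(diag(cS)))
  ldetSig <- 2 * sum(log(diag(cSig)))
  ldetSig + sum(diag(chol2inv(cSig) %*% S)) - ldetS - p
}

# Objective and analytic gradient over the free-parameter vector.
# Returns a big finite value at non-PD trial points so the optimizer can
# backtrack.
.make_objective <- function(tmpl, sampS) {
  p <- nrow(sampS)
  cS <- chol(sampS)
  ldetS <- 2 * sum(log(diag(cS)))
  Fm <- tmpl$F
  nv <- length(tmpl$vars)
  I_nv <- diag(nv)
  obj <- function(theta) {
    m <- ram_fill(tmpl, theta)
    B <- tryCatch(solve(I_nv - m$A), error = function(e) NULL)
    if (is.null(B)) return(1e10)
    V <- B %*% m$S %*% t(B)
    Sig <- Fm %*% V %*% t(Fm)
    Sig <- (Sig + t(Sig)) / 2
    cSig <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(cSig)) return(1e10)
    2 * sum(log(diag(cSig))) + sum(diag(chol2inv(cSig) %*% sampS)) -
      ldetS - p
  }
  grad <- function(theta) {
    m <- ram_fill(tmpl, theta)
    B <- tryCatch(solve(I_nv - m$A), error = function(e) NULL)
    if (is.null(B)) return(rep(0, tmpl$n_free))
    V <- B %*% m$S %*% t(B)
    Sig <- Fm %*% V %*% t(Fm)
    Sig <- (Sig + t(Sig)) / 2
    cSig <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(cSig)) return(rep(0, tmpl$n_free))
    Siginv <- chol2inv(cSig)
    W <- Siginv - Siginv %*% sampS %*% Siginv          # dF/dSigma
    FtWF <- t(Fm) %*% W %*% Fm
    GS <- t(B) %*% FtWF %*% B                          # dF/dS entries
    MA <- B %*% m$S %*% t(B) %*% FtWF %*% B            # for A entries
    g <- numeric(tmpl$n_free)
    ia <- which(tmpl$Afree != 0L, arr.ind = TRUE)
    if (nrow(ia))
      g[tmpl$Afree[ia]] <- g[tmpl$Afree[ia]] + 2 * MA[cbind(ia[, 2], ia[, 1])]
    is <- which(tmpl$Sfree != 0L & upper.tri(tmpl$Sfree, diag = TRUE),
                arr.ind = TRUE)
    for (r in seq_len(nrow(is))) {
      i <- is[r, 1]; j <- is[r, 2]
      g[tmpl$Sfree[i, j]] <- g[tmpl$Sfree[i, j]] +
        if (i == j) GS[i, i] else 2 * GS[i, j]
    }
    g
  }
  list(obj = obj, grad = grad)
}

# Spec start values: free loadings 0.5, paths 0, variances = observed sample
# variances (latent variance 0.05 x reference-indicator variance); covariances
# between observed exogenous variables start at their sample values, pairs
# involving a latent at 0.
.start_values <- function(model, tmpl, sampS) {
  theta <- numeric(tmpl$n_free)
  v_obs <- diag(sampS)
  for (k in seq_len(tmpl$n_free)) {
    lab <- tmpl$labels[k]
    kind <- tmpl$kind[k]
    if (kind == "loading") theta[k] <- 0.5
    else if (kind == "path") theta[k] <- 0
    else if (kind %in% c("variance", "residual")) {
      v <- sub("~~.*$", "", lab)
      if (v %in% names(model$latents)) {
        ref <- model$latents[[v]][1]
        theta[k] <- 0.05 * v_obs[ref]
      } else theta[k] <- v_obs[v]
    } else {  # covariance
      pr <- strsplit(lab, "~~", fixed = TRUE)[[1]]
      theta[k] <- if (all(pr %in% rownames(sampS))) sampS[pr[1], pr[2]] else 0
    }
  }
  theta
}

# Exact ML solution for latent-free recursive models whose exogenous block is
# saturated and whose disturbances are uncorrelated: per-equation least
# squares on the sample covariance plus moment estimates of the exogenous
# block (the classical recursive-system ML equivalence).
.closed_form_applicable <- function(model, tmpl) {
  if (length(model$latents)) return(FALSE)
  exo <- model$exogenous
  # every exogenous pair must covary freely
  if (length(exo) > 1) {
    for (a in seq_along(exo)) for (b in seq_len(a - 1L))
      if (tmpl$Sfree[exo[a], exo[b]] == 0L) return(FALSE)
  }
  # no free covariance may involve an endogenous variable
  covs <- which(tmpl$Sfree != 0L & upper.tri(tmpl$Sfree), arr.ind = TRUE)
  if (nrow(covs)) {
    nm <- rownames(tmpl$Sfree)
    for (r in seq_len(nrow(covs)))
      if (!(nm[covs[r, 1]] %in% exo) || !(nm[covs[r, 2]] %in% exo))
        return(FALSE)
  }
  TRUE
}

.closed_form_solve <- function(model, tmpl, sampS) {
  theta <- numeric(tmpl$n_free)
  exo <- model$exogenous
  for (v in exo) theta[tmpl$Sfree[v, v]] <- sampS[v, v]
  if (length(exo) > 1)
    for (a in seq_along(exo)) for (b in seq_len(a - 1L))
      theta[tmpl$Sfree[exo[a], exo[b]]] <- sampS[exo[a], exo[b]]
  for (y in names(model$regressions)) {
    xs <- model$regressions[[y]]
    beta <- solve(sampS[xs, xs, drop = FALSE], sampS[xs, y])
    for (i in seq_along(xs))
      theta[tmpl$Afree[y, xs[i]]] <- beta[i]
    theta[tmpl$Sfree[y, y]] <-
      sampS[y, y] - drop(crossprod(sampS[xs, y], beta))
  }
  theta
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimises the normal-theory discrepancy [fml()] over the model's free
#' parameters (RAM parameterization) and returns estimates, standard errors,
#' the standardized solution, fit indices, R-squared per endogenous variable
#' and convergence diagnostics. The chi-square statistic uses the
#' `(N - 1) * F_ML` convention; the sample covariance uses denominator
#' `N - 1` with listwise deletion.
#'
#' For recursive latent-free models with a saturated exogenous block and
#' uncorrelated disturbances the ML optimum coincides with per-equation least
#' squares; `engine = "auto"` (default) solves those models in closed form
#' and verifies the gradient, while `engine = "iterative"` always runs the
#' quasi-Newton optimizer from the documented start values.
#'
#' @param model A [parse_model()] `path_model`.
#' @param data A data frame containing the model's observed variables
#'   (ignored when `sample_cov` is given).
#' @param sample_cov Optional sample covariance matrix over the observed
#'   variables (requires `n`).
#' @param n Sample size when fitting from `sample_cov`.
#' @param engine `"auto"` or `"iterative"`.
#' @param min_n Minimum listwise-complete sample size (default 50; ignored
#'   when fitting from `sample_cov`).
#' @param se Compute standard errors from the inverse information matrix,
#'   `Var(theta) = (2 / (N - 1)) H^-1` with `H` the Hessian of `F_ML`?
#' @param max_iter Iteration cap for the optimizer.
#' @return An object of class `msem_fit`.
#' @export
fit_ml <- function(model, data = NULL, sample_cov = NULL, n = NULL,
                   engine = c("auto", "iterative"), min_n = 50, se = TRUE,
                   max_iter = 1000L) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "path_model"))
  tmpl <- ram_template(model)
  obs <- tmpl$observed
  if (is.null(sample_cov)) {
    if (is.null(data)) stop("supply either data or sample_cov")
    missing_cols <- setdiff(obs, names(data))
    if (length(missing_cols))
      stop("data lacks model variable(s): ",
           paste(missing_cols, collapse = ", "))
    X <- data[, obs, drop = FALSE]
    X <- X[stats::complete.cases(X), , drop = FALSE]
    n <- nrow(X)
    if (n <= length(obs))
      stop("need more listwise-complete rows (", n, ") than observed ",
           "variables (", length(obs), ")")
    if (n < min_n)
      stop("only ", n, " listwise-complete rows; below the floor of ", min_n)
    sampS <- stats::cov(as.matrix(X))
  } else {
    if (is.null(n)) stop("n is required with sample_cov")
    sampS <- as.matrix(sample_cov)
    if (is.null(rownames(sampS)) && nrow(sampS) == length(obs))
      dimnames(sampS) <- list(obs, obs)
    missing_cols <- setdiff(obs, rownames(sampS))
    if (length(missing_cols))
      stop("sample_cov lacks model variable(s): ",
           paste(missing_cols, collapse = ", "))
    sampS <- sampS[obs, obs]
  }
  sampS <- (sampS + t(sampS)) / 2
  p <- length(obs)
  fobj <- .make_objective(tmpl, sampS)
  lower <- rep(-Inf, tmpl$n_free)
  lower[tmpl$kind %in% c("variance", "residual")] <-
    1e-8 * max(diag(sampS))
  closed <- engine == "auto" && .closed_form_applicable(model, tmpl)
  iterations <- 0L
  if (closed) {
    theta <- .closed_form_solve(model, tmpl, sampS)
    gnorm <- sqrt(sum(fobj$grad(theta)^2))
    converged <- TRUE
    if (gnorm > 1e-6) {  # fall back, should not happen
      closed <- FALSE
    }
  }
  if (!closed) {
    theta0 <- .start_values(model, tmpl, sampS)
    opt <- stats::nlminb(theta0, fobj$obj, fobj$grad, lower = lower,
                         control = list(iter.max = max_iter,
                                        eval.max = 5L * max_iter,
                                        rel.tol = 1e-12))
    theta <- opt$par
    iterations <- opt$iterations
    gnorm <- sqrt(sum(fobj$grad(theta)^2))
    converged <- opt$convergence == 0 || gnorm <= 1e-6
    if (!converged) {
      # PORT occasionally stalls near the optimum; restart from the current
      # point, then polish with BFGS if still short of the gradient target
      opt2 <- stats::nlminb(theta, fobj$obj, fobj$grad, lower = lower,
                            control = list(iter.max = max_iter,
                                           eval.max = 5L * max_iter,
                                           rel.tol = 1e-12))
      theta <- opt2$par
      iterations <- iterations + opt2$iterations
      gnorm <- sqrt(sum(fobj$grad(theta)^2))
      converged <- opt2$convergence == 0 || gnorm <= 1e-6
      if (!converged) {
        opt3 <- stats::optim(theta, fobj$obj, fobj$grad, method = "BFGS",
                             control = list(maxit = max_iter,
                                            reltol = 1e-14))
        if (fobj$obj(opt3$par) <= fobj$obj(theta)) theta <- opt3$par
        gnorm <- sqrt(sum(fobj$grad(theta)^2))
        converged <- gnorm <= 1e-5
      }
      opt$message <- "restarted"
    }
    if (!converged)
      warning("optimizer did not converge (", opt$message,
              "); gradient norm ", format(gnorm))
  }
  fval <- fobj$obj(theta)
  m <- ram_fill(tmpl, theta)
  nv <- length(tmpl$vars)
  B <- solve(diag(nv) - m$A)
  V <- B %*% m$S %*% t(B)
  dimnames(V) <- list(tmpl$vars, tmpl$vars)
  Sigma <- tmpl$F %*% V %*% t(tmpl$F)
  dimnames(Sigma) <- list(obs, obs)
  chi2 <- (n - 1) * fval
  df <- p * (p + 1) / 2 - tmpl$n_free
  # baseline independence model: diagonal Sigma with free variances; its ML
  # solution is diag(S) exactly, so F_b = -ln|R| in closed form
  R <- stats::cov2cor(sampS)
  chi2_b <- -(n - 1) * determinant(R, logarithm = TRUE)$modulus[1]
  df_b <- p * (p - 1) / 2
  ses_vec <- rep(NA_real_, tmpl$n_free)
  if (se) {
    H <- tryCatch(stats::optimHess(theta, fobj$obj, fobj$grad),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hi)) {
        vv <- (2 / (n - 1)) * diag(Hi)
        ses_vec <- sqrt(pmax(vv, 0))
      }
    }
  }
  sds <- sqrt(pmax(diag(V), 0))
  params <- data.frame(
    label = tmpl$labels, kind = tmpl$kind, est = theta, se = ses_vec,
    stringsAsFactors = FALSE)
  params$z <- params$est / params$se
  params$p <- 2 * stats::pnorm(-abs(params$z))
  fit <- structure(list(
    model = model, template = tmpl, vars = tmpl$vars, observed = obs,
    n = n, S = sampS, A = m$A, Smat = m$S, Sigma = Sigma, V = V,
    sds = sds, fml = fval, chi2 = chi2, df = df,
    chi2_baseline = chi2_b, df_baseline = df_b,
    params = params, converged = converged, grad_norm = gnorm,
    iterations = iterations,
    engine = if (closed) "closed-form" else "iterative"),
    class = "msem_fit")
  fit$params$std <- .standardized_estimates(fit)
  fit$indices <- fit_indices(fit)
  fit$r2 <- r_squared(fit)
  fit
}

#' @export
print.msem_fit <- function(x, ...) {
  cat("Structural equation model fit (ML", paste0(", ", x$engine), ")\n",
      sep = "")
  cat(sprintf("  n = %d, F_ML = %.6g, chi2 = %.3f, df = %d\n",
              x$n, x$fml, x$chi2, x$df))
  idx <- x$indices
  cat(sprintf("  CFI = %.3f  IFI = %.3f  NFI = %.3f  RMSEA = %.3f%s\n",
              idx["CFI"], idx["IFI"], idx["NFI"], idx["RMSEA"],
              if (isTRUE(attr(idx, "acceptable"))) "  (acceptable)" else ""))
  if (!x$converged) cat("  ** NOT CONVERGED **\n")
  pr <- x$params[x$params$kind %in% c("loading", "path"), ]
  if (nrow(pr)) {
    cat("  paths and loadings (est [std]):\n")
    for (i in seq_len(nrow(pr)))
      cat(sprintf("    %-34s %8.4f [%7.4f]\n",
                  pr$label[i], pr$est[i], pr$std[i]))
  }
  invisible(x)
}

#' Covariance-structure fit indices
#'
#' Computes NFI, IFI, CFI and RMSEA from the fitted model's chi-square and a
#' baseline independence model (all covariances fixed to zero, variances
#' free), and flags acceptability at the conventional thresholds
#' (CFI/IFI/NFI >= 0.90, RMSEA <= 0.08).
#'
#' @param fit An `msem_fit`, or a list/vector with elements `chi2`, `df`,
#'   `chi2_baseline`, `df_baseline`, `n`.
#' @return Named numeric vector `CFI`, `IFI`, `NFI`, `RMSEA` with attributes
#'   `acceptable` (all four thresholds met) and `flags` (per-index).
#' @examples
#' fit_indices(list(chi2 = 100, df = 40, chi2_baseline = 1000,
#'                  df_baseline = 45, n = 401))
#' @export
fit_indices <- function(fit) {
  chi2 <- fit$chi2; df <- fit$df
  chi2_b <- fit$chi2_baseline; df_b <- fit$df_baseline; n <- fit$n
  nfi <- (chi2_b - chi2) / chi2_b
  ifi <- (chi2_b - chi2) / (chi2_b - df)
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)
  rmsea <- if (df == 0) {
    0  # saturated model: RMSEA undefined, reported 0
  } else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  out <- c(CFI = cfi, IFI = ifi, NFI = nfi, RMSEA = rmsea)
  flags <- c(CFI = cfi >= 0.90, IFI = ifi >= 0.90, NFI = nfi >= 0.90,
             RMSEA = rmsea <= 0.08)
  attr(out, "flags") <- flags
  attr(out, "acceptable") <- all(flags)
  if (df == 0) attr(out, "note") <- "saturated model (df = 0)"
  out
}

# Standardized estimate for every parameter: paths/loadings scaled by
# implied SD(predictor)/SD(outcome); covariances to correlations; variances
# to proportions of implied variance.
.standardized_estimates <- function(fit) {
  tmpl <- fit$template
  sds <- fit$sds
  if (any(sds == 0))
    stop("standardization error: zero implied variance for ",
         paste(tmpl$vars[sds == 0], collapse = ", "))
  std <- numeric(tmpl$n_free)
  ia <- which(tmpl$Afree != 0L, arr.ind = TRUE)
  if (nrow(ia))
    std[tmpl$Afree[ia]] <- fit$A[ia] * sds[ia[, 2]] / sds[ia[, 1]]
  is <- which(tmpl$Sfree != 0L & upper.tri(tmpl$Sfree, diag = TRUE),
              arr.ind = TRUE)
  for (r in seq_len(nrow(is))) {
    i <- is[r, 1]; j <- is[r, 2]
    std[tmpl$Sfree[i, j]] <- fit$Smat[i, j] / (sds[i] * sds[j])
  }
  std
}

#' Standardized solution of a fitted model
#'
#' @param fit A converged `msem_fit`.
#' @return Data frame of parameters with the `std` column: path and loading
#'   coefficients on the fully standardized (unit-variance) scale,
#'   covariances as correlations, variances as proportions of implied
#'   variance.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "msem_fit"))
  fit$params[, c("label", "kind", "est", "std")]
}

#' R-squared per endogenous variable
#'
#' `R^2(y) = 1 - (disturbance or unique variance) / implied variance`.
#'
#' @param fit An `msem_fit`.
#' @return Named numeric vector over structural outcomes and indicators.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "msem_fit"))
  endo <- c(fit$model$endogenous_structural,
            unlist(fit$model$latents, use.names = FALSE))
  endo <- intersect(fit$vars, endo)
  out <- vapply(endo, function(v)
    1 - fit$Smat[v, v] / fit$V[v, v], 0)
  out
}

# Standardized path/loading matrix over all variables (latents included).
std_path_matrix <- function(fit) {
  sds <- fit$sds
  Astd <- fit$A * outer(1 / sds, sds)
  dimnames(Astd) <- list(fit$vars, fit$vars)
  Astd
}
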