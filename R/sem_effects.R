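#' Direct, indirect and total effects from a path-coefficient matrix
#'
#' For a recursive standardized path matrix `A` (`A[i, j]` = path j -> i),
#' the total-effect matrix is `T = (I - A)^-1 - I`; the direct effect of a
#' predictor on the outcome is the corresponding entry of `A` and the
#' indirect effect the difference. Exact additivity
#' `total = direct + indirect` holds by construction.
#'
#' @param A Square path matrix with variable dimnames.
#' @param outcome Outcome variable name.
#' @param predictors Optional predictor ordering; defaults to every variable
#'   with a nonzero total effect on the outcome.
#' @return Data frame `predictor`, `direct`, `indirect`, `total` of class
#'   `effects_table`.
#' @examples
#' A <- matrix(0, 3, 3, dimnames = rep(list(c("x", "m", "y")), 2))
#' A["m", "x"] <- 0.5; A["y", "m"] <- 0.4; A["y", "x"] <- 0.3
#' path_effects(A, "y")
#' @export
path_effects <- function(A, outcome, predictors = NULL) {
  vars <- rownames(A)
  if (is.null(vars)) stop("A needs dimnames")
  if (!outcome %in% vars) stop("outcome '", outcome, "' not in the model")
  total_mat <- solve(diag(nrow(A)) - A) - diag(nrow(A))
  total <- total_mat[outcome, ]
  direct <- A[outcome, ]
  if (is.null(predictors))
    predictors <- vars[vars != outcome & (total != 0 | direct != 0)]
  out <- data.frame(predictor = predictors,
                    direct = unname(direct[predictors]),
                    indirect = unname(total[predictors] - direct[predictors]),
                    total = unname(total[predictors]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("effects_table", "data.frame"), outcome = outcome)
}

#' Effect decomposition of a fitted structural model
#'
#' Standardized direct, indirect (through all mediating paths) and total
#' effects of each predictor on the outcome, from the fitted standardized
#' path matrix. Rows default to the outcome equation's predictors in model
#' order (the mediator last).
#'
#' @param fit An `msem_fit`.
#' @param outcome Outcome variable (default `"mets_severity"` when present,
#'   otherwise the last structural outcome).
#' @param predictors Optional predictor ordering.
#' @return An `effects_table` data frame.
#' @export
decompose_effects <- function(fit, outcome = NULL, predictors = NULL) {
  stopifnot(inherits(fit, "msem_fit"))
  if (is.null(outcome)) {
    outs <- fit$model$endogenous_structural
    outcome <- if ("mets_severity" %in% outs) "mets_severity"
               else outs[length(outs)]
  }
  if (!outcome %in% fit$model$endogenous_structural)
    stop("outcome '", outcome, "' is not endogenous in the model")
  if (is.null(predictors)) {
    direct_preds <- fit$model$regressions[[outcome]]
    Astd <- std_path_matrix(fit)
    total <- (solve(diag(nrow(Astd)) - Astd) - diag(nrow(Astd)))[outcome, ]
    others <- setdiff(names(total)[total != 0], c(direct_preds, outcome))
    others <- setdiff(others, unlist(fit$model$latents))  # not indicators
    predictors <- c(direct_preds, others)
  }
  path_effects(std_path_matrix(fit), outcome, predictors)
}

#' @export
print.effects_table <- function(x, digits = 3, ...) {
  cat("Standardized effects on", attr(x, "outcome") %||% "outcome")
  if (!is.null(attr(x, "sex"))) cat(" (", attr(x, "sex"), ")", sep = "")
  cat("\n")
  print.data.frame(cbind(x[1], round(x[-1], digits)), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap inference for direct/indirect/total effects
#'
#' Nonparametric case resampling: rows are resampled with replacement `B`
#' times, the model is refitted and the effect decomposition recomputed.
#' Percentile 95% confidence intervals; the two-sided p-value is the smallest
#' level at which the percentile interval excludes zero,
#' `p = 2 min(Pr*(effect <= 0), Pr*(effect >= 0))`. Non-converged replicates
#' are dropped and counted.
#'
#' @param model A `path_model`.
#' @param table Data frame with the model's observed variables.
#' @param B Number of bootstrap replicates (>= 100; default 2000).
#' @param seed Mandatory RNG seed for reproducibility.
#' @param outcome Outcome passed to [decompose_effects()].
#' @param conf Confidence level (default 0.95).
#' @param strict Escalate the >20% non-convergence warning to an error?
#' @param engine Fitting engine passed to [fit_ml()].
#' @return The point-estimate `effects_table` augmented with `ci_low`,
#'   `ci_high` and `p` per effect type (columns `direct_ci_low`, ...,
#'   `total_p`), with attributes `B`, `dropped`.
#' @export
bootstrap_effects <- function(model, table, B = 2000L, seed,
                              outcome = NULL, conf = 0.95, strict = FALSE,
                              engine = "auto") {
  if (missing(seed)) stop("seed is mandatory for bootstrap_effects")
  if (B < 100L) stop("B must be at least 100")
  fit0 <- fit_ml(model, table, engine = engine)
  eff0 <- decompose_effects(fit0, outcome = outcome)
  obs <- fit0$observed
  X <- table[stats::complete.cases(table[, obs, drop = FALSE]), obs,
             drop = FALSE]
  n <- nrow(X)
  set.seed(seed)
  draws <- array(NA_real_, c(B, nrow(eff0), 3L),
                 dimnames = list(NULL, eff0$predictor,
                                 c("direct", "indirect", "total")))
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(suppressWarnings(
      fit_ml(model, X[idx, , drop = FALSE], engine = engine, se = FALSE)),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged) { dropped <- dropped + 1L; next }
    eb <- decompose_effects(fb, outcome = attr(eff0, "outcome"),
                            predictors = eff0$predictor)
    draws[b, , ] <- as.matrix(eb[, c("direct", "indirect", "total")])
  }
  if (dropped > 0.2 * B) {
    msg <- paste0(dropped, "/", B, " bootstrap replicates failed to converge")
    if (strict) stop(msg) else warning(msg)
  }
  alpha <- (1 - conf) / 2
  for (ty in c("direct", "indirect", "total")) {
    m <- draws[, , ty, drop = FALSE]
    ci_lo <- apply(m, 2, stats::quantile, probs = alpha, na.rm = TRUE)
    ci_hi <- apply(m, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
    pv <- apply(m, 2, function(z) {
      z <- z[!is.na(z)]
      if (!length(z)) return(NA_real_)
      min(1, 2 * min(mean(z <= 0), mean(z >= 0)))
    })
    eff0[[paste0(ty, "_ci_low")]] <- unname(ci_lo)
    eff0[[paste0(ty, "_ci_high")]] <- unname(ci_hi)
    eff0[[paste0(ty, "_p")]] <- unname(pv)
  }
  attr(eff0, "B") <- B
  attr(eff0, "dropped") <- dropped
  attr(eff0, "conf") <- conf
  eff0
}
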