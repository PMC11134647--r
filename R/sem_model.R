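# Model mini-language:
#   latent =~ ind1 + ind2 + ind3     measurement equation
#   y ~ x1 + x2                      structural regression
#   x1 ~~ x2                         covariance between exogenous variables
#   # comment                        (also trailing comments)
# Statements are separated by newlines or semicolons.

#' Parse a structural model specification
#'
#' Parses the package's plain-text model mini-language (`=~` measurement,
#' `~` regression, `~~` covariance, `#` comments) into a validated
#' `path_model`. The regression graph must be recursive (acyclic); every
#' latent gets its first listed indicator's loading fixed to 1 for
#' identification, with the latent variance left free. Unless
#' `auto_cov = FALSE`, all pairs of exogenous variables (including exogenous
#' latents) covary freely, matching the conventional path-diagram default.
#'
#' @param spec Model syntax: a single string, a character vector of lines, or
#'   a file path (when `file = TRUE`).
#' @param auto_cov Automatically covary all exogenous variables?
#' @param file Treat `spec` as a path to read?
#' @return An object of class `path_model`.
#' @examples
#' m <- parse_model("
#'   obesity =~ bmi + wc + bfm
#'   sleep_duration ~ age + obesity
#'   mets_severity ~ age + obesity + sleep_duration
#' ")
#' m
#' @export
parse_model <- function(spec, auto_cov = TRUE, file = FALSE) {
  if (file) spec <- readLines(spec, warn = FALSE)
  lines <- unlist(strsplit(paste(spec, collapse = "\n"), "[\n;]"))
  lines_raw <- sub("#.*$", "", lines)
  latents <- list(); regressions <- list(); covariances <- list()
  order_seen <- character(0)
  note <- function(v) order_seen <<- union(order_seen, v)
  check_name <- function(tok, i) {
    if (!grepl("^[A-Za-z.][A-Za-z0-9._]*$", tok))
      stop("parse error at line ", i, ": invalid variable name '", tok, "'")
    tok
  }
  split_rhs <- function(rhs, i) {
    toks <- trimws(unlist(strsplit(rhs, "\\+")))
    toks <- toks[toks != ""]
    if (!length(toks)) stop("parse error at line ", i, ": empty right side")
    vapply(toks, check_name, "", i = i, USE.NAMES = FALSE)
  }
  for (i in seq_along(lines_raw)) {
    ln <- trimws(lines_raw[i])
    if (ln == "") next
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("parse error at line ", i, ": ", ln)
      lhs <- check_name(trimws(parts[1]), i)
      rhs <- split_rhs(parts[2], i)
      if (length(rhs) < 3)
        warning("latent '", lhs, "' has fewer than 3 indicators")
      latents[[lhs]] <- union(latents[[lhs]], rhs)
      note(c(lhs, rhs))
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "~~", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("parse error at line ", i, ": ", ln)
      lhs <- check_name(trimws(parts[1]), i)
      rhs <- split_rhs(parts[2], i)
      for (r in rhs) covariances[[length(covariances) + 1L]] <- c(lhs, r)
      note(c(lhs, rhs))
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "~", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("parse error at line ", i, ": ", ln)
      lhs <- check_name(trimws(parts[1]), i)
      rhs <- split_rhs(parts[2], i)
      regressions[[lhs]] <- c(regressions[[lhs]], rhs)
      note(c(lhs, rhs))
    } else {
      stop("parse error at line ", i, ": ", ln)
    }
  }
  if (!length(regressions) && !length(latents))
    stop("model contains no equations")
  # cycle check on the structural (regression) graph
  cyc <- .find_cycle(regressions)
  if (!is.null(cyc))
    stop("model is not recursive; cycle: ", paste(cyc, collapse = " -> "))
  all_vars <- order_seen
  observed <- setdiff(all_vars, names(latents))
  indicators <- unlist(latents, use.names = FALSE)
  if (any(indicators %in% names(latents)))
    stop("higher-order latents (latent indicators) are not supported")
  endogenous <- union(names(regressions), indicators)
  exogenous <- setdiff(all_vars, endogenous)
  if (auto_cov && length(exogenous) > 1) {
    have <- vapply(covariances, function(p) paste(sort(p), collapse = "\r"), "")
    for (a in seq_along(exogenous)) for (b in seq_len(a - 1L)) {
      pr <- c(exogenous[b], exogenous[a])
      if (!paste(sort(pr), collapse = "\r") %in% have)
        covariances[[length(covariances) + 1L]] <- pr
    }
  }
  structure(list(
    latents = latents, regressions = regressions, covariances = covariances,
    variables = all_vars, observed = observed, exogenous = exogenous,
    endogenous_structural = names(regressions), auto_cov = auto_cov),
    class = "path_model")
}

# Kahn topological sort over outcome <- predictor edges; returns NULL if
# acyclic, otherwise one offending cycle (found by DFS) for the error message.
.find_cycle <- function(regressions) {
  nodes <- union(names(regressions), unlist(regressions))
  if (!length(nodes)) return(NULL)
  preds <- regressions
  indeg <- vapply(nodes, function(v) {
    sum(vapply(preds, function(p) v %in% p, TRUE))
  }, 0L)
  # edges predictor -> outcome; indegree of outcome = number of predictors
  indeg <- vapply(nodes, function(v) length(preds[[v]]), 0L)
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (out in names(preds)) {
      if (v %in% preds[[out]]) {
        preds[[out]] <- setdiff(preds[[out]], v)
        if (!length(preds[[out]])) {
          queue <- c(queue, out)
          preds[[out]] <- NULL
        }
      }
    }
  }
  if (seen == length(nodes)) return(NULL)
  # locate a cycle by DFS among remaining nodes
  remaining <- setdiff(nodes, character(0))
  stack <- character(0)
  onstack <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    if (v %in% onstack) {
      i <- match(v, stack)
      found <<- c(stack[i:length(stack)], v)
      return()
    }
    stack <<- c(stack, v); onstack <<- c(onstack, v)
    for (p in regressions[[v]]) visit(p)
    stack <<- stack[-length(stack)]; onstack <<- setdiff(onstack, v)
  }
  for (v in names(regressions)) { visit(v); if (!is.null(found)) break }
  if (is.null(found)) found <- "unlocatable"
  found
}

#' @export
print.path_model <- function(x, ...) {
  cat("Structural path model\n")
  cat("  observed:", length(x$observed), " latent:", length(x$latents), "\n")
  for (l in names(x$latents))
    cat("  ", l, "=~", paste(x$latents[[l]], collapse = " + "), "\n")
  for (y in names(x$regressions))
    cat("  ", y, "~", paste(x$regressions[[y]], collapse = " + "), "\n")
  cat("  free exogenous covariances:", length(x$covariances), "\n")
  invisible(x)
}

#' The packaged default sleep-mediation model
#'
#' Latent obesity measured by BMI, waist circumference and body fat mass;
#' every exogenous predictor (age, SES, physical activity, obesity, sleep
#' latency, nap duration, night shift) has a path to sleep duration and to
#' MetS severity; sleep duration has a path to MetS severity; exogenous
#' variables covary freely.
#'
#' @return A `path_model`.
#' @export
default_model <- function() {
  parse_model(system.file("models", "mets_default.txt", package = "metsem"),
              file = TRUE)
}

# --- RAM parameterization -------------------------------------------------

# Builds the fixed/free template for the model: variable ordering (latents
# first), asymmetric matrix A (loadings + paths), symmetric matrix S
# (variances/covariances), observed filter F, and the free-parameter index
# map. Entries of `Afree`/`Sfree` give the parameter index or 0 if fixed.
ram_template <- function(model) {
  vars <- c(names(model$latents), setdiff(model$variables,
                                          names(model$latents)))
  nv <- length(vars)
  A <- matrix(0, nv, nv, dimnames = list(vars, vars))
  Afree <- matrix(0L, nv, nv, dimnames = list(vars, vars))
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  Sfree <- matrix(0L, nv, nv, dimnames = list(vars, vars))
  labels <- character(0); kind <- character(0)
  k <- 0L
  new_par <- function(lab, what) {
    k <<- k + 1L; labels[k] <<- lab; kind[k] <<- what; k
  }
  for (l in names(model$latents)) {
    inds <- model$latents[[l]]
    A[inds[1], l] <- 1  # reference indicator
    for (ind in inds[-1])
      Afree[ind, l] <- new_par(paste0(l, "=~", ind), "loading")
  }
  for (y in names(model$regressions))
    for (x in model$regressions[[y]])
      Afree[y, x] <- new_par(paste0(y, "~", x), "path")
  for (v in vars)
    Sfree[v, v] <- new_par(paste0(v, "~~", v),
                           if (v %in% model$exogenous) "variance"
                           else "residual")
  for (pr in model$covariances) {
    if (Sfree[pr[1], pr[2]] == 0L) {
      id <- new_par(paste0(pr[1], "~~", pr[2]), "covariance")
      Sfree[pr[1], pr[2]] <- id
      Sfree[pr[2], pr[1]] <- id
    }
  }
  observed <- intersect(vars, model$observed)
  Fm <- matrix(0, length(observed), nv,
               dimnames = list(observed, vars))
  Fm[cbind(observed, observed)] <- 1
  list(vars = vars, observed = observed, A = A, Afree = Afree,
       S = S, Sfree = Sfree, F = Fm, labels = labels, kind = kind,
       n_free = k)
}

# Fill A and S from a parameter vector.
ram_fill <- function(tmpl, theta) {
  A <- tmpl$A; S <- tmpl$S
  ia <- which(tmpl$Afree != 0L)
  A[ia] <- theta[tmpl$Afree[ia]]
  is <- which(tmpl$Sfree != 0L)
  S[is] <- theta[tmpl$Sfree[is]]
  list(A = A, S = S)
}

#' Model-implied covariance matrix of the observed variables
#'
#' Evaluates the RAM identity `Sigma = F (I - A)^-1 S (I - A)^-T F'` for
#' given path/loading matrix `A`, covariance matrix `S` and observed-variable
#' filter `F`.
#'
#' @param A Square asymmetric matrix of loadings and regression paths
#'   (`A[i, j]` is the path j -> i).
#' @param S Symmetric matrix of exogenous variances/covariances, disturbance
#'   and unique variances.
#' @param F Observed-variable filter (rows select observed variables);
#'   defaults to the identity (all variables observed).
#' @return The implied covariance matrix over the observed variables.
#' @examples
#' A <- matrix(0, 3, 3); S <- diag(3)
#' implied_covariance(A, S)   # F S F' = S
#' @export
implied_covariance <- function(A, S, F = diag(nrow(A))) {
  IA <- diag(nrow(A)) - A
  B <- tryCatch(solve(IA), error = function(e)
    stop("(I - A) is singular; model is not recursive?"))
  V <- B %*% S %*% t(B)
  Sig <- F %*% V %*% t(F)
  (Sig + t(Sig)) / 2
}
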