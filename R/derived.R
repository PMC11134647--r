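#' Principal-component socioeconomic status index with tertile grouping
#'
#' Builds a wealth-index-style SES score: asset/education items are
#' standardized, the first principal component of their correlation matrix is
#' extracted, and the component is oriented so that a designated
#' wealth-positive anchor item loads positively (principal-component sign is
#' otherwise arbitrary). Scores are grouped into tertiles at the empirical
#' 1/3 and 2/3 quantiles using lower-closed intervals.
#'
#' @param items A numeric matrix or data frame, participants in rows, SES
#'   items in columns. Zero-variance items are dropped with a warning.
#' @param orient_item Column name or index of the anchor item whose loading is
#'   forced positive (default: the first column, conventionally education).
#' @return A list of class `ses_index` with elements `model` (item labels,
#'   standardization means/SDs, first-component loadings with unit norm,
#'   proportion of variance explained, orientation anchor, tertile cutpoints),
#'   `score` (per-participant index) and `tertile` (ordered factor
#'   `low`/`moderate`/`high`).
#' @examples
#' set.seed(1)
#' items <- matrix(rnorm(60), 20, 3,
#'                 dimnames = list(NULL, c("education", "car", "pc")))
#' ses <- ses_index(items)
#' ses$model$explained
#' @export
ses_index <- function(items, orient_item = 1L) {
  items <- as.matrix(items)
  if (is.null(colnames(items)))
    colnames(items) <- paste0("item", seq_len(ncol(items)))
  if (ncol(items) < 2L) stop("need at least 2 SES items")
  if (nrow(items) < 3L) stop("need at least 3 participants")
  storage.mode(items) <- "double"
  sds <- apply(items, 2, stats::sd)
  zero <- !is.na(sds) & sds == 0
  if (any(zero)) {
    warning("dropping zero-variance item(s): ",
            paste(colnames(items)[zero], collapse = ", "))
    items <- items[, !zero, drop = FALSE]
    sds <- sds[!zero]
    if (ncol(items) < 2L) stop("fewer than 2 items left after validation")
  }
  anchor <- if (is.character(orient_item)) orient_item
            else colnames(items)[orient_item]
  if (!anchor %in% colnames(items))
    stop("orientation item '", anchor, "' not among the items")
  mu <- colMeans(items)
  z <- scale(items, center = mu, scale = sds)
  R <- stats::cor(items)
  eig <- eigen(R, symmetric = TRUE)
  loadings <- eig$vectors[, 1L]
  names(loadings) <- colnames(items)
  flipped <- loadings[anchor] < 0
  if (flipped) loadings <- -loadings
  score <- drop(z %*% loadings)
  if (length(unique(score)) < 3L)
    stop("fewer than 3 distinct SES scores; tertiles undefined")
  cuts <- stats::quantile(score, c(1 / 3, 2 / 3), names = FALSE)
  tertile <- factor(c("low", "moderate", "high")[
    findInterval(score, cuts) + 1L],
    levels = c("low", "moderate", "high"), ordered = TRUE)
  structure(list(
    model = list(items = colnames(items), means = mu, sds = sds,
                 loadings = loadings,
                 explained = eig$values[1L] / ncol(items),
                 oriented_to = anchor, flipped = flipped,
                 cutpoints = cuts),
    score = score, tertile = tertile), class = "ses_index")
}

#' @export
print.ses_index <- function(x, ...) {
  cat("SES wealth index:", length(x$model$items), "items,",
      sprintf("first component explains %.1f%% of variance\n",
              100 * x$model$explained))
  print(round(x$model$loadings, 3))
  invisible(x)
}

#' Physical activity category from daily MET-hours
#'
#' Categorizes 24-hour activity diaries: `low` for [24, 36.5], `moderate` for
#' (36.5, 45), `vigorous` for >= 45 MET-hours/day. The printed reporting bands
#' (36.6-44.9) leave tiny gaps at (36.5, 36.6) and (44.9, 45); these are
#' closed by continuity into the moderate band. Values below 24 (impossible
#' for a full 24-hour diary, where resting alone yields 24 MET-hours) are
#' labelled `below_range` with a warning.
#'
#' @param met_hours Numeric vector of MET-hours per day (non-negative).
#' @return Factor with levels `below_range`, `low`, `moderate`, `vigorous`.
#' @examples
#' pa_category(c(30, 40, 45))
#' @export
pa_category <- function(met_hours) {
  if (any(met_hours < 0, na.rm = TRUE)) stop("met_hours must be >= 0")
  if (any(met_hours < 24, na.rm = TRUE))
    warning("met_hours below 24 labelled 'below_range' ",
            "(a 24-h diary cannot fall below resting expenditure)")
  lev <- c("below_range", "low", "moderate", "vigorous")
  idx <- findInterval(met_hours, c(24, 36.5, 45)) + 1L
  # low band is closed on the right: exactly 36.5 stays low
  idx[!is.na(met_hours) & met_hours == 36.5] <- 2L
  factor(lev[idx], levels = lev)
}

#' Skewness/kurtosis normality screen
#'
#' Computes adjusted Fisher-Pearson sample skewness (G1) and sample excess
#' kurtosis (G2) per variable and flags each as acceptably normal when
#' |skewness| <= 3 and |excess kurtosis| <= 10. A failing variable triggers a
#' warning but never aborts downstream fitting.
#'
#' @param table A data frame.
#' @param variables Character vector of numeric columns to screen.
#' @param skew_limit,kurt_limit Acceptance thresholds (defaults 3 and 10).
#' @return A data frame of class `normality_report` with per-variable `n`,
#'   `skewness`, `kurtosis`, `skew_pass`, `kurt_pass`, `pass`. Variables with
#'   fewer than 4 non-missing values are reported `NA`.
#' @export
normality_screen <- function(table, variables, skew_limit = 3,
                             kurt_limit = 10) {
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars))
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 4L)
      return(data.frame(variable = v, n = n, skewness = NA_real_,
                        kurtosis = NA_real_, skew_pass = NA, kurt_pass = NA,
                        pass = NA))
    g1 <- sample_skewness(x)
    g2 <- sample_kurtosis(x)
    sp <- abs(g1) <= skew_limit
    kp <- abs(g2) <= kurt_limit
    data.frame(variable = v, n = n, skewness = g1, kurtosis = g2,
               skew_pass = sp, kurt_pass = kp, pass = sp && kp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  failing <- out$variable[!is.na(out$pass) & !out$pass]
  if (length(failing))
    warning("variable(s) failing the normality screen: ",
            paste(failing, collapse = ", "))
  attr(out, "thresholds") <- c(skew = skew_limit, kurtosis = kurt_limit)
  class(out) <- c("normality_report", "data.frame")
  out
}

#' Adjusted Fisher-Pearson sample skewness (G1)
#' @param x Numeric vector (n >= 3).
#' @return The G1 skewness coefficient.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2); m3 <- mean(d^3)
  if (m2 == 0) return(0)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Sample excess kurtosis (G2)
#' @param x Numeric vector (n >= 4).
#' @return The G2 excess-kurtosis coefficient.
#' @export
sample_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2); m4 <- mean(d^4)
  if (m2 == 0) return(0)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}
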