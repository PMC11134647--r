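# Canonical column set for a cohort table. Mandatory columns are the ones the
# downstream severity score and structural model cannot run without.
.mandatory_cols <- c("id", "sex", "age", "bmi", "wc", "bfm",
                     "tg", "hdl", "fbs", "sbp", "sleep_duration")
.optional_cols <- c("residence", "ses", "met_hours", "sleep_latency",
                    "nap_duration", "night_shift", "energy_intake",
                    "mets", "cvd", "gestational_diabetes", "thyroid",
                    "cancer", "depression", "alcohol", "smoker", "pregnant",
                    "complete")

.numeric_cols <- c("age", "bmi", "wc", "bfm", "tg", "hdl", "fbs", "sbp",
                   "sleep_duration", "ses", "met_hours", "sleep_latency",
                   "nap_duration", "night_shift", "energy_intake")
.logical_cols <- c("mets", "cvd", "gestational_diabetes", "thyroid", "cancer",
                   "depression", "alcohol", "smoker", "pregnant", "complete")

#' Read a cohort CSV into a validated cohort table
#'
#' Reads a participant-level CSV (UTF-8, comma separated, header row, "."
#' decimal mark, empty string = missing) and returns a typed data frame with
#' the package's canonical column names. Rows whose mandatory fields fail to
#' parse are flagged incomplete via the `complete` column — they are never
#' dropped at read time, so the exclusion cascade can count them.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the column names used in the file, e.g.
#'   `c(sbp = "systolic_bp")`. Unmapped columns are matched by name.
#' @return A `data.frame` with canonical columns; numeric columns coerced to
#'   numeric, exclusion flags to logical, `sex` to a factor with levels
#'   `male`, `female`. Carries a logical `complete` column.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(generate_cohort(default_config("male", n = 5), seed = 1), tmp,
#'           row.names = FALSE)
#' head(read_cohort(tmp))
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) stop("empty cohort file: ", path)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema maps '", canon, "' to missing column '", src, "'")
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols))
    stop("cohort table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  as_cohort(raw)
}

#' Coerce a data frame to a typed cohort table
#'
#' @param df A data frame with canonical cohort columns.
#' @return The typed data frame with a `complete` flag column.
#' @export
as_cohort <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- rep(FALSE, nrow(df))
  for (col in intersect(.numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- bad | (!is.na(v) & v != "" & is.na(vn) &
                      col %in% .mandatory_cols)
      v <- vn
    }
    df[[col]] <- v
  }
  for (col in intersect(.logical_cols, names(df))) {
    v <- df[[col]]
    if (!is.logical(v)) {
      if (is.numeric(v)) v <- v != 0
      else v <- tolower(as.character(v)) %in% c("true", "t", "1", "yes")
    }
    df[[col]] <- v
  }
  if ("sex" %in% names(df)) {
    sx <- tolower(as.character(df$sex))
    sx[sx %in% c("m", "1")] <- "male"
    sx[sx %in% c("f", "2")] <- "female"
    unknown <- !is.na(sx) & !sx %in% c("male", "female")
    if (any(unknown))
      stop("sex must be 'male' or 'female'; found: ",
           paste(unique(sx[unknown]), collapse = ", "))
    df$sex <- factor(sx, levels = c("male", "female"))
  }
  # mandatory fields that are missing or unparseable mark the row incomplete
  mand_present <- intersect(setdiff(.mandatory_cols, "id"), names(df))
  miss <- Reduce(`|`, lapply(df[mand_present], is.na), rep(FALSE, nrow(df)))
  flagged <- if ("complete" %in% names(df)) df$complete & !miss & !bad
             else !miss & !bad
  flagged[is.na(flagged)] <- FALSE
  df$complete <- flagged
  df
}

#' Define an exclusion rule
#'
#' @param name Short label for the rule (used in the attrition report).
#' @param predicate A one-sided formula or quoted expression over cohort
#'   columns; rows where it evaluates `TRUE` are excluded. `NA` counts as
#'   not excluded.
#' @return An object of class `exclusion_rule`.
#' @examples
#' exclusion_rule("cvd", ~cvd)
#' exclusion_rule("energy", ~energy_intake < 500 | energy_intake >= 4200)
#' @export
exclusion_rule <- function(name, predicate) {
  expr <- if (inherits(predicate, "formula")) predicate[[2L]]
          else if (is.call(predicate) || is.name(predicate)) predicate
          else stop("predicate must be a one-sided formula or expression")
  structure(list(name = name, predicate = expr), class = "exclusion_rule")
}

#' The default ten-rule exclusion cascade
#'
#' Cardiovascular disease, gestational diabetes, thyroid disorder, cancer,
#' depression, incomplete information, inadequate energy intake (< 500 or
#' >= 4200 kcal/day), alcohol consumption, current smoking, and pregnancy —
#' applied in that order.
#'
#' @return A list of [exclusion_rule()] objects.
#' @export
default_exclusion_rules <- function() {
  list(
    exclusion_rule("cvd", ~cvd),
    exclusion_rule("gestational_diabetes", ~gestational_diabetes),
    exclusion_rule("thyroid", ~thyroid),
    exclusion_rule("cancer", ~cancer),
    exclusion_rule("depression", ~depression),
    exclusion_rule("incomplete", ~!complete),
    exclusion_rule("energy", ~energy_intake < 500 | energy_intake >= 4200),
    exclusion_rule("alcohol", ~alcohol),
    exclusion_rule("smoker", ~smoker),
    exclusion_rule("pregnant", ~pregnant)
  )
}

#' Apply an ordered exclusion cascade
#'
#' Evaluates each rule's predicate over the rows still in the study. With
#' `sequential = TRUE` (the default) a record is attributed to the first rule
#' that excludes it, so per-rule counts are non-overlapping and sum exactly to
#' `initial_n - final_n`. With `sequential = FALSE` every rule counts all rows
#' it matches, so counts may overlap (the survivor set is identical).
#'
#' @param table A cohort table.
#' @param rules A list of [exclusion_rule()] objects, in application order.
#' @param sequential Attribute each exclusion to the first matching rule?
#' @return A list with elements `table` (the surviving rows) and `report`
#'   (an `attrition_report` with `initial_n`, per-rule `excluded`, `final_n`).
#' @examples
#' fx <- attrition_fixture()
#' res <- apply_exclusions(fx, default_exclusion_rules())
#' res$report
#' @export
apply_exclusions <- function(table, rules, sequential = TRUE) {
  stopifnot(is.data.frame(table))
  if (length(rules) &&
      !all(vapply(rules, inherits, TRUE, "exclusion_rule")))
    stop("rules must be exclusion_rule objects")
  initial_n <- nrow(table)
  alive <- rep(TRUE, initial_n)
  excluded <- integer(length(rules))
  names(excluded) <- vapply(rules, `[[`, "", "name")
  for (k in seq_along(rules)) {
    expr <- rules[[k]]$predicate
    vars <- all.vars(expr)
    unknown <- setdiff(vars, names(table))
    if (length(unknown))
      stop("rule '", rules[[k]]$name, "' references unknown field(s): ",
           paste(unknown, collapse = ", "))
    hit <- eval(expr, table, parent.frame())
    hit <- rep_len(as.logical(hit), initial_n)
    hit[is.na(hit)] <- FALSE
    if (sequential) {
      hit <- hit & alive
      alive <- alive & !hit
    }
    excluded[k] <- sum(hit)
  }
  if (!sequential) {
    # survivor set is still rule-order independent
    for (k in seq_along(rules)) {
      hit <- eval(rules[[k]]$predicate, table, parent.frame())
      hit[is.na(hit)] <- FALSE
      alive <- alive & !hit
    }
  }
  report <- structure(
    list(initial_n = initial_n, excluded = excluded,
         final_n = sum(alive), sequential = sequential),
    class = "attrition_report")
  list(table = table[alive, , drop = FALSE], report = report)
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Attrition report (", if (x$sequential) "sequential" else "overlapping",
      " counting)\n", sep = "")
  cat("  initial n:", x$initial_n, "\n")
  for (nm in names(x$excluded))
    cat(sprintf("  - %-22s %6d excluded\n", nm, x$excluded[[nm]]))
  cat("  final n:  ", x$final_n, "\n")
  invisible(x)
}

#' @export
as.list.attrition_report <- function(x, ...) {
  list(initial_n = x$initial_n, excluded = as.list(x$excluded),
       final_n = x$final_n, sequential = x$sequential)
}

#' Two-sample comparison of means
#'
#' Student's pooled-variance t test (the default) or Welch's unequal-variance
#' t test. The statistic's sign follows `mean(x) - mean(y)`. When both groups
#' have zero variance the test degenerates: equal means give t = 0, p = 1 by
#' convention; unequal means give p = 0.
#'
#' @param x,y Numeric vectors, each with at least two finite values.
#' @param method `"pooled"` or `"welch"`.
#' @return A list with `statistic`, `df`, `p.value`.
#' @examples
#' compare_means(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_means <- function(x, y, method = c("pooled", "welch")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two non-missing values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2, p.value = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p.value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = (method == "pooled"))
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction;
#' `df = (nrow - 1) * (ncol - 1)`.
#'
#' @param counts A matrix of non-negative integer counts with positive row and
#'   column marginals.
#' @return A list with `chi2`, `df`, `p.value`.
#' @examples
#' compare_proportions(rbind(c(422, 1703), c(600, 1210)))
#' @export
compare_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all row and column marginals must be positive")
  if (all(counts == 0)) stop("all-zero table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}

#' Sex-stratified descriptive table
#'
#' Continuous variables are summarised as mean (sd) per sex with a two-sample
#' t-test p-value; categorical variables as n (%) per level per sex with a
#' single chi-square p-value. Percentages use the stated denominator: the sex
#' column totals for the overall sex split, the within-sex group total for
#' levels of a categorical variable.
#'
#' @param table A cohort table with a populated `sex` column.
#' @param variables Character vector of columns to summarise. Logical, factor
#'   and character columns are treated as categorical, numeric as continuous.
#' @param method t-test flavour passed to [compare_means()].
#' @return A data frame with columns `variable`, `level`, `overall`, `male`,
#'   `female` (formatted), numeric columns `male_mean`/`female_mean` or
#'   `male_pct`/`female_pct`, and `p.value`.
#' @export
describe_by_sex <- function(table, variables, method = "pooled") {
  stopifnot("sex" %in% names(table))
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars))
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  sexes <- c("male", "female")
  n_by_sex <- vapply(sexes, function(s) sum(table$sex == s, na.rm = TRUE), 0)
  both_present <- all(n_by_sex >= 2)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  # leading row: the sex split itself, percentages over the column total
  add(variable = "sex", level = sexes,
      overall = sprintf("%d (%.2f)", n_by_sex, 100 * n_by_sex / nrow(table)),
      male = c(as.character(n_by_sex[1]), ""),
      female = c("", as.character(n_by_sex[2])),
      male_pct = c(100 * n_by_sex[1] / nrow(table), NA),
      female_pct = c(NA, 100 * n_by_sex[2] / nrow(table)),
      male_mean = NA_real_, female_mean = NA_real_,
      p.value = NA_real_)
  for (v in variables) {
    col <- table[[v]]
    if (all(is.na(col))) {
      warning("variable '", v, "' is entirely missing; reported as NA")
      add(variable = v, level = NA_character_, overall = NA_character_,
          male = NA_character_, female = NA_character_,
          male_pct = NA_real_, female_pct = NA_real_,
          male_mean = NA_real_, female_mean = NA_real_, p.value = NA_real_)
      next
    }
    if (is.numeric(col)) {
      by_sex <- lapply(sexes, function(s) col[table$sex == s & !is.na(col)])
      p <- if (both_present && all(lengths(by_sex) >= 2))
        compare_means(by_sex[[1]], by_sex[[2]], method = method)$p.value
      else NA_real_
      fmt <- function(z) if (length(z)) sprintf("%.2f ± %.2f",
                                                mean(z), stats::sd(z)) else NA
      add(variable = v, level = NA_character_,
          overall = fmt(col[!is.na(col)]),
          male = fmt(by_sex[[1]]), female = fmt(by_sex[[2]]),
          male_pct = NA_real_, female_pct = NA_real_,
          male_mean = if (length(by_sex[[1]])) mean(by_sex[[1]]) else NA_real_,
          female_mean = if (length(by_sex[[2]])) mean(by_sex[[2]]) else NA_real_,
          p.value = p)
    } else {
      f <- if (is.logical(col)) factor(col, levels = c(TRUE, FALSE),
                                       labels = c("yes", "no"))
           else factor(col)
      keep <- !is.na(f) & !is.na(table$sex)
      tab <- table(f[keep], droplevels(table$sex[keep]))
      p <- if (both_present && ncol(tab) == 2 && nrow(tab) >= 2 &&
               all(rowSums(tab) > 0))
        compare_proportions(tab)$p.value else NA_real_
      tot <- table(f[!is.na(f)])
      for (lv in levels(f)) {
        nm <- if ("male" %in% colnames(tab)) tab[lv, "male"] else 0
        nf <- if ("female" %in% colnames(tab)) tab[lv, "female"] else 0
        add(variable = v, level = lv,
            overall = sprintf("%d (%.2f)", tot[[lv]],
                              100 * tot[[lv]] / sum(tot)),
            male = sprintf("%d (%.2f)", nm, 100 * nm / max(sum(tab[, colnames(tab) == "male"]), 1)),
            female = sprintf("%d (%.2f)", nf, 100 * nf / max(sum(tab[, colnames(tab) == "female"]), 1)),
            male_pct = 100 * nm / max(sum(tab[, colnames(tab) == "male"]), 1),
            female_pct = 100 * nf / max(sum(tab[, colnames(tab) == "female"]), 1),
            male_mean = NA_real_, female_mean = NA_real_,
            p.value = if (lv == levels(f)[1]) p else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
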