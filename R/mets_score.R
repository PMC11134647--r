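# Sex-specific weights of the continuous MetS severity score
# (DeBoer-style, adult sex-specific equations; TG enters on the natural-log
# scale). Units are assumed mg/dL for HDL, TG and glucose, cm for waist
# circumference, mmHg for systolic blood pressure — callers supplying other
# units get silently wrong scores.
.mets_coef <- list(
  male   = c(intercept = -5.5459, wc = 0.0135, hdl = -0.0278, sbp = 0.0054,
             log_tg = 0.8340, glucose = 0.0105),
  female = c(intercept = -7.7516, wc = 0.0162, hdl = -0.0157, sbp = 0.0084,
             log_tg = 0.8872, glucose = 0.0206)
)

#' Continuous sex-specific MetS severity score
#'
#' Weighted combination of waist circumference, HDL cholesterol, systolic
#' blood pressure, log triglycerides and fasting glucose, with sex-specific
#' weights. The score is z-score-like: higher values mean a worse metabolic
#' profile. Expected units: `wc` cm, `hdl`/`tg`/`glucose` mg/dL, `sbp` mmHg.
#'
#' @param wc Waist circumference (cm).
#' @param hdl HDL cholesterol (mg/dL).
#' @param sbp Systolic blood pressure (mmHg).
#' @param tg Triglycerides (mg/dL); must be positive (enters as natural log).
#' @param glucose Fasting glucose (mg/dL).
#' @param sex `"male"` or `"female"` (vectorized, recycled against the
#'   component vectors).
#' @return Numeric vector of severity scores; `NA` where any component is
#'   missing.
#' @examples
#' mets_severity_score(100, 50, 120, 150, 100, "male")    # 0.2910
#' mets_severity_score(100, 50, 120, 150, 100, "female")  # 0.5968
#' @export
mets_severity_score <- function(wc, hdl, sbp, tg, glucose, sex) {
  n <- max(length(wc), length(hdl), length(sbp), length(tg),
           length(glucose), length(sex))
  wc <- rep_len(wc, n); hdl <- rep_len(hdl, n); sbp <- rep_len(sbp, n)
  tg <- rep_len(tg, n); glucose <- rep_len(glucose, n)
  sex <- rep_len(as.character(sex), n)
  if (!all(sex %in% c("male", "female") | is.na(sex)))
    stop("sex must be 'male' or 'female'")
  if (any(!is.na(tg) & tg <= 0))
    stop("tg must be positive (log-transformed)")
  out <- rep(NA_real_, n)
  for (s in c("male", "female")) {
    b <- .mets_coef[[s]]
    i <- which(sex == s)
    out[i] <- b["intercept"] + b["wc"] * wc[i] + b["hdl"] * hdl[i] +
      b["sbp"] * sbp[i] + b["log_tg"] * log(tg[i]) + b["glucose"] * glucose[i]
  }
  unname(out)
}

#' Add a MetS severity column to a cohort table
#'
#' Row-wise application of [mets_severity_score()] honouring each record's
#' sex; missing components propagate to a missing score.
#'
#' @param table A cohort table with columns `wc`, `hdl`, `sbp`, `tg`, `fbs`
#'   and `sex` (fasting blood sugar `fbs` supplies the glucose component).
#' @param column Name of the output column (default `"mets_severity"`).
#' @return The table with the severity column appended.
#' @export
score_table <- function(table, column = "mets_severity") {
  need <- c("wc", "hdl", "sbp", "tg", "fbs", "sex")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing component column(s): ", paste(missing_cols, collapse = ", "))
  table[[column]] <- if (nrow(table) == 0L) numeric(0) else
    mets_severity_score(table$wc, table$hdl, table$sbp, table$tg,
                        table$fbs, as.character(table$sex))
  table
}

#' Default binary MetS criteria (assumption, not taken from the severity
#' equations)
#'
#' An NCEP-ATP-III-style rule set supplied purely as a labelled convenience:
#' elevated waist circumference (>= 102 cm men / 88 cm women), triglycerides
#' >= 150 mg/dL, low HDL (<= 40 men / 50 women mg/dL), SBP >= 130 mmHg,
#' fasting glucose >= 100 mg/dL; MetS if at least 3 criteria are met.
#' Thresholds count as met under the ">=" (or "<=" for HDL) convention.
#'
#' @return A criteria configuration list for [classify_mets()].
#' @export
default_mets_criteria <- function() {
  list(
    min_criteria = 3L,
    components = list(
      wc      = list(direction = "high", male = 102, female = 88),
      tg      = list(direction = "high", male = 150, female = 150),
      hdl     = list(direction = "low",  male = 40,  female = 50),
      sbp     = list(direction = "high", male = 130, female = 130),
      glucose = list(direction = "high", male = 100, female = 100)
    )
  )
}

#' Binary MetS classification under an explicit criteria configuration
#'
#' @param wc,hdl,sbp,tg,glucose Component vectors (units as in
#'   [mets_severity_score()]).
#' @param sex `"male"`/`"female"` vector.
#' @param criteria Criteria configuration; see [default_mets_criteria()].
#' @return Logical vector: `TRUE` when at least `criteria$min_criteria`
#'   component criteria are met. Boundary values exactly at a threshold count
#'   as meeting it.
#' @export
classify_mets <- function(wc, hdl, sbp, tg, glucose, sex,
                          criteria = default_mets_criteria()) {
  comp <- list(wc = wc, hdl = hdl, sbp = sbp, tg = tg, glucose = glucose)
  n <- max(lengths(comp), length(sex))
  comp <- lapply(comp, rep_len, n)
  sex <- rep_len(as.character(sex), n)
  unknown <- setdiff(names(criteria$components), names(comp))
  if (length(unknown))
    stop("criteria reference unknown component(s): ",
         paste(unknown, collapse = ", "))
  met <- matrix(FALSE, n, length(criteria$components))
  for (k in seq_along(criteria$components)) {
    nm <- names(criteria$components)[k]
    cr <- criteria$components[[k]]
    thr <- ifelse(sex == "male", cr$male, cr$female)
    met[, k] <- if (cr$direction == "high") comp[[nm]] >= thr
                else comp[[nm]] <= thr
  }
  rowSums(met) >= criteria$min_criteria
}
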