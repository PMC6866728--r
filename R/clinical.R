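# Linking ROI grey-matter summaries to clinical scores: nearest-visit
# matching with backward fill, bivariate correlation, and age/sex-adjusted
# regression.

#' Match each subject's clinical scores to the visit nearest the scan
#'
#' For every subject and score, the visit minimising |visit date - scan date|
#' is chosen (ties broken toward the earlier visit, whose data cannot be
#' contaminated by post-scan progression).  A missing value at the chosen
#' visit is replaced by the most recent non-missing value from an earlier or
#' equal visit; if none exists the cell is marked `missing`.
#'
#' @param visits long table: `subject_id`, `visit_date` (Date or parseable),
#'   `score`, `value`.
#' @param scans table: `subject_id`, `scan_date`.
#' @return tibble of clinical matches: `subject_id`, `score`, `visit_date`,
#'   `value`, `provenance` in `nearest_visit` / `filled_most_recent` /
#'   `missing`.  Subjects with no visits at all get `missing` rows for every
#'   score present in the visit table.
#' @export
match_nearest_visit <- function(visits, scans) {
  visits <- tibble::as_tibble(visits)
  scans <- tibble::as_tibble(scans)
  need <- c("subject_id", "visit_date", "score", "value")
  if (!all(need %in% names(visits)))
    stopf("visits table needs columns: %s", paste(need, collapse = ", "))
  if (!all(c("subject_id", "scan_date") %in% names(scans)))
    stopf("scans table needs subject_id and scan_date")
  visits$visit_date <- as.Date(visits$visit_date)
  scans$scan_date <- as.Date(scans$scan_date)
  if (anyNA(visits$visit_date) || anyNA(scans$scan_date))
    stopf("unparseable dates in visit or scan table")
  scores <- sort(unique(visits$score))

  grid <- tidyr::expand_grid(scans[, c("subject_id", "scan_date")],
                             score = scores)
  matched <- purrr::pmap(grid, function(subject_id, scan_date, score) {
    v <- visits[visits$subject_id == subject_id & visits$score == score, ]
    if (nrow(v) == 0)
      return(tibble::tibble(subject_id = subject_id, score = score,
                            visit_date = as.Date(NA), value = NA_real_,
                            provenance = "missing"))
    gap <- abs(as.numeric(v$visit_date - scan_date))
    # minimal |gap|; ties -> earlier visit
    cand <- which(gap == min(gap))
    chosen <- cand[which.min(v$visit_date[cand])]
    val <- v$value[chosen]
    prov <- "nearest_visit"
    if (is.na(val)) {
      earlier <- v[v$visit_date <= v$visit_date[chosen] & !is.na(v$value), ]
      if (nrow(earlier) > 0) {
        val <- earlier$value[which.max(earlier$visit_date)]
        prov <- "filled_most_recent"
      } else {
        prov <- "missing"
      }
    }
    tibble::tibble(subject_id = subject_id, score = score,
                   visit_date = v$visit_date[chosen], value = val,
                   provenance = prov)
  })
  dplyr::bind_rows(matched)
}

#' Correlate an ROI grey-matter summary with a matched clinical score
#'
#' Pearson correlation with a two-sided p-value on the complete pairs.
#' Entries whose provenance is `missing` (or whose value is NA) are dropped
#' with a message.
#'
#' @param roi_means named per-subject ROI means (names = subject ids), e.g.
#'   from [extract_roi_mean()].
#' @param matches [match_nearest_visit()] output filtered to one score, or
#'   any table with `subject_id`, `value` (and optionally `provenance`).
#' @return one-row tibble: `r`, `p`, `n`, `n_dropped`.
#' @export
correlate_roi_score <- function(roi_means, matches) {
  matches <- tibble::as_tibble(matches)
  if (length(unique(matches$score %||% "one")) > 1)
    stopf("matches table contains more than one score; filter first")
  val <- matches$value[match(names(roi_means), matches$subject_id)]
  if ("provenance" %in% names(matches)) {
    prov <- matches$provenance[match(names(roi_means), matches$subject_id)]
    val[!is.na(prov) & prov == "missing"] <- NA_real_
  }
  ok <- !is.na(val) & !is.na(roi_means)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    rlang::inform(sprintf("%d subjects dropped (missing score or ROI value)",
                          n_dropped))
  x <- roi_means[ok]; y <- val[ok]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stopf("degenerate variable: ROI means are constant")
  if (stats::sd(y) == 0) stopf("degenerate variable: score values are constant")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), n_dropped = n_dropped)
}

#' Age- and sex-adjusted ROI-score association
#'
#' OLS of the ROI grey-matter mean on score, age and sex (complete cases);
#' reports the t statistic, two-sided p and coefficient of the score term.
#'
#' @param roi_means per-subject ROI means.
#' @param score matched score values, aligned with `roi_means`.
#' @param age,sex covariates aligned with `roi_means`; `sex` is two-level.
#' @return one-row tibble: `coefficient`, `t`, `p`, `n`.
#' @export
adjusted_association <- function(roi_means, score, age, sex) {
  n_in <- length(roi_means)
  stopifnot(length(score) == n_in, length(age) == n_in, length(sex) == n_in)
  sex_num <- if (is.numeric(sex)) sex else {
    lev <- sort(unique(as.character(sex[!is.na(sex)])))
    as.numeric(as.character(sex) == lev[length(lev)])
  }
  df <- stats::complete.cases(roi_means, score, age, sex_num)
  d <- data.frame(gm = roi_means[df], score = score[df],
                  age = age[df], sex = sex_num[df])
  if (nrow(d) - 4 <= 0) stopf("too few complete cases (n = %d)", nrow(d))
  X <- cbind(1, d$score, d$age, d$sex)
  if (qr(X)$rank < 4) stopf("collinear predictors in adjusted model")
  fit <- stats::lm(gm ~ score + age + sex, data = d)
  sm <- summary(fit)$coefficients
  tibble::tibble(coefficient = sm["score", "Estimate"],
                 t = sm["score", "t value"],
                 p = sm["score", "Pr(>|t|)"],
                 n = nrow(d))
}
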