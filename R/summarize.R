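# Cohort summary bundle: between-group, velocity-by-collateral and outcome
# tables shaped like the published Tables 1-5, plus the key numeric results
# (medians, proportions, odds ratios) they are formatted from.

rcvf_indices <- c("rcvf1", "rcvf2", "rcvf3", "rcvf21", "rcvf31")

# 2x2 of a logical exposure across two groups: rows group1/group2,
# cols yes/no; returns the auto-mode association p-value.
binary_group_p <- function(yes1, n1, yes2, n2) {
  association_test_2x2(yes1, n1 - yes1, yes2, n2 - yes2)$p_value
}

#' Summarize a scored cohort
#'
#' Builds the table bundle of the cohort analysis: baseline demographics,
#' within-group hemisphere comparison, between-group imaging findings,
#' velocity-by-collateral cross-tables with Woolf odds ratios (symptomatic
#' group), and 3-month outcome associations including univariate and
#' NIHSS-adjusted logistic odds ratios for the two-vein absence category.
#' Counts print as `"k (p%)"` with percentages rounded half away from zero;
#' skewed variables print as `"median (q1-q3)"`.
#'
#' @param scores Per-patient scores from [score_cohort()].
#' @param clinical Per-patient clinical records (see [read_clinical_csv()]).
#' @param velocity_cohort Group whose values set the fast/slow median
#'   thresholds (default `"symptomatic"`, the analysis cohort of the
#'   velocity and outcome tables).
#' @return An object of class `"cvf_summary"`: list of data frames
#'   (`baseline`, `hemispheres`, `imaging`, `velocity_collateral`,
#'   `outcome`) plus `key`, a list of the numeric results behind them.
#' @export
summarize_cohort <- function(scores, clinical,
                             velocity_cohort = "symptomatic") {
  for (col in c("patient_id", "group")) {
    if (is.null(scores[[col]])) stop("scores lack mandatory column: ", col)
    if (is.null(clinical[[col]])) stop("clinical lacks mandatory column: ", col)
  }
  d <- merge(scores, clinical[setdiff(names(clinical), "group")],
             by = "patient_id")
  groups <- c("symptomatic", "asymptomatic")
  n_by <- table(factor(d$group, levels = groups))
  if (any(n_by == 0)) {
    stop("between-group summaries need at least one patient per group; ",
         "missing: ", paste(groups[n_by == 0], collapse = ", "))
  }
  sym <- d[d$group == "symptomatic", ]
  asym <- d[d$group == "asymptomatic", ]

  # --- baseline (Table-1 shape) -----------------------------------------
  baseline <- NULL
  add_row <- function(tab, variable, symptomatic, asymptomatic, p) {
    rbind(tab, data.frame(variable = variable, symptomatic = symptomatic,
                          asymptomatic = asymptomatic, p = fmt_p(p),
                          stringsAsFactors = FALSE))
  }
  if (!is.null(d$age)) {
    p_age <- tryCatch(
      group_compare_continuous(sym$age, asym$age, "t")$p_value,
      error = function(e) NA_real_
    )
    baseline <- add_row(baseline, "Age, years", fmt_mean_sd(sym$age),
                        fmt_mean_sd(asym$age), p_age)
  }
  bin_vars <- c(Female = "sex", Hypertension = "hypertension",
                `Diabetes mellitus` = "diabetes",
                `Smoking history` = "smoking", Drinking = "drinking",
                `Lipid disorder` = "lipid_disorder",
                `Occlusion (100%)` = "stenosis_class")
  for (lab in names(bin_vars)) {
    col <- bin_vars[[lab]]
    if (is.null(d[[col]])) next
    as_yes <- switch(col,
      sex = function(x) x == "female",
      stenosis_class = function(x) x == "occlusion",
      function(x) as.logical(x)
    )
    y1 <- sum(as_yes(sym[[col]]), na.rm = TRUE)
    y2 <- sum(as_yes(asym[[col]]), na.rm = TRUE)
    baseline <- add_row(
      baseline, lab, fmt_count_pct(y1, nrow(sym)),
      fmt_count_pct(y2, nrow(asym)),
      binary_group_p(y1, nrow(sym), y2, nrow(asym))
    )
  }

  # --- hemispheres (Table-2 shape) --------------------------------------
  hemispheres <- NULL
  absent_any <- function(g, side) {
    cols <- paste0(c("smcv_", "vot_", "vol_"), side)
    rowSums(g[cols] == "absent") > 0
  }
  for (g_name in groups) {
    g <- d[d$group == g_name, ]
    for (vn in c("any", tolower(vein_names))) {
      if (vn == "any") {
        ka <- sum(absent_any(g, "aff"))
        kc <- sum(absent_any(g, "contra"))
        lab <- "CVF-"
      } else {
        ka <- sum(g[[paste0(vn, "_aff")]] == "absent")
        kc <- sum(g[[paste0(vn, "_contra")]] == "absent")
        lab <- paste0(toupper(vn), "-")
      }
      hemispheres <- rbind(hemispheres, data.frame(
        group = g_name, variable = lab,
        affected = fmt_count_pct(ka, nrow(g)),
        contralateral = fmt_count_pct(kc, nrow(g)),
        p = fmt_p(binary_group_p(ka, nrow(g), kc, nrow(g))),
        stringsAsFactors = FALSE
      ))
    }
    for (tm in c("cvf1", "cvf2", "cvf3", "cvf21", "cvf31")) {
      xa <- g[[paste0(tm, "_aff")]]
      xc <- g[[paste0(tm, "_contra")]]
      ok <- !is.na(xa) & !is.na(xc)
      p <- if (sum(ok) >= 2 && any(xa[ok] != xc[ok])) {
        suppressWarnings(stats::wilcox.test(xa[ok], xc[ok], paired = TRUE,
                                            exact = FALSE,
                                            correct = FALSE)$p.value)
      } else {
        NA_real_
      }
      hemispheres <- rbind(hemispheres, data.frame(
        group = g_name, variable = paste0(toupper(tm), ", s"),
        affected = fmt_median_iqr(xa), contralateral = fmt_median_iqr(xc),
        p = fmt_p(p), stringsAsFactors = FALSE
      ))
    }
  }

  # --- imaging findings (Table-3 shape) ---------------------------------
  imaging <- NULL
  ips_bin <- function(g) g$ipsilateral_cvf_minus_n >= 1
  k1 <- sum(ips_bin(sym)); k2 <- sum(ips_bin(asym))
  imaging <- add_row(imaging, "Ipsilateral CVF-",
                     fmt_count_pct(k1, nrow(sym)),
                     fmt_count_pct(k2, nrow(asym)),
                     binary_group_p(k1, nrow(sym), k2, nrow(asym)))
  for (vn in vein_names) {
    in_set <- function(g) grepl(vn, g$ipsilateral_cvf_minus, fixed = TRUE)
    k1 <- sum(in_set(sym)); k2 <- sum(in_set(asym))
    imaging <- add_row(imaging, paste0("Ipsilateral ", vn, "-"),
                       fmt_count_pct(k1, nrow(sym)),
                       fmt_count_pct(k2, nrow(asym)),
                       binary_group_p(k1, nrow(sym), k2, nrow(asym)))
  }
  for (ncat in 1:3) {
    k1 <- sum(sym$ipsilateral_cvf_minus_n == ncat)
    k2 <- sum(asym$ipsilateral_cvf_minus_n == ncat)
    if (ncat == 3 && k1 + k2 == 0) next  # representable but typically absent
    imaging <- add_row(imaging, sprintf("CVF- = %d", ncat),
                       fmt_count_pct(k1, nrow(sym)),
                       fmt_count_pct(k2, nrow(asym)),
                       binary_group_p(k1, nrow(sym), k2, nrow(asym)))
  }
  for (idx in rcvf_indices) {
    p <- tryCatch(
      group_compare_continuous(sym[[idx]], asym[[idx]])$p_value,
      error = function(e) NA_real_
    )
    imaging <- add_row(imaging, paste0(idx, ", s"),
                       fmt_median_iqr(sym[[idx]]),
                       fmt_median_iqr(asym[[idx]]), p)
  }
  if (!is.null(d$collateral_status)) {
    k1 <- sum(sym$collateral_status == "poor")
    k2 <- sum(asym$collateral_status == "poor")
    imaging <- add_row(imaging, "Poor collateral status",
                       fmt_count_pct(k1, nrow(sym)),
                       fmt_count_pct(k2, nrow(asym)),
                       binary_group_p(k1, nrow(sym), k2, nrow(asym)))
  }
  if (!is.null(d$antegrade_label)) {
    k1 <- sum(sym$antegrade_label == "compromised")
    k2 <- sum(asym$antegrade_label == "compromised")
    imaging <- add_row(imaging, "Compromised antegrade flow",
                       fmt_count_pct(k1, nrow(sym)),
                       fmt_count_pct(k2, nrow(asym)),
                       binary_group_p(k1, nrow(sym), k2, nrow(asym)))
  }

  # --- velocity x collateral (Table-4 shape, analysis cohort) -----------
  vc <- d[d$group == velocity_cohort, ]
  velocity_collateral <- NULL
  velocity_or <- list()
  velocity_labels <- list()
  if (!is.null(vc$collateral_status) && nrow(vc) > 0) {
    poor <- vc$collateral_status == "poor"
    for (idx in rcvf_indices) {
      if (all(is.na(vc[[idx]]))) next
      cl <- classify_velocity(vc[[idx]])
      velocity_labels[[idx]] <- cl
      fast <- cl$label == "fast"
      ok <- !is.na(fast)
      a <- sum(fast[ok] & poor[ok])      # fast, poor collateral
      b <- sum(!fast[ok] & poor[ok])
      cc <- sum(fast[ok] & !poor[ok])
      dd <- sum(!fast[ok] & !poor[ok])
      or <- odds_ratio_woolf(a, b, cc, dd)
      velocity_or[[idx]] <- or
      velocity_collateral <- rbind(velocity_collateral, data.frame(
        index = idx, threshold_s = cl$threshold,
        good_fast = fmt_count_pct(cc, cc + dd),
        good_slow = fmt_count_pct(dd, cc + dd),
        poor_fast = fmt_count_pct(a, a + b),
        poor_slow = fmt_count_pct(b, a + b),
        p = fmt_p(association_test_2x2(a, b, cc, dd)$p_value),
        or = or$odds_ratio, ci_low = or$ci_low, ci_high = or$ci_high,
        stringsAsFactors = FALSE
      ))
    }
  }

  # --- outcome at 3 months (Table-5 shape, symptomatic) -----------------
  oc <- sym[!is.na(sym$mrs_3mo), ]
  outcome <- NULL
  outcome_or <- list()
  if (nrow(oc) > 0 && length(unique(oc$mrs_3mo > 2)) == 2L) {
    poor_out <- oc$mrs_3mo > 2
    good <- oc[!poor_out, ]
    bad <- oc[poor_out, ]
    orow <- function(variable, good_txt, poor_txt, p, or = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_) {
      rbind(outcome, data.frame(
        variable = variable, good_outcome = good_txt, poor_outcome = poor_txt,
        p = fmt_p(p), or = or, ci_low = ci_low, ci_high = ci_high,
        stringsAsFactors = FALSE
      ))
    }
    if (!is.null(oc$age)) {
      p <- tryCatch(group_compare_continuous(good$age, bad$age, "t")$p_value,
                    error = function(e) NA_real_)
      outcome <- orow("Age, years", fmt_mean_sd(good$age),
                      fmt_mean_sd(bad$age), p)
    }
    if (!is.null(oc$nihss)) {
      p <- tryCatch(group_compare_continuous(good$nihss, bad$nihss)$p_value,
                    error = function(e) NA_real_)
      lf <- tryCatch(logistic_regression(poor_out, oc$nihss),
                     error = function(e) NULL)
      outcome <- orow("NIHSS", fmt_median_iqr(good$nihss, 0),
                      fmt_median_iqr(bad$nihss, 0), p,
                      if (is.null(lf)) NA_real_ else lf$odds_ratio[2],
                      if (is.null(lf)) NA_real_ else lf$ci_low[2],
                      if (is.null(lf)) NA_real_ else lf$ci_high[2])
    }
    bin_rows <- list(
      `Ipsilateral CVF-` = ips_bin(oc),
      `CVF- = 1` = oc$ipsilateral_cvf_minus_n == 1,
      `CVF- = 2` = oc$ipsilateral_cvf_minus_n == 2
    )
    if (!is.null(oc$collateral_status)) {
      bin_rows[["Poor collateral status"]] <- oc$collateral_status == "poor"
    }
    if (!is.null(oc$antegrade_label)) {
      bin_rows[["Compromised antegrade flow"]] <-
        oc$antegrade_label == "compromised"
    }
    for (idx in names(velocity_labels)) {
      lbl <- velocity_labels[[idx]]$label[match(oc$patient_id,
                                                vc$patient_id)]
      bin_rows[[paste0("Slow ", idx)]] <- lbl == "slow"
    }
    for (lab in names(bin_rows)) {
      flag <- bin_rows[[lab]]
      kg <- sum(flag[!poor_out], na.rm = TRUE)
      kp <- sum(flag[poor_out], na.rm = TRUE)
      p <- binary_group_p(kg, nrow(good), kp, nrow(bad))
      or <- ci_l <- ci_h <- NA_real_
      if (lab == "CVF- = 2") {
        # cross-product with good outcome as the case row, exposure CVF-=2
        wo <- odds_ratio_woolf(kg, nrow(good) - kg, kp, nrow(bad) - kp)
        outcome_or$cvf_minus_2_univariate <- wo
        or <- wo$odds_ratio; ci_l <- wo$ci_low; ci_h <- wo$ci_high
        adj <- tryCatch(
          logistic_regression(!poor_out, as.integer(flag),
                              adjustment = oc$nihss),
          error = function(e) NULL
        )
        if (!is.null(adj)) outcome_or$cvf_minus_2_adjusted <- adj
      }
      outcome <- orow(lab, fmt_count_pct(kg, nrow(good)),
                      fmt_count_pct(kp, nrow(bad)), p, or, ci_l, ci_h)
    }
  }

  key <- list(
    n = stats::setNames(as.integer(n_by), groups),
    median_rcvf21 = c(
      symptomatic = stats::median(sym$rcvf21, na.rm = TRUE),
      asymptomatic = stats::median(asym$rcvf21, na.rm = TRUE)
    ),
    ipsilateral_prop = c(
      symptomatic = mean(ips_bin(sym)),
      asymptomatic = mean(ips_bin(asym))
    ),
    velocity_or = velocity_or,
    velocity_thresholds = vapply(velocity_labels, `[[`, numeric(1),
                                 "threshold"),
    outcome_or = outcome_or
  )
  structure(
    list(baseline = baseline, hemispheres = hemispheres, imaging = imaging,
         velocity_collateral = velocity_collateral, outcome = outcome,
         key = key),
    class = "cvf_summary"
  )
}

#' @export
print.cvf_summary <- function(x, ...) {
  sections <- c(baseline = "Baseline demographics",
                hemispheres = "Affected vs contralateral hemisphere",
                imaging = "Imaging findings by group",
                velocity_collateral =
                  "CVF velocity vs collateral status (analysis cohort)",
                outcome = "3-month outcome associations (symptomatic)")
  for (nm in names(sections)) {
    if (is.null(x[[nm]])) next
    cat("\n== ", sections[[nm]], " ==\n", sep = "")
    print(x[[nm]], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
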