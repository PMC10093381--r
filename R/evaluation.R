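#' Confusion matrix of reference vs predicted subtype labels
#'
#' Rows are the reference classification, columns the predicted one.
#' Labels outside the class universe are an error.
#'
#' @param reference,predicted label vectors of equal length (joined
#'   externally on sample id).
#' @param levels class universe; defaults to the four molecular subtypes
#'   POLE, MSI, CN-low, CN-high.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(reference, predicted, levels = SUBTYPES) {
  if (length(reference) != length(predicted)) {
    stop_("reference and predicted labels differ in length")
  }
  bad <- setdiff(unique(c(as.character(reference), as.character(predicted))),
                 levels)
  if (length(bad)) {
    stop_("label(s) outside the class universe: ", paste(bad, collapse = ", "))
  }
  m <- table(factor(reference, levels = levels),
             factor(predicted, levels = levels))
  m <- matrix(as.integer(m), nrow = length(levels),
              dimnames = list(reference = levels, predicted = levels))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = reference, columns = predicted), n =",
      sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision is diagonal over column sum, recall diagonal over row sum,
#' F1 their harmonic mean; an empty column (class never predicted) gets
#' precision 0 and an all-zero precision/recall pair gets F1 0.
#'
#' @param m a [confusion_matrix()].
#' @return data frame with one row per class: `precision`, `recall`, `f1`,
#'   `support` (reference row sum).
#' @export
per_class_metrics <- function(m) {
  d <- diag(m)
  cs <- colSums(m)
  rs <- rowSums(m)
  prec <- ifelse(cs == 0, 0, d / cs)
  rec <- ifelse(rs == 0, 0, d / rs)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  data.frame(class = rownames(m), precision = prec, recall = rec, f1 = f1,
             support = as.integer(rs), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Row percentages of a confusion matrix
#'
#' Each row is normalised by its reference-class size; with
#' `digits = 0` this reproduces whole-percent table reporting
#' (half-up rounding).
#'
#' @param m a [confusion_matrix()].
#' @param digits decimals of the percentage (default 0); `NULL` for
#'   unrounded fractions.
#' @return numeric matrix of percentages (or fractions when
#'   `digits = NULL`).
#' @export
row_percentages <- function(m, digits = 0) {
  rs <- rowSums(m)
  frac <- sweep(unclass(m), 1, ifelse(rs == 0, 1, rs), `/`)
  if (is.null(digits)) return(frac)
  round_half_up(100 * frac, digits)
}

#' Aggregate classification metrics
#'
#' Accuracy plus macro- (unweighted class mean) or weighted-
#' (reference-class-size weighted) averaged precision, recall and F1.
#' Over a complete confusion matrix, weighted recall equals accuracy.
#'
#' @param m a [confusion_matrix()].
#' @param averaging `"macro"` or `"weighted"`.
#' @return named numeric vector: `accuracy`, `precision`, `recall`, `f1`.
#' @export
aggregate_metrics <- function(m, averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  pc <- per_class_metrics(m)
  w <- if (averaging == "macro") {
    rep(1 / nrow(pc), nrow(pc))
  } else {
    pc$support / sum(pc$support)
  }
  c(accuracy = sum(diag(m)) / sum(m),
    precision = sum(w * pc$precision),
    recall = sum(w * pc$recall),
    f1 = sum(w * pc$f1))
}

#' Chi-square test of homogeneity between two class distributions
#'
#' Pearson chi-square on the 2 x k table of the two count vectors, with
#' `k - 1` degrees of freedom and no continuity correction; used to compare
#' the subtype distributions produced by two classification methods.
#'
#' @param counts_a,counts_b per-class counts over the same class universe.
#' @return list of class `chisq_homogeneity` with `statistic`, `df`,
#'   `p_value`.
#' @export
chisq_homogeneity <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop_("count vectors differ in length")
  }
  tab <- rbind(counts_a, counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop_("zero expected count; drop empty classes")
  ht <- stats::chisq.test(tab, correct = FALSE)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value)),
    class = "chisq_homogeneity"
  )
}

#' @export
print.chisq_homogeneity <- function(x, ...) {
  cat(sprintf("Chi-square homogeneity: X2 = %.4f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with right censoring, via
#' [survival::survfit()].
#'
#' @param time follow-up times in months (>= 0).
#' @param event 1 = event observed, 0 = censored.
#' @param group optional grouping factor (one curve per group).
#' @return a `survfit` object.
#' @export
km_curve <- function(time, event, group = NULL) {
  if (any(time < 0, na.rm = TRUE)) stop_("negative follow-up time")
  if (is.null(group)) {
    survival::survfit(survival::Surv(time, event) ~ 1)
  } else {
    df <- data.frame(time = time, event = event, group = factor(group))
    survival::survfit(survival::Surv(time, event) ~ group, data = df)
  }
}

#' Survival probability at a time point
#'
#' Step value of the product-limit curve at the largest event time not
#' exceeding `t` (the usual convention for "36-month rates"); 1 before the
#' first event.
#'
#' @param fit a `survfit` object from [km_curve()].
#' @param t time point (same units as the fit).
#' @return numeric survival probability (vector when the fit has strata).
#' @export
survival_at <- function(fit, t) {
  s <- summary(fit, times = t, extend = TRUE)
  if (is.null(s$strata)) s$surv else {
    stats::setNames(s$surv, sub("^group=", "", as.character(s$strata)))
  }
}

#' k-group log-rank test
#'
#' Omnibus log-rank comparison of k survival distributions via
#' [survival::survdiff()]; the statistic is chi-square with `k - 1`
#' degrees of freedom under the null.
#'
#' @param time,event follow-up and event indicator as in [km_curve()].
#' @param group grouping factor with k >= 2 observed levels.
#' @return list of class `logrank_result` with `statistic`, `df`,
#'   `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) stop_("log-rank test needs >= 2 groups")
  if (sum(event, na.rm = TRUE) == 0) stop_("log-rank test needs >= 1 event")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  structure(
    list(statistic = unname(sd$chisq), df = nlevels(group) - 1,
         p_value = stats::pchisq(sd$chisq, nlevels(group) - 1,
                                 lower.tail = FALSE)),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Full cohort evaluation against a reference classification
#'
#' Reproduces the published evaluation protocol: confusion matrix of
#' reference vs predicted subtype, per-class and macro/weighted averaged
#' metrics, chi-square comparison of the two class distributions,
#' Kaplan-Meier curves per subtype under both labelings, survival
#' proportions at a landmark time (default 36 months), and the k-group
#' log-rank test per labeling. Records without follow-up are dropped from
#' the survival part only.
#'
#' @param calls a `subtype_calls` data frame (see
#'   [predict.ec_classifier()]).
#' @param clinical a `clinical_table` with `tcga_subtype`,
#'   `followup_months` and `event`.
#' @param landmark_months landmark for survival proportions (default 36).
#' @return object of class `cohort_evaluation`.
#' @export
evaluate_cohort <- function(calls, clinical, landmark_months = 36) {
  if (is.null(clinical$tcga_subtype)) {
    stop_("clinical table has no reference tcga_subtype column")
  }
  idx <- match(calls$sample, clinical$sample)
  if (anyNA(idx)) {
    stop_("samples missing from the clinical table: ",
          paste(calls$sample[is.na(idx)], collapse = ", "))
  }
  ref <- clinical$tcga_subtype[idx]
  keep <- !is.na(ref)
  cm <- confusion_matrix(ref[keep], calls$subtype[keep])
  out <- list(
    confusion = cm,
    per_class = per_class_metrics(cm),
    macro = aggregate_metrics(cm, "macro"),
    weighted = aggregate_metrics(cm, "weighted"),
    distribution_test = chisq_homogeneity(rowSums(cm), colSums(cm)),
    landmark_months = landmark_months
  )
  has_fu <- !is.null(clinical$followup_months) &&
    any(!is.na(clinical$followup_months[idx]))
  if (has_fu) {
    surv <- data.frame(
      time = clinical$followup_months[idx],
      event = clinical$event[idx],
      reference = ref,
      predicted = calls$subtype,
      stringsAsFactors = FALSE
    )
    surv <- surv[!is.na(surv$time) & !is.na(surv$event), , drop = FALSE]
    out$survival_data <- surv
    for (lab in c("reference", "predicted")) {
      g <- factor(surv[[lab]], levels = SUBTYPES)
      fit <- km_curve(surv$time, surv$event, g)
      out[[paste0("km_", lab)]] <- fit
      out[[paste0("landmark_", lab)]] <-
        survival_at(fit, landmark_months)
      out[[paste0("logrank_", lab)]] <-
        logrank_test(surv$time, surv$event, g)
    }
  }
  class(out) <- "cohort_evaluation"
  out
}

#' @export
print.cohort_evaluation <- function(x, digits = 4, ...) {
  print(x$confusion)
  cat("\nRow percentages:\n")
  print(row_percentages(x$confusion))
  cat("\nPer-class metrics:\n")
  print(transform(x$per_class,
                  precision = round(precision, digits),
                  recall = round(recall, digits),
                  f1 = round(f1, digits)))
  cat("\nMacro-averaged:   ")
  cat(paste(names(x$macro), round(x$macro, digits), sep = "=",
            collapse = "  "), "\n")
  cat("Weighted-averaged:")
  cat(paste(names(x$weighted), round(x$weighted, digits), sep = "=",
            collapse = "  "), "\n\n")
  print(x$distribution_test)
  if (!is.null(x$km_reference)) {
    cat(sprintf("\n%d-month survival (reference): %s\n", x$landmark_months,
                paste(names(x$landmark_reference),
                      round(x$landmark_reference, 2),
                      sep = "=", collapse = "  ")))
    cat(sprintf("%d-month survival (predicted): %s\n", x$landmark_months,
                paste(names(x$landmark_predicted),
                      round(x$landmark_predicted, 2),
                      sep = "=", collapse = "  ")))
    cat("Log-rank (reference): ")
    print(x$logrank_reference)
    cat("Log-rank (predicted): ")
    print(x$logrank_predicted)
  }
  invisible(x)
}

#' Kaplan-Meier plot of a cohort evaluation
#'
#' Draws the per-subtype survival curves under the reference and the
#' predicted labeling side by side, with log-rank p-values in the panel
#' corners.
#'
#' @param x a `cohort_evaluation`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cohort_evaluation <- function(x, ...) {
  if (is.null(x$km_reference)) {
    stop_("evaluation carries no survival data")
  }
  cols <- c("#1b9e77", "#7570b3", "#d95f02", "#e7298a")
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (lab in c("reference", "predicted")) {
    fit <- x[[paste0("km_", lab)]]
    graphics::plot(fit, col = cols, lwd = 2, xlab = "Months",
                   ylab = "Survival probability",
                   main = paste0(toupper(substring(lab, 1, 1)),
                                 substring(lab, 2), " labels"), ...)
    graphics::legend("bottomleft", legend = SUBTYPES, col = cols, lwd = 2,
                     bty = "n")
    graphics::text(
      graphics::par("usr")[2] * 0.65, 0.98,
      sprintf("log-rank p = %.3g", x[[paste0("logrank_", lab)]]$p_value)
    )
  }
  invisible(x)
}
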