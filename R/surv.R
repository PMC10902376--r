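#' Kaplan-Meier curves and log-rank test across subtypes
#'
#' Product-limit estimate per group plus the k-group log-rank (Mantel-Cox)
#' chi-square. Groups with no subjects are dropped with a warning.
#'
#' @param clinical data.frame with `os_time` (> 0) and `event` (1 death,
#'   0 censored); rows aligned with `labels`.
#' @param labels group (subtype) per subject.
#' @return object of class `km_report`: `curves` (data.frame: group, time,
#'   surv, n_risk, n_event), `medians` (named median survival per group),
#'   `logrank_chisq`, `df`, `p_value`, `fit` (the survfit object).
#' @export
km_logrank <- function(clinical, labels) {
  stopifnot(nrow(clinical) == length(labels),
            all(clinical$os_time > 0), all(clinical$event %in% 0:1))
  grp <- as.factor(labels)
  empty <- levels(grp)[table(grp) == 0]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    grp <- droplevels(grp)
  }
  if (nlevels(grp) < 2) stop("log-rank test needs at least 2 groups")
  df_surv <- data.frame(time = clinical$os_time, event = clinical$event,
                        group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = df_surv)
  sm <- summary(fit)
  curves <- data.frame(
    group = sub("^group=", "", as.character(sm$strata)),
    time = sm$time, surv = sm$surv, n_risk = sm$n.risk,
    n_event = sm$n.event, stringsAsFactors = FALSE)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(fit)$table))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = df_surv)
  df <- nlevels(grp) - 1L
  structure(list(curves = curves, medians = med,
                 logrank_chisq = unname(sd_$chisq), df = df,
                 p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
                 fit = fit),
            class = "km_report")
}

#' @export
print.km_report <- function(x, ...) {
  cat(sprintf("km_report: %d groups | log-rank chi-sq = %.4g (df = %d), p = %.3g\n",
              x$df + 1L, x$logrank_chisq, x$df, x$p_value))
  print(round(x$medians, 2))
  invisible(x)
}

# reference-level encodings mirroring the clinical reporting convention
encode_clinical <- function(clinical, labels) {
  out <- data.frame(time = clinical$os_time, event = clinical$event)
  if ("age" %in% names(clinical))
    out$age <- factor(ifelse(clinical$age > 65, "> 65", "<= 65"),
                      levels = c("> 65", "<= 65"))
  if ("sex" %in% names(clinical))
    out$sex <- factor(clinical$sex, levels = c("M", "F"),
                      labels = c("Male", "Female"))
  if ("mgmt" %in% names(clinical))
    out$mgmt <- factor(clinical$mgmt,
                       levels = c("methylated", "unmethylated"))
  if ("eor" %in% names(clinical))
    out$eor <- factor(clinical$eor,
                      levels = c("near/gross total", "partial/biopsy"))
  if (!is.null(labels))
    out$subtype <- factor(paste0("Subtype ", labels))
  out
}

cox_level_table <- function(fit, model_label) {
  s <- summary(fit)
  co <- s$coefficients; ci <- s$conf.int
  data.frame(term = rownames(co),
             hazard_ratio = unname(co[, "exp(coef)"]),
             ci_low = unname(ci[, "lower .95"]),
             ci_high = unname(ci[, "upper .95"]),
             p_value = unname(co[, "Pr(>|z|)"]),
             model = model_label, stringsAsFactors = FALSE)
}

#' Univariate and multivariate Cox regression over clinical factors
#'
#' Fits a univariate Cox proportional-hazards model (Efron ties) per factor,
#' then a multivariate model on the factors reaching univariate p < 0.05
#' (any level). Categorical encodings follow the reporting convention:
#' reference levels age > 65, male, MGMT methylated, near/gross-total
#' resection, subtype 1. Subjects with missing values are excluded listwise
#' per fit.
#'
#' @param clinical data.frame with `os_time`, `event` and any of `age`,
#'   `sex`, `mgmt`, `eor`.
#' @param labels subtype per subject, or `NULL` to omit the subtype factor.
#' @param covariates factors to consider (default all available + subtype).
#' @param screen_p univariate p threshold admitting a factor to the
#'   multivariate model.
#' @return object of class `cox_report`: `univariate` and `multivariate`
#'   data.frames (term, hazard_ratio, ci_low, ci_high, p_value),
#'   `admitted` (factor names), `n_used` per model.
#' @export
cox_fit <- function(clinical, labels = NULL, covariates = NULL,
                    screen_p = 0.05) {
  enc <- encode_clinical(clinical, labels)
  avail <- setdiff(names(enc), c("time", "event"))
  if (is.null(covariates)) covariates <- avail
  covariates <- intersect(covariates, avail)
  if (!length(covariates)) stop("no usable covariates")

  uni <- list(); uni_p <- numeric(0); n_uni <- integer(0)
  for (v in covariates) {
    d <- enc[!is.na(enc[[v]]), c("time", "event", v)]
    fit <- survival::coxph(survival::Surv(time, event) ~ .,
                           data = d, ties = "efron")
    if (!fit$iter && any(is.na(stats::coef(fit))))
      stop("cox fit failed for factor ", v)
    tab <- cox_level_table(fit, "univariate")
    uni[[v]] <- tab
    uni_p[v] <- min(tab$p_value)
    n_uni[v] <- fit$n
  }
  admitted <- names(uni_p)[uni_p < screen_p]
  multi <- NULL; n_multi <- NA_integer_
  if (length(admitted)) {
    d <- enc[, c("time", "event", admitted)]
    d <- d[stats::complete.cases(d), ]
    fit <- survival::coxph(survival::Surv(time, event) ~ .,
                           data = d, ties = "efron")
    if (any(is.na(stats::coef(fit))))
      stop("multivariate cox fit is degenerate (separation or collinearity)")
    multi <- cox_level_table(fit, "multivariate")
    n_multi <- fit$n
  }
  structure(list(univariate = do.call(rbind, uni), multivariate = multi,
                 admitted = admitted,
                 n_used = list(univariate = n_uni, multivariate = n_multi)),
            class = "cox_report")
}

#' @export
print.cox_report <- function(x, ...) {
  cat("cox_report (univariate):\n")
  print(x$univariate, row.names = FALSE, digits = 3)
  if (!is.null(x$multivariate)) {
    cat("multivariate (factors admitted at p < 0.05: ",
        paste(x$admitted, collapse = ", "), "):\n", sep = "")
    print(x$multivariate, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Pairwise two-group hazard ratios between subtypes
#'
#' One two-group Cox fit per unordered subtype pair; the earlier-numbered
#' subtype is the reference, so the reported HR is for membership in the
#' later-numbered subtype.
#'
#' @inheritParams km_logrank
#' @return data.frame: reference, comparison, hazard_ratio, ci_low, ci_high,
#'   p_value.
#' @export
pairwise_subtype_hr <- function(clinical, labels) {
  lv <- sort(unique(labels))
  out <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    sel <- labels %in% c(lv[i], lv[j])
    d <- data.frame(time = clinical$os_time[sel], event = clinical$event[sel],
                    g = factor(labels[sel], levels = c(lv[i], lv[j])))
    fit <- survival::coxph(survival::Surv(time, event) ~ g, data = d,
                           ties = "efron")
    s <- summary(fit)
    out[[length(out) + 1L]] <- data.frame(
      reference = lv[i], comparison = lv[j],
      hazard_ratio = unname(s$conf.int[1, "exp(coef)"]),
      ci_low = unname(s$conf.int[1, "lower .95"]),
      ci_high = unname(s$conf.int[1, "upper .95"]),
      p_value = unname(s$coefficients[1, "Pr(>|z|)"]))
  }
  do.call(rbind, out)
}

#' Rename subtypes by survival risk
#'
#' Relabels clusters so subtype 1 has the worst (smallest) Kaplan-Meier
#' median overall survival, subtype 2 the next, and so on; groups whose
#' median is never reached sort last. Ties break on mean survival time.
#'
#' @inheritParams km_logrank
#' @return integer labels renamed by decreasing risk, with attribute
#'   `"mapping"` (old label -> new label).
#' @export
order_subtypes_by_risk <- function(clinical, labels) {
  lv <- sort(unique(labels))
  med <- vapply(lv, function(l) {
    fit <- survival::survfit(
      survival::Surv(clinical$os_time[labels == l],
                     clinical$event[labels == l]) ~ 1)
    m <- unname(summary(fit)$table["median"])
    if (is.na(m)) Inf else m
  }, numeric(1))
  mean_t <- vapply(lv, function(l) mean(clinical$os_time[labels == l]),
                   numeric(1))
  ord <- order(med, mean_t)
  map <- stats::setNames(seq_along(lv), lv[ord])
  new <- unname(map[as.character(labels)])
  attr(new, "mapping") <- map
  new
}

#' Per-variable subtype comparison tests
#'
#' Kruskal-Wallis for continuous variables, Fisher's exact test for
#' categorical ones (exact network algorithm; falls back to p-value
#' simulation for large sparse tables, flagged in the output). Constant
#' variables get p = 1 with a flag.
#'
#' @param data data.frame of variables to compare (numeric -> Kruskal-Wallis;
#'   character/factor/logical -> Fisher).
#' @param labels subtype per row.
#' @return data.frame: variable, test, statistic (NA for Fisher), p_value,
#'   flag.
#' @export
subtype_feature_tests <- function(data, labels) {
  stopifnot(nrow(data) == length(labels))
  grp <- as.factor(labels)
  if (nlevels(grp) < 2) stop("need at least 2 subtypes")
  rows <- lapply(names(data), function(v) {
    x <- data[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2)
      return(data.frame(variable = v, test = "none", statistic = NA_real_,
                        p_value = 1, flag = "constant"))
    if (is.numeric(x)) {
      kt <- stats::kruskal.test(x[ok], grp[ok])
      data.frame(variable = v, test = "kruskal-wallis",
                 statistic = unname(kt$statistic), p_value = kt$p.value,
                 flag = "")
    } else {
      tab <- table(x[ok], grp[ok])
      ft <- tryCatch(
        list(p = stats::fisher.test(tab)$p.value, flag = ""),
        error = function(e)
          list(p = stats::fisher.test(tab, simulate.p.value = TRUE,
                                      B = 1e4)$p.value,
               flag = "simulated"))
      data.frame(variable = v, test = "fisher", statistic = NA_real_,
                 p_value = ft$p, flag = ft$flag)
    }
  })
  do.call(rbind, rows)
}
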