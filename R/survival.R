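# Kaplan-Meier estimation, log-rank comparison, and Harrell's concordance
# index, wrapping the survival package.  Group comparisons are computed over
# the intersection of the clinical table and the supplied sample -> group
# mapping; treatment stratification is a plain row filter applied by the
# caller before analysis.

surv_align <- function(clin, groups) {
  g <- as_label_map(groups, "groups")
  common <- intersect(clin$sample, names(g))
  if (!length(common)) stop2("no clinical sample carries a group label")
  clin <- clin[match(common, clin$sample), , drop = FALSE]
  clin$group <- unname(g[common])
  clin
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator for each group; censored times reduce the risk
#' set without a step.  Requested groups with no clinical samples are
#' skipped with a warning.
#'
#' @param clin clinical data frame with `sample`, `time`, `event`.
#' @param groups optional sample -> group mapping; omitted = one curve for
#'   the whole cohort.
#' @return named list of data frames (one per group): `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` at each observed time.
#' @export
kaplan_meier <- function(clin, groups = NULL) {
  if (is.null(groups)) {
    clin$group <- "all"
  } else {
    requested <- unique(as_label_map(groups, "groups"))
    clin <- surv_align(clin, groups)
    empty <- setdiff(requested, clin$group)
    if (length(empty))
      warning("group(s) with no clinical samples skipped: ",
              paste(empty, collapse = ", "))
  }
  out <- list()
  for (grp in unique(clin$group)) {
    d <- clin[clin$group == grp, ]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    out[[grp]] <- data.frame(time = fit$time,
                             n_risk = fit$n.risk,
                             n_event = fit$n.event,
                             n_censor = fit$n.censor,
                             survival = fit$surv)
  }
  out
}

#' k-group log-rank test
#'
#' @param clin clinical data frame with `sample`, `time`, `event`.
#' @param groups sample -> group mapping with >= 2 non-empty groups over the
#'   intersection.
#' @return list with `statistic` (chi-square), `dof` (k - 1), `p`.
#' @export
logrank_test <- function(clin, groups) {
  d <- surv_align(clin, groups)
  k <- length(unique(d$group))
  if (k < 2L) stop2("log-rank needs >= 2 non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  list(statistic = unname(sd_$chisq), dof = k - 1L,
       p = stats::pchisq(sd_$chisq, df = k - 1L, lower.tail = FALSE))
}

#' Harrell's concordance index for a risk score or ordered risk groups
#'
#' A pair of samples is usable when the shorter observed time carries an
#' event (or the times tie with discordant event status, in which case the
#' censored sample is the survivor); risk ties contribute 0.5.  Computed via
#' `survival::concordance()` with `reverse = TRUE`, so C > 0.5 means higher
#' risk goes with shorter survival.  The confidence interval is the normal
#' approximation C +/- z * se with the infinitesimal-jackknife standard
#' error reported by the survival package.
#'
#' @param clin clinical data frame with `sample`, `time`, `event`.
#' @param risk named numeric vector (sample -> risk score), or a named
#'   character/factor vector of ordinal groups combined with `group_order`.
#' @param group_order explicit low-to-high ordering of the group labels when
#'   `risk` is categorical (e.g. `c("low", "intermediate", "high")`);
#'   categorical risk without an ordering is an error.
#' @param conf_level confidence level for the interval; default 0.95.
#' @return list with `C`, `se`, `ci` (length-2 vector), `n`,
#'   `usable_pairs` (concordant + discordant + risk-tied).
#' @export
concordance_index <- function(clin, risk, group_order = NULL,
                              conf_level = 0.95) {
  if (is.null(names(risk))) stop2("risk must be named by sample")
  if (is.character(risk) || is.factor(risk)) {
    if (is.null(group_order))
      stop2("categorical risk needs an explicit group_order (low to high)")
    lev <- as.character(risk)
    if (!all(lev %in% group_order))
      stop2("risk label(s) outside group_order: ",
            paste(setdiff(lev, group_order), collapse = ", "))
    risk <- stats::setNames(match(lev, group_order), names(risk))
  }
  common <- intersect(clin$sample, names(risk))
  if (length(common) < 2L) stop2("risk defined on < 2 clinical samples")
  d <- clin[match(common, clin$sample), , drop = FALSE]
  d$risk <- unname(risk[common])
  fit <- survival::concordance(survival::Surv(time, event) ~ risk,
                               data = d, reverse = TRUE)
  cnt <- fit$count
  usable <- unname(cnt["concordant"] + cnt["discordant"] + cnt["tied.x"])
  if (usable == 0) stop2("no usable pairs (all times censored or tied)")
  se <- sqrt(fit$var)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(C = unname(fit$concordance), se = unname(se),
       ci = unname(c(fit$concordance - z * se, fit$concordance + z * se)),
       n = length(common), usable_pairs = usable)
}
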