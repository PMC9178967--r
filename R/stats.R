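DIST_LEVELS <- c("WMH", "2", "4", "6", "8", "10")

#' Natural-log lesion volume
#'
#' @param v_ml WMH volume, mL (> 0; zero-lesion subjects are excluded
#'   upstream).
#' @return `log(v_ml)` (natural log).
#' @export
log_wmh_volume <- function(v_ml) {
  if (any(v_ml <= 0)) stop("WMH volume must be > 0 (zero-WMH subjects excluded)")
  log(v_ml)
}

#' Group-wise standardization of continuous predictors
#'
#' Centers each predictor at its group mean and divides by the group
#' standard deviation (or globally when `by_group = FALSE`), adding
#' `<var>_z` columns.
#'
#' @param table Data frame with a `group` column.
#' @param vars Predictors to standardize.
#' @param by_group Standardize within group.
#' @return The table with added `_z` columns.
#' @export
standardize_predictors <- function(table,
                                   vars = intersect(c("age", "moca",
                                                      "log_wmh_volume"),
                                                    names(table)),
                                   by_group = TRUE) {
  g <- if (by_group) table$group else rep("all", nrow(table))
  for (v in vars) {
    z <- rep(NA_real_, nrow(table))
    for (gl in unique(g)) {
      i <- g == gl
      s <- sd(table[[v]][i])
      if (!is.finite(s) || s == 0)
        stop(sprintf("zero variance in predictor '%s' within group '%s'", v, gl))
      z[i] <- (table[[v]][i] - mean(table[[v]][i])) / s
    }
    table[[paste0(v, "_z")]] <- z
  }
  table
}

#' Orthogonal polynomial contrast codes for distance
#'
#' Linear and quadratic orthogonal polynomial columns over equally spaced
#' scores for the ordered distance levels; columns are zero-sum, mutually
#' orthogonal and unit-normalized.
#'
#' @param levels Ordered level labels (default `WMH, 2, ..., 10`).
#' @return Matrix with columns `.L` and `.Q`, rows named by level.
#' @export
quadratic_contrast <- function(levels = DIST_LEVELS) {
  cp <- contr.poly(length(levels))[, 1:2, drop = FALSE]
  dimnames(cp) <- list(levels, c(".L", ".Q"))
  cp
}

# distance factor carrying only the linear + quadratic polynomial codes
distance_factor <- function(x, levels = DIST_LEVELS) {
  f <- factor(as.character(x), levels = levels)
  if (anyNA(f)) stop("unknown distance levels: ",
                     paste(setdiff(unique(as.character(x)), levels),
                           collapse = ", "))
  contrasts(f, how.many = 2) <- quadratic_contrast(levels)
  f
}

prepare_metric_table <- function(table, outcome) {
  tab <- table[table$metric == outcome, , drop = FALSE]
  if (nrow(tab) == 0) stop(sprintf("no rows for outcome '%s'", outcome))
  missing_lev <- setdiff(DIST_LEVELS, unique(as.character(tab$distance_level)))
  if (length(missing_lev))
    stop("absent distance levels: ", paste(missing_lev, collapse = ", "))
  tab$distance <- distance_factor(tab$distance_level)
  tab$scanner <- factor(tab$scanner)
  tab$subject_id <- factor(tab$subject_id)
  tab
}

new_penumbra_lmm <- function(model, family, outcome, headline) {
  sm <- summary(model)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "df", "t", "p")[seq_len(ncol(ct))]
  ct$term <- rownames(ct)
  rownames(ct) <- NULL
  structure(list(model = model, family = family, outcome = outcome,
                 terms = ct[, c("term", "estimate", "se", "df", "t", "p")],
                 headline = headline,
                 singular = lme4::isSingular(model),
                 converged =
                   length(model@optinfo$conv$lme4$messages) == 0),
            class = "penumbra_lmm")
}

#' @export
print.penumbra_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model [%s], outcome %s\n", x$family, x$outcome))
  if (x$singular) cat("  (singular random-effects fit)\n")
  if (!x$converged) cat("  (convergence warning)\n")
  tt <- x$terms
  tt$estimate <- signif(tt$estimate, 4)
  tt$se <- signif(tt$se, 3)
  tt$p <- signif(tt$p, 3)
  print(tt[, c("term", "estimate", "se", "df", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.penumbra_lmm <- function(object, ...) {
  setNames(object$terms$estimate, object$terms$term)
}

#' @export
summary.penumbra_lmm <- function(object, ...) summary(object$model, ...)

#' Extract one term's row from a fitted model
#'
#' @param fit A `penumbra_lmm`.
#' @param term Term name (as in `fit$terms$term`).
#' @return One-row data frame.
#' @export
term_row <- function(fit, term) {
  r <- fit$terms[fit$terms$term == term, , drop = FALSE]
  if (nrow(r) == 0) stop(sprintf("term '%s' not in model", term))
  r
}

#' Distance-by-group mixed model
#'
#' Fixed effects: standardized age and MoCA, distance (orthogonal linear +
#' quadratic polynomial codes over WMH, 2, ..., 10 mm), group
#' (older-adult baseline, coefficient labelled for the stroke level), and
#' the distance-by-group interaction. Random effects: scanner intercept
#' and participant nested within scanner. P-values use the Satterthwaite
#' degree-of-freedom approximation. The headline "Distance" row is the
#' quadratic column.
#'
#' @param table Long-format ROI table (one row per subject x distance
#'   level x metric) with covariates `age`, `moca`, `group`, `scanner`.
#' @param outcome Metric name (`"FA"`, `"MD"`, `"MWF"`, `"GMT2"`).
#' @return A `penumbra_lmm`.
#' @export
fit_distance_group <- function(table, outcome) {
  tab <- prepare_metric_table(table, outcome)
  tab$group <- factor(tab$group, levels = c("older_adult", "stroke"))
  if (any(table(tab$group[!duplicated(tab$subject_id)]) < 2))
    stop("need >= 2 subjects per group")
  if (anyNA(tab$age) || anyNA(tab$moca)) stop("incomplete covariates")
  tab <- standardize_predictors(tab, c("age", "moca"))
  m <- lmerTest::lmer(
    mean ~ age_z + moca_z + distance * group + (1 | scanner / subject_id),
    data = tab, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular =
                                  lme4::.makeCC(action = "ignore", tol = 1e-4)))
  headline <- data.frame(
    label = c("Age", "MoCA", "Distance", "Group (S)", "Distance*group"),
    term = c("age_z", "moca_z", "distance.Q", "groupstroke",
             "distance.Q:groupstroke"), stringsAsFactors = FALSE)
  new_penumbra_lmm(m, "distance_group", outcome, headline)
}

#' Distance-by-hemisphere mixed model (unilateral stroke)
#'
#' Same structure as [fit_distance_group()] with hemisphere
#' (contralesional baseline; coefficient labelled for the ipsilesional
#' level) replacing group. Bilateral-stroke subjects are dropped with a
#' message; the table must carry per-hemisphere ROI means.
#'
#' @inheritParams fit_distance_group
#' @return A `penumbra_lmm`.
#' @export
fit_distance_hemisphere <- function(table, outcome) {
  tab <- table[table$group == "stroke" &
                 table$hemisphere_of_stroke %in% c("left", "right"), ,
               drop = FALSE]
  n_drop <- length(unique(table$subject_id[table$group == "stroke"])) -
    length(unique(tab$subject_id))
  if (n_drop > 0)
    message(sprintf("excluding %d bilateral/no-hemisphere stroke subject(s)",
                    n_drop))
  if (!"hemisphere" %in% names(tab) || all(is.na(tab$hemisphere)))
    stop("table lacks per-hemisphere ROI rows")
  tab <- prepare_metric_table(tab, outcome)
  tab$hemisphere <- factor(tab$hemisphere,
                           levels = c("contralesional", "ipsilesional"))
  tab <- standardize_predictors(tab, c("age", "moca"), by_group = FALSE)
  m <- lmerTest::lmer(
    mean ~ age_z + moca_z + distance * hemisphere +
      (1 | scanner / subject_id),
    data = tab, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular =
                                  lme4::.makeCC(action = "ignore", tol = 1e-4)))
  headline <- data.frame(
    label = c("Age", "MoCA", "Distance", "Hemisphere (I)",
              "Distance*hemisphere"),
    term = c("age_z", "moca_z", "distance.Q", "hemisphereipsilesional",
             "distance.Q:hemisphereipsilesional"), stringsAsFactors = FALSE)
  new_penumbra_lmm(m, "distance_hemisphere", outcome, headline)
}

#' Lesion-volume model on WMH-ROI metrics
#'
#' One row per subject (the WMH ROI only): fixed effects standardized age,
#' MoCA and natural-log WMH volume; random intercept for scanner only (no
#' repeated measures).
#'
#' @inheritParams fit_distance_group
#' @return A `penumbra_lmm`.
#' @export
fit_wmh_volume_model <- function(table, outcome) {
  tab <- table[table$metric == outcome &
                 as.character(table$distance_level) == "WMH", , drop = FALSE]
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject rows in WMH table")
  if (nrow(tab) == 0) stop(sprintf("no WMH rows for outcome '%s'", outcome))
  tab$log_wmh_volume <- log_wmh_volume(tab$wmh_volume_ml)
  tab$scanner <- factor(tab$scanner)
  tab <- standardize_predictors(tab, c("age", "moca", "log_wmh_volume"))
  m <- lmerTest::lmer(
    mean ~ age_z + moca_z + log_wmh_volume_z + (1 | scanner),
    data = tab, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular =
                                  lme4::.makeCC(action = "ignore", tol = 1e-4)))
  headline <- data.frame(
    label = c("Age", "MoCA", "WMH volume"),
    term = c("age_z", "moca_z", "log_wmh_volume_z"), stringsAsFactors = FALSE)
  new_penumbra_lmm(m, "wmh_volume", outcome, headline)
}

#' Tukey-adjusted post hoc contrasts
#'
#' `family = "distance"`: all pairwise distance-level contrasts (15 for 6
#' levels). `family = "interaction"`: pairwise distance levels within each
#' group plus group contrasts within each distance level (follow-up to a
#' distance-by-group interaction; for the hemisphere model the second
#' factor is hemisphere). Adjusted p-values use the studentized-range
#' (Tukey) family correction.
#'
#' @param fit A `penumbra_lmm` from [fit_distance_group()] or
#'   [fit_distance_hemisphere()].
#' @param family Contrast family.
#' @return Data frame with `contrast`, `by`, `estimate`, `p_raw`,
#'   `p_adj`, `family_size`.
#' @export
tukey_posthoc <- function(fit, family = c("distance", "interaction")) {
  family <- match.arg(family)
  model <- fit$model
  fac2 <- if (fit$family == "distance_hemisphere") "hemisphere" else "group"
  as_df <- function(prs, by = NA_character_) {
    adj <- as.data.frame(prs)
    raw <- as.data.frame(update(prs, adjust = "none"))
    data.frame(contrast = as.character(adj$contrast),
               by = if (!is.null(adj[[by]])) as.character(adj[[by]]) else NA,
               estimate = adj$estimate, p_raw = raw$p.value,
               p_adj = pmax(adj$p.value, raw$p.value),
               family_size = nrow(adj), stringsAsFactors = FALSE)
  }
  if (family == "distance") {
    emm <- emmeans::emmeans(model, "distance")
    as_df(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  } else {
    e1 <- emmeans::emmeans(model, "distance", by = fac2)
    e2 <- emmeans::emmeans(model, fac2, by = "distance")
    rbind(as_df(emmeans::contrast(e1, "pairwise", adjust = "tukey"), fac2),
          as_df(emmeans::contrast(e2, "pairwise", adjust = "tukey"),
                "distance"))
  }
}

#' Simulate a long-format ROI table directly
#'
#' ROI-level generative model matching the mixed-model structure: metric
#' mean = grand mean + scanner intercept + subject intercept + programmed
#' distance profile + group shift + interaction + residual noise. With the
#' default null effects the table realizes the programmed-null conditions
#' used for type-I error checks.
#'
#' @param n_older,n_stroke Group sizes.
#' @param effects List with `grand`, `profile` (a [gradient_profile()] or
#'   `NULL` for flat), `group_shift`, `wmh_interaction` (extra shift in
#'   the stroke WMH ROI), `sd_scanner`, `sd_subject`, `sd_resid`.
#' @param metric Metric name for the rows.
#' @param seed Integer seed.
#' @return Long-format data frame compatible with [fit_distance_group()].
#' @export
simulate_roi_table <- function(n_older, n_stroke,
                               effects = list(grand = 80, profile = NULL,
                                              group_shift = 0,
                                              wmh_interaction = 0,
                                              sd_scanner = 0.5,
                                              sd_subject = 1,
                                              sd_resid = 1),
                               metric = "GMT2", seed = 1L) {
  set.seed(as.integer(seed))
  groups <- c(rep("older_adult", n_older), rep("stroke", n_stroke))
  n <- length(groups)
  scanners <- rep_len(c("A_32echo", "B_48echo"), n)
  sc_re <- setNames(rnorm(2, 0, effects$sd_scanner),
                    c("A_32echo", "B_48echo"))
  # ring mid-distances: WMH at 0, ring k at 2k - 1 mm
  dmid <- c(0, 2 * (1:5) - 1)
  prof <- if (is.null(effects$profile)) rep(effects$grand, 6)
          else profile_value(effects$profile, dmid)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    su_re <- rnorm(1, 0, effects$sd_subject)
    mu <- prof + sc_re[scanners[i]] + su_re
    if (groups[i] == "stroke") {
      mu <- mu + effects$group_shift
      mu[1] <- mu[1] + effects$wmh_interaction
    }
    rows[[i]] <- data.frame(
      subject_id = sprintf("sub-%03d", i), group = groups[i],
      scanner = scanners[i], age = round(runif(1, 45, 80), 1),
      moca = max(0, min(30, round(rnorm(1, 26, 2.5)))),
      hemisphere_of_stroke = ifelse(groups[i] == "stroke", "left", "none"),
      wmh_volume_ml = exp(rnorm(1, log(0.4), 0.8)),
      distance_level = DIST_LEVELS, metric = metric,
      mean = mu + rnorm(6, 0, effects$sd_resid),
      n_voxels = 100L, hemisphere = NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
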