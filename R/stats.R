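# Univariate checks: 2x2 attention-by-tone ANOVA on per-cell ERP means and
# post-hoc paired t-tests, plus the behavioral reaction-time comparison.

#' Paired t-test
#'
#' Thin wrapper around [stats::t.test()] (two-tailed, paired):
#' `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1`.
#'
#' @param x,y paired per-subject values, equal length n >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2, "stats",
              "paired_t needs two equal-length vectors, n >= 2")
  d <- x - y
  assert_that(stats::sd(d) > 0, "stats",
              "all pairwise differences are equal; t undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Per-subject cell means of ERP peak amplitudes
#'
#' For every subject, filters and baseline-corrects the selected pre-probe
#' trials of every block (both tone types), extracts per-trial N1 and P3
#' peaks and averages them within each attention-state x tone cell.
#' Subjects lacking any of the four cells are dropped with a warning (the
#' ANOVA needs the complete 2x2 design).
#'
#' @param cohort list of `mw_session`.
#' @param spec an `mw_feature_spec`.
#' @return data.frame with columns `subject_id`, `attention`, `tone`,
#'   `n1`, `p3` (4 rows per retained subject).
#' @export
cell_means_table <- function(cohort, spec = feature_spec()) {
  out <- list()
  for (session in cohort) {
    sel <- lapply(session$blocks, select_preprobe_trials,
                  n = spec$trials_per_block)
    states <- rep(vapply(session$blocks, `[[`, "", "probe_response"),
                  lengths(sel))
    epochs <- unlist(sel, recursive = FALSE)
    if (!length(epochs)) next
    tones <- vapply(epochs, function(e) as.character(e$tone_type), "")
    pk <- peaks_for_epochs(epochs, spec, session$sampling_rate_hz,
                           session$time_ms)
    cells <- expand.grid(attention = c("on_task", "mind_wandering"),
                         tone = c("standard", "target"),
                         stringsAsFactors = FALSE)
    cells$n1 <- NA_real_; cells$p3 <- NA_real_
    for (i in seq_len(nrow(cells))) {
      m <- states == cells$attention[i] & tones == cells$tone[i]
      if (any(m)) {
        cells$n1[i] <- mean(pk$n1[m])
        cells$p3[i] <- mean(pk$p3[m])
      }
    }
    if (anyNA(cells$n1)) {
      warning(sprintf("%s: incomplete attention x tone design; dropped",
                      session$subject_id), call. = FALSE)
      next
    }
    cells$subject_id <- session$subject_id
    out[[session$subject_id]] <- cells
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-factor attention x tone ANOVA on cell means
#'
#' Fixed-effects two-way ANOVA with interaction on the 4n per-subject cell
#' means (n subjects x 2 attention states x 2 tones), fitted with
#' [stats::lm()]. Each effect has 1 numerator df and the error term
#' `4n - 4` df. Effects with zero sum of squares get F = 0 by convention
#' (degenerate all-equal input).
#'
#' @param cells output of [cell_means_table()] (or any data.frame with
#'   `attention`, `tone` and the value column).
#' @param value name of the response column, e.g. `"n1"` or `"p3"`.
#' @return list with `F_attention`, `F_tone`, `F_interaction`, `df1`,
#'   `df2`, `p_attention`, `p_tone`, `p_interaction`, and the `anova`
#'   table.
#' @export
anova_2x2 <- function(cells, value = "n1") {
  assert_that(value %in% names(cells), "stats",
              sprintf("no column '%s' in cells", value))
  counts <- table(cells$attention, cells$tone)
  assert_that(identical(dim(counts), c(2L, 2L)) && all(counts > 0),
              "stats", "incomplete 2x2 attention x tone design")
  d <- data.frame(y = cells[[value]],
                  attention = factor(cells$attention),
                  tone = factor(cells$tone))
  fit <- stats::lm(y ~ attention * tone, data = d)
  an <- suppressWarnings(stats::anova(fit))   # degenerate zero-residual input
  eff <- c("attention", "tone", "attention:tone")
  ss <- an[eff, "Sum Sq"]; ms_err <- an["Residuals", "Mean Sq"]
  f <- an[eff, "F value"]; p <- an[eff, "Pr(>F)"]
  zero <- ss < 1e-22
  f[zero] <- 0; p[zero] <- 1          # degenerate 0/0 cases
  f[!zero & !is.finite(f)] <- Inf
  list(F_attention = f[1], F_tone = f[2], F_interaction = f[3],
       df1 = 1L, df2 = an["Residuals", "Df"],
       p_attention = p[1], p_tone = p[2], p_interaction = p[3],
       anova = an)
}

#' Post-hoc paired attention contrasts per tone
#'
#' Paired t-tests of on-task vs mind-wandering per-subject cell means,
#' separately for standard and target tones.
#'
#' @param cells output of [cell_means_table()].
#' @param value response column name.
#' @return data.frame with one row per tone: `t`, `df`, `p`.
#' @export
attention_posthoc <- function(cells, value = "n1") {
  rows <- lapply(c("standard", "target"), function(tn) {
    w <- cells[cells$tone == tn, ]
    on <- w[w$attention == "on_task", ]
    mw <- w[w$attention == "mind_wandering", ]
    mw <- mw[match(on$subject_id, mw$subject_id), ]
    r <- paired_t(on[[value]], mw[[value]])
    data.frame(tone = tn, t = r$t, df = r$df, p = r$p)
  })
  do.call(rbind, rows)
}

#' Reaction-time comparison between attention states
#'
#' Averages each subject's target-tone reaction times per attention state
#' and compares them with a paired t-test (on task minus mind wandering;
#' slower mind-wandering responses give a negative t). Subjects without
#' target trials in both states are dropped.
#'
#' @param cohort list of `mw_session`.
#' @return list with `t`, `df`, `p`, `mean_on_task`, `mean_mind_wandering`,
#'   `n_subjects`.
#' @export
rt_attention_test <- function(cohort) {
  per <- lapply(cohort, function(s) {
    rt <- unlist(lapply(s$blocks, `[[`, "rt_ms"))
    st <- rep(vapply(s$blocks, `[[`, "", "probe_response"),
              vapply(s$blocks, function(b) length(b$rt_ms), 0L))
    ok <- !is.na(rt)
    c(on = mean(rt[ok & st == "on_task"]),
      mw = mean(rt[ok & st == "mind_wandering"]))
  })
  m <- do.call(rbind, per)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  assert_that(nrow(m) >= 2, "stats",
              "need >= 2 subjects with target RTs in both states")
  r <- paired_t(m[, "on"], m[, "mw"])
  c(r, list(mean_on_task = mean(m[, "on"]),
            mean_mind_wandering = mean(m[, "mw"]), n_subjects = nrow(m)))
}
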