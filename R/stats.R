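#' Event timings relative to ROSC across subjects
#'
#' For each subject's event set, computes `rosc_time - event_time` in
#' seconds (positive = before ROSC) for every PIVA peak and the etCO2 rise.
#' Events after ROSC give negative entries, retained. Missing events (e.g.
#' the etCO2 rule never met) give `NA` cells, noted via `message()`.
#'
#' @param event_sets list of `piva_event_set` objects (or equivalent lists
#'   read back by [read_events()]), one per subject.
#' @return data.frame of class `piva_timing_table`: column `subject` plus
#'   one column per event type (`<channel>_piva_peak`, `etco2_rise`), values
#'   in seconds before ROSC.
#' @export
build_timing_table <- function(event_sets) {
  if (!length(event_sets)) stop("no event sets supplied")
  if (is.null(names(event_sets))) {
    names(event_sets) <- sprintf("subject_%02d", seq_along(event_sets))
  }
  channels <- unique(unlist(lapply(event_sets,
                                   function(es) names(es$piva_peak_time))))
  cols <- c(paste0(channels, "_piva_peak"), "etco2_rise")
  tab <- as.data.frame(matrix(NA_real_, nrow = length(event_sets),
                              ncol = length(cols),
                              dimnames = list(NULL, cols)))
  for (i in seq_along(event_sets)) {
    es <- event_sets[[i]]
    rosc <- es$rosc_time
    for (ch in channels) {
      et <- es$piva_peak_time[[ch]]
      if (!is.null(et) && is.finite(et)) {
        tab[i, paste0(ch, "_piva_peak")] <- rosc - et
      }
    }
    et <- es$etco2_rise_time
    if (!is.null(et) && length(et) == 1L && is.finite(et)) {
      tab[i, "etco2_rise"] <- rosc - et
    } else {
      message("subject ", names(event_sets)[i], ": etCO2 event absent")
    }
  }
  out <- cbind(data.frame(subject = names(event_sets),
                          stringsAsFactors = FALSE), tab)
  class(out) <- c("piva_timing_table", "data.frame")
  out
}

#' Mean, standard error and n
#'
#' The reporting convention for event timings: arithmetic mean and standard
#' error of the mean (sample SD with n-1 denominator over sqrt(n); 0 when
#' n = 1). `NA`s are dropped.
#'
#' @param values numeric vector.
#' @return list with `mean`, `se`, `n`; `NULL` when no finite values remain.
#' @export
describe_timing <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n == 0L) return(NULL)
  se <- if (n == 1L) 0 else stats::sd(v) / sqrt(n)
  list(mean = mean(v), se = se, n = n)
}

#' Shapiro-Wilk normality screen
#'
#' Thin, validated wrapper around the standard Shapiro-Wilk statistic,
#' applied to each event type before the parametric comparisons.
#'
#' @param values numeric vector, 3 <= n <= 5000 after dropping `NA`s.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3L) stop("Shapiro-Wilk requires at least 3 observations")
  if (length(v) > 5000L) stop("Shapiro-Wilk limited to 5000 observations")
  if (stats::sd(v) == 0) {
    stop("Shapiro-Wilk undefined for a constant vector (zero variance)")
  }
  sw <- stats::shapiro.test(v)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Uncorrected Fisher's LSD pairwise comparisons
#'
#' Between-group mode (default): one-way ANOVA pooled error mean square
#' MSE with df = N - k, then every pair tested with
#' t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j)), two-sided,
#' uncorrected. Paired mode treats rows of a rectangular subjects x groups
#' layout as blocks (repeated-measures error term, df = (n - 1)(k - 1)) —
#' appropriate when every subject contributes all event types; pass
#' `paired = TRUE` and equal-length groups measured on the same subjects in
#' the same order.
#'
#' @param groups named list of numeric vectors (event type -> timings);
#'   `NA`s dropped per group (unpaired) or per subject row (paired).
#' @param alpha significance threshold (default 0.05).
#' @param paired logical (default FALSE).
#' @return list of class `piva_lsd`: `groups` (data.frame with `group`,
#'   `mean`, `se`, `n`, Shapiro-Wilk `W` and `p` where n >= 3), `p_values`
#'   (symmetric k x k matrix), `t_values`, `significant` (logical matrix at
#'   `alpha`), `mse`, `df`, `alpha`, `paired`.
#' @export
fisher_lsd <- function(groups, alpha = 0.05, paired = FALSE) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  if (paired) {
    lens <- lengths(groups)
    if (length(unique(lens)) != 1L) {
      stop("paired mode requires equal-length groups (subjects x groups)")
    }
    mat <- do.call(cbind, groups)
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    n <- nrow(mat)
    if (n < 2L) stop("paired mode needs at least 2 complete subjects")
    grand <- mean(mat)
    subj_eff <- rowMeans(mat) - grand
    grp_eff <- colMeans(mat) - grand
    resid <- mat - outer(subj_eff, grp_eff, `+`) - grand
    df <- (n - 1L) * (k - 1L)
    mse <- sum(resid^2) / df
    ns <- rep(n, k)
    means <- colMeans(mat)
    clean <- lapply(seq_len(k), function(j) mat[, j])
    names(clean) <- names(groups)
  } else {
    clean <- lapply(groups, function(v) v[is.finite(v)])
    ns <- lengths(clean)
    if (any(ns < 2L)) {
      stop("each group needs n >= 2 (got: ",
           paste(sprintf("%s=%d", names(groups), ns), collapse = ", "), ")")
    }
    means <- vapply(clean, mean, numeric(1))
    df <- sum(ns) - k
    mse <- sum(vapply(clean, function(v) sum((v - mean(v))^2), numeric(1))) / df
  }
  if (mse <= 0) stop("zero pooled variance: LSD t statistics undefined")
  tmat <- pmat <- matrix(NA_real_, k, k,
                         dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se_ij <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tv <- (means[i] - means[j]) / se_ij
      pv <- 2 * stats::pt(-abs(tv), df)
      tmat[i, j] <- tmat[j, i] <- tv
      pmat[i, j] <- pmat[j, i] <- pv
    }
  }
  diag(pmat) <- 1
  diag(tmat) <- 0
  gdf <- do.call(rbind, lapply(names(groups), function(g) {
    d <- describe_timing(clean[[g]])
    sw <- if (d$n >= 3 && stats::sd(clean[[g]]) > 0) {
      shapiro_wilk(clean[[g]])
    } else {
      list(W = NA_real_, p = NA_real_)
    }
    data.frame(group = g, mean = d$mean, se = d$se, n = d$n,
               shapiro_W = sw$W, shapiro_p = sw$p)
  }))
  structure(list(groups = gdf, t_values = tmat, p_values = pmat,
                 significant = pmat < alpha, mse = mse, df = df,
                 alpha = alpha, paired = paired),
            class = "piva_lsd")
}

#' @export
print.piva_lsd <- function(x, ...) {
  cat(sprintf("Fisher's LSD (%s), alpha = %g, MSE = %.4g, df = %d\n",
              if (x$paired) "paired" else "between-group",
              x$alpha, x$mse, x$df))
  print(x$groups, row.names = FALSE)
  cat("pairwise p-values:\n")
  print(signif(x$p_values, 4))
  invisible(x)
}

#' Timing comparison across event types
#'
#' Convenience wrapper: builds the timing table from per-subject event
#' sets, describes each event type (mean +/- SE before ROSC), screens
#' normality, and runs uncorrected Fisher's LSD across event types when at
#' least two subjects contribute.
#'
#' @param event_sets list of event sets, one per subject.
#' @param alpha LSD significance threshold.
#' @param paired use the repeated-measures error term (see [fisher_lsd()]).
#' @return list with `timing_table` and `comparisons` (a [fisher_lsd()]
#'   result, or `NULL` with a message when fewer than 2 usable subjects).
#' @export
compare_event_timings <- function(event_sets, alpha = 0.05, paired = FALSE) {
  tab <- build_timing_table(event_sets)
  groups <- as.list(tab[, setdiff(names(tab), "subject"), drop = FALSE])
  usable <- vapply(groups, function(v) sum(is.finite(v)), integer(1))
  comparisons <- NULL
  if (nrow(tab) >= 2L && sum(usable >= 2L) >= 2L) {
    comparisons <- fisher_lsd(groups[usable >= 2L], alpha = alpha,
                              paired = paired)
  } else {
    message("fewer than two usable groups/subjects: descriptives only, ",
            "comparisons skipped")
  }
  list(timing_table = tab, comparisons = comparisons)
}
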