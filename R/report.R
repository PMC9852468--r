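# Figure-level aggregation: per-site replicate means/sd, cross-site medians
# and quartiles per platform, fold changes against a baseline platform, and
# Student's t comparisons.
#
# The input is a tidy replicate-level table with columns `site`, `platform`
# and `value` (one row per biological replicate; `value` is typically an
# editing percentage from summarize_calls()).

.check_replicate_table <- function(df) {
  if (!all(c("site", "platform", "value") %in% names(df)))
    .stop("need columns 'site', 'platform', 'value'", "penquant_config_error")
  invisible(df)
}

#' Aggregate replicate-level editing values
#'
#' Per site/platform: mean and sd over replicates. Per platform: median and
#' quartiles over the site means (quartiles use linear interpolation,
#' `stats::quantile` type 7).
#'
#' @param df replicate-level data.frame (`site`, `platform`, `value`).
#' @return list with `per_site` (`site`, `platform`, `n`, `mean`, `sd`) and
#'   `per_platform` (`platform`, `n_sites`, `median`, `q1`, `q3`).
#' @export
aggregate_editing <- function(df) {
  .check_replicate_table(df)
  key <- interaction(df$site, df$platform, drop = TRUE, sep = "\r")
  per_site <- do.call(rbind, lapply(levels(key), function(k) {
    v <- df$value[key == k]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(site = parts[1], platform = parts[2], n = length(v),
               mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_site <- per_site[order(per_site$platform, per_site$site), ,
                       drop = FALSE]
  rownames(per_site) <- NULL
  per_platform <- do.call(rbind, lapply(unique(per_site$platform),
                                        function(pl) {
    m <- per_site$mean[per_site$platform == pl]
    q <- quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(platform = pl, n_sites = length(m), median = q[2],
               q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
  }))
  rownames(per_platform) <- NULL
  list(per_site = per_site, per_platform = per_platform)
}

#' Per-site fold changes against a baseline platform
#'
#' The mean value of `baseline_platform` at each site is set to 1 and the
#' other platforms' site means are normalized to it. Sites where the
#' baseline mean is 0 get `NA` folds (with a warning) and are excluded from
#' the cross-site medians.
#'
#' @param df replicate-level data.frame (`site`, `platform`, `value`).
#' @param baseline_platform platform used as the denominator; must be
#'   present at every site.
#' @return list with `per_site` (`site`, `platform`, `fold`) and `median`
#'   (`platform`, `n_sites`, `median_fold`).
#' @export
fold_change <- function(df, baseline_platform) {
  .check_replicate_table(df)
  agg <- aggregate_editing(df)$per_site
  base <- agg[agg$platform == baseline_platform, , drop = FALSE]
  sites <- unique(agg$site)
  if (!all(sites %in% base$site))
    .stop("baseline platform missing for some sites", "penquant_config_error")
  base_mean <- setNames(base$mean, base$site)
  if (any(base_mean == 0))
    warning("baseline mean is 0 at some sites; folds undefined there",
            call. = FALSE)
  per_site <- agg
  per_site$fold <- ifelse(base_mean[per_site$site] == 0, NA_real_,
                          per_site$mean / base_mean[per_site$site])
  per_site <- per_site[, c("site", "platform", "fold")]
  med <- do.call(rbind, lapply(unique(per_site$platform), function(pl) {
    f <- per_site$fold[per_site$platform == pl]
    f <- f[!is.na(f)]
    data.frame(platform = pl, n_sites = length(f),
               median_fold = if (length(f)) median(f) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(med) <- NULL
  list(per_site = per_site, median = med)
}

#' Compare two platforms: per-site t-tests and a fold-change test
#'
#' Per site, a two-tailed two-sample Student's t-test (equal variances by
#' default; `var_equal = FALSE` gives Welch) of the replicate values of
#' `platform_a` versus `platform_b`. Additionally, the per-site folds of
#' `platform_b` normalized to `platform_a` site means are tested against 1
#' with a two-tailed one-sample t-test.
#'
#' @param df replicate-level data.frame (`site`, `platform`, `value`).
#' @param platform_a,platform_b platforms to compare (b is normalized to a).
#' @param var_equal assume equal variances (default TRUE).
#' @return list with `per_site` (`site`, `t`, `df`, `p`) and `fold_test`
#'   (list: `folds`, `t`, `df`, `p`; `NA` when fewer than 2 sites).
#' @export
compare_platforms <- function(df, platform_a, platform_b, var_equal = TRUE) {
  .check_replicate_table(df)
  sites <- sort(unique(df$site))
  per_site <- do.call(rbind, lapply(sites, function(s) {
    va <- df$value[df$site == s & df$platform == platform_a]
    vb <- df$value[df$site == s & df$platform == platform_b]
    if (length(va) < 2 || length(vb) < 2)
      .stop("need >= 2 replicates per group for t-tests",
            "penquant_config_error")
    if (sd(va) == 0 && sd(vb) == 0 && mean(va) == mean(vb)) {
      # degenerate identical groups: t = 0, p = 1
      data.frame(site = s, t = 0, df = length(va) + length(vb) - 2, p = 1,
                 stringsAsFactors = FALSE)
    } else {
      tt <- t.test(va, vb, var.equal = var_equal)
      data.frame(site = s, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(per_site) <- NULL

  fc <- fold_change(df[df$platform %in% c(platform_a, platform_b), ,
                       drop = FALSE], platform_a)
  folds <- fc$per_site$fold[fc$per_site$platform == platform_b]
  folds <- folds[!is.na(folds)]
  fold_test <- if (length(folds) >= 2 && sd(folds) > 0) {
    tt <- t.test(folds, mu = 1)
    list(folds = folds, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  } else if (length(folds) >= 2) {
    list(folds = folds, t = 0, df = length(folds) - 1,
         p = if (all(folds == 1)) 1 else NA_real_)
  } else {
    list(folds = folds, t = NA_real_, df = NA_real_, p = NA_real_)
  }
  list(per_site = per_site, fold_test = fold_test)
}
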