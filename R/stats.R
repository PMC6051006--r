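#' Per-group descriptive summary of a feature table
#'
#' Sample mean and SD (n-1 denominator) of each band's relative energy
#' (percent) per diagnostic group — the layout of the published cohort table.
#'
#' @param features A `feature_table` from [build_feature_table()].
#' @return data.frame with columns `band`, `group`, `mean_pct`, `sd_pct`, `n`.
#' @export
summarize_features <- function(features) {
  groups <- unique(features$group)
  if (length(groups) < 2L)
    stop_input("both diagnostic groups must be present (got: ",
               paste(groups, collapse = ", "), ")")
  bands <- c("delta", "theta", "alpha", "beta")
  out <- expand.grid(band = bands, group = groups, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  cols <- paste0(out$band, "_pct")
  out$mean_pct <- out$sd_pct <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v <- features[features$group == out$group[i], cols[i]]
    if (length(v) < 2L) stop_input("need >= 2 epochs per group for the summary")
    out$mean_pct[i] <- mean(v)
    out$sd_pct[i] <- sd(v)
    out$n[i] <- length(v)
  }
  out
}

#' Welch two-sample t-test from summary statistics
#'
#' The unequal-variance (Welch) t statistic with Satterthwaite fractional
#' degrees of freedom, computed directly from per-group (mean, SD, n). This
#' is the form that reproduces the published band-screening statistics from
#' the published summary table alone.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param band Optional label carried through to the result.
#' @return List of class `welch_t`: `t`, `df`, `p` (two-sided), `band`.
#' @examples
#' # alpha-band screening from published group summaries
#' welch_t_from_summary(30.60, 6.03, 218, 9.64, 7.68, 232, band = "alpha")
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2, band = NA_character_) {
  if (n1 < 2 || n2 < 2) stop_input("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop_input("SDs must be nonnegative")
  if (s1 == 0 && s2 == 0)
    stop_input("both group variances are zero; t statistic undefined")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, band = band), class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t%s: t = %.4f, df = %.1f, p = %.3g\n",
              if (is.na(x$band)) "" else paste0(" [", x$band, "]"),
              x$t, x$df, x$p))
  invisible(x)
}

#' Welch two-sample t-test from raw samples
#'
#' Identical (bit for bit) to [welch_t_from_summary()] applied to the two
#' samples' own means, SDs and sizes.
#'
#' @param x1,x2 Numeric vectors, each of length >= 2.
#' @param band Optional label.
#' @return A `welch_t` object.
#' @export
welch_t_from_samples <- function(x1, x2, band = NA_character_) {
  if (length(x1) < 2L || length(x2) < 2L) stop_input("both samples need n >= 2")
  welch_t_from_summary(mean(x1), sd(x1), length(x1),
                       mean(x2), sd(x2), length(x2), band = band)
}

#' Band-wise t screening of a feature table
#'
#' Runs the Welch test on each band's relative energy, group 1 vs group 2.
#'
#' @param features A `feature_table`.
#' @param group_order Length-2 character: which group is "group 1" (its mean
#'   enters with positive sign). Default `c("normal", "encephalopathy")`,
#'   matching the published sign convention (delta t negative).
#' @return data.frame with columns `band`, `t`, `df`, `p`.
#' @export
band_ttests <- function(features, group_order = c("normal", "encephalopathy")) {
  if (!all(group_order %in% features$group))
    stop_input("groups ", paste(group_order, collapse = ", "),
               " not all present in the feature table")
  bands <- c("delta", "theta", "alpha", "beta")
  rows <- lapply(bands, function(b) {
    col <- paste0(b, "_pct")
    r <- welch_t_from_samples(features[features$group == group_order[1], col],
                              features[features$group == group_order[2], col],
                              band = b)
    data.frame(band = b, t = r$t, df = r$df, p = r$p)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
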