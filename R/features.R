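#' Absolute and relative subband energies
#'
#' Energy of each coefficient set is its sum of squares; the total is the sum
#' over A6 and D1..D6 (for the periodized transform this equals the epoch's
#' time-domain energy). Relative energies divide by that total: delta from
#' A6, theta/alpha/beta from D6/D5/D4, and the D1-D3 sum as the
#' high-frequency residual, so the five fractions sum to one by construction.
#'
#' @param subbands A `subband_set` from [wavedec6()].
#' @return Object of class `band_energies`: list with `e_abs` (named, uV^2
#'   units per subband), `e_total`, `rel` (named fractions delta, theta,
#'   alpha, beta), `rel_residual`.
#' @export
band_energies <- function(subbands) {
  stopifnot(inherits(subbands, "subband_set"))
  e_abs <- vapply(subbands$coeffs, function(cf) sum(cf^2), numeric(1))
  e_total <- sum(e_abs)
  if (e_total == 0)
    stop(errorCondition("epoch has zero energy; relative energies undefined",
                        class = c("eegsubband_zero_energy", "error")))
  rel <- c(delta = unname(e_abs[["A6"]]),
           theta = unname(e_abs[["D6"]]),
           alpha = unname(e_abs[["D5"]]),
           beta  = unname(e_abs[["D4"]])) / e_total
  rel_residual <- (e_abs[["D3"]] + e_abs[["D2"]] + e_abs[["D1"]]) / e_total
  structure(list(e_abs = e_abs, e_total = e_total, rel = rel,
                 rel_residual = unname(rel_residual)),
            class = "band_energies")
}

#' @export
print.band_energies <- function(x, ...) {
  cat(sprintf("<band_energies> total %.4g | %s | residual %.2f%%\n", x$e_total,
              paste(sprintf("%s %.2f%%", names(x$rel), 100 * x$rel), collapse = " "),
              100 * x$rel_residual))
  invisible(x)
}

#' Per-epoch relative band-energy feature table for a cohort
#'
#' Applies the processing chain denoise -> six-level decomposition -> relative
#' energies to every epoch, yielding one row of percent-of-total band
#' energies per epoch. Zero-energy epochs are skipped with a warning and
#' recorded in the `rejects` attribute rather than producing NaN rows.
#'
#' @param cohort An `eeg_cohort`, or a plain list of [eeg_epoch()] objects.
#' @param denoise Apply [lpf_tvd()] first (default TRUE, the clinical
#'   processing order); FALSE is the ablation path.
#' @param lam,fc_hz,n_iter,tol Denoiser settings, see [lpf_tvd()].
#' @param filters,boundary Decomposition settings, see [wavedec6()].
#' @return A data.frame (class `feature_table`) with columns `epoch_id`,
#'   `group`, `delta_pct`, `theta_pct`, `alpha_pct`, `beta_pct`,
#'   `residual_pct` and attribute `rejects` (character vector of skipped
#'   epoch ids). Percentages lie in [0, 100].
#' @export
build_feature_table <- function(cohort, denoise = TRUE, lam = 0.8, fc_hz = 40,
                                n_iter = 50L, tol = 1e-6,
                                filters = db4_filters(), boundary = "periodic") {
  epochs <- if (inherits(cohort, "eeg_cohort")) cohort$epochs else cohort
  rows <- vector("list", length(epochs))
  rejects <- character()
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    stopifnot(inherits(ep, "eeg_epoch"))
    row <- tryCatch({
      proc <- if (denoise) lpf_tvd(ep, lam = lam, fc_hz = fc_hz,
                                   n_iter = n_iter, tol = tol) else ep
      be <- band_energies(wavedec6(proc, filters = filters, boundary = boundary))
      data.frame(epoch_id = ep$epoch_id, group = ep$group,
                 delta_pct = 100 * be$rel[["delta"]],
                 theta_pct = 100 * be$rel[["theta"]],
                 alpha_pct = 100 * be$rel[["alpha"]],
                 beta_pct = 100 * be$rel[["beta"]],
                 residual_pct = 100 * be$rel_residual)
    }, eegsubband_zero_energy = function(e) {
      rejects <<- c(rejects, ep$epoch_id)
      NULL
    })
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  ft <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
        else data.frame(epoch_id = character(), group = character(),
                        delta_pct = numeric(), theta_pct = numeric(),
                        alpha_pct = numeric(), beta_pct = numeric(),
                        residual_pct = numeric())
  if (length(rejects))
    warning(length(rejects), " zero-energy epoch(s) skipped: ",
            paste(rejects, collapse = ", "))
  class(ft) <- c("feature_table", class(ft))
  attr(ft, "rejects") <- rejects
  ft
}
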