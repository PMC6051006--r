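#' End-to-end screening pipeline on a synthetic cohort
#'
#' Chains the full analysis: generate (or accept) a cohort, extract denoised
#' relative band-energy features, run the band-wise Welch t screening, and
#' compare linear-SVM feature subsets under the published train/test
#' protocol. One seed drives cohort generation and the split.
#'
#' @param params [generator_params()] for the synthetic cohort; ignored when
#'   `cohort` is supplied.
#' @param cohort Optional pre-built `eeg_cohort` (e.g. from [read_epochs()]).
#' @param seed Integer master seed; the cohort uses `seed` and the split uses
#'   `seed + 1`.
#' @param denoise Apply [lpf_tvd()] before decomposition (default TRUE).
#' @param n_train_per_group Training protocol, see [split_features()].
#' @param out_dir Optional directory; when given, features, the group
#'   summary, the t table and the classifier comparison are written there via
#'   [write_results()].
#' @return List: `features`, `summary`, `ttests`, `classification`, `seed`.
#' @export
run_pipeline <- function(params = generator_params(seed = seed),
                         cohort = NULL, seed = 1L, denoise = TRUE,
                         n_train_per_group = c(encephalopathy = 100L,
                                               normal = 100L),
                         out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(params)
  features <- build_feature_table(cohort, denoise = denoise)
  summary <- summarize_features(features)
  ttests <- band_ttests(features)
  classification <- run_feature_set_comparison(
    features, n_train_per_group = n_train_per_group, seed = seed + 1L)
  out <- list(features = features, summary = summary, ttests = ttests,
              classification = classification, seed = seed)
  if (!is.null(out_dir)) {
    write_results(list(features = features, summary = summary,
                       ttests = ttests, classification = classification),
                  out_dir, run_info = list(seed = seed, denoise = denoise))
  }
  out
}
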