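#' Feature-set registry and one-call extraction
#'
#' `feature_set_names()` lists the implemented sets;
#' `extract_features()` runs the preprocessing pipeline (zero-lag 10--400 Hz
#' band-pass, 150/25 ms windows) on one subject's recordings and computes
#' the requested feature set.
#'
#' @param recs List of [emg_recording()]s from one subject, or a
#'   ready-made `window_set`.
#' @param set One of `feature_set_names()`.
#' @param kernel_seed Seed for the rocket/minirocket kernel bank.
#' @param canonical Passed to [kernel_transform()].
#' @param ... Passed to [preprocess_trials()] (e.g. `window_ms`).
#' @return A [feature_matrix()].
#' @export
extract_features <- function(recs, set = feature_set_names(),
                             kernel_seed = 1L, canonical = FALSE, ...) {
  set <- match.arg(set)
  win <- if (inherits(recs, "window_set")) recs else preprocess_trials(recs, ...)
  switch(set,
    htd = htd_set(win),
    tdpsd = tdpsd_set(win),
    tdar = tdar_set(win),
    du = du_set(win),
    wlphasor = fphasor_set(win, "wl"),
    rmsphasor = fphasor_set(win, "rms"),
    phasor = phasor_combined_set(win),
    rocket = ,
    minirocket = {
      bank <- build_bank(set, dim(win$windows)[3], dim(win$windows)[2],
                         seed = kernel_seed)
      kernel_transform(win, bank, canonical = canonical)
    })
}

#' @rdname extract_features
#' @export
feature_set_names <- function() {
  c("phasor", "wlphasor", "rmsphasor", "htd", "tdpsd", "tdar", "du",
    "rocket", "minirocket")
}
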