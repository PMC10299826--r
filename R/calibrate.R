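# Grid calibration of the free noise/threshold/feedback parameters against
# the qualitative signature suite of the full model.

#' Signature checks for a full-model parameter set
#'
#' Runs the easy discrimination test on a cohort of model bees and reports
#' whether the three easy-test behavioural signatures hold on the pooled
#' table: rejections outnumber acceptances, incorrect rejections outnumber
#' incorrect acceptances, and correct acceptances are faster on average
#' than incorrect acceptances.
#'
#' @param params A [model_params()] object.
#' @param learned A [train_weights()] state.
#' @param seeds Master seeds whose runs are pooled.
#' @param spec A [test_spec()] for the easy test.
#' @return Logical vector with elements `rejection_bias`, `fewer_false_accepts`,
#'   `fast_correct_accepts`.
#' @export
signature_check <- function(params, learned,
                            seeds = 1:4, spec = test_spec("easy")) {
  tab <- do.call(rbind, lapply(seeds, function(s) {
    run_test(spec, params, "full", learned, seed = s * 1000L)
  }))
  x <- count_responses(tab)
  t_ca <- mean(tab$decision_time[tab$category == "CA"])
  t_ia <- mean(tab$decision_time[tab$category == "IA"])
  c(rejection_bias = (x[["nCR"]] + x[["nIR"]]) > (x[["nCA"]] + x[["nIA"]]),
    fewer_false_accepts = x[["nIR"]] > x[["nIA"]],
    fast_correct_accepts = !is.na(t_ia) && !is.na(t_ca) && t_ca < t_ia)
}

#' Calibrate noise, threshold and feedback strength
#'
#' Grid-searches `sigma`, `theta` and `vr` (the parameters the behavioural
#' data leave free) for the first combination whose full-model easy-test
#' signatures all hold, scanning in the given order.  All other parameters
#' are taken from `base`.
#'
#' @param learned A [train_weights()] state.
#' @param sigma_grid,theta_grid,vr_grid Candidate values.
#' @param base Baseline [model_params()] supplying the fixed parameters.
#' @param seeds Master seeds pooled per candidate.
#' @return The first passing `model_params`, with the signature results in
#'   attribute `signatures`; `NULL` when no candidate passes.
#' @export
calibrate_model <- function(learned,
                            sigma_grid = c(0.4, 0.6, 0.8),
                            theta_grid = c(1.0, 1.25, 1.5),
                            vr_grid = c(0.4, 0.6, 0.8),
                            base = model_params(),
                            seeds = 1:4) {
  for (sg in sigma_grid) for (th in theta_grid) for (vv in vr_grid) {
    p <- unclass(base)
    p$sigma <- sg; p$theta <- th; p$vr <- vv
    cand <- do.call(model_params, p)
    sig <- signature_check(cand, learned, seeds = seeds)
    if (all(sig)) {
      attr(cand, "signatures") <- sig
      return(cand)
    }
  }
  NULL
}
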