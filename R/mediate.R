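#' One-shot mediation analysis on a data frame
#'
#' Convenience pipeline: fits the SEM and returns the mediation estimands by
#' closed-form combination, Monte Carlo g-computation, or both (in which case
#' the two methods' rows are stacked, so their agreement — a useful check of
#' Monte Carlo error — can be read off directly).
#'
#' @param data A data frame.
#' @param spec A [sem_spec()].
#' @param method `"combination"`, `"monte_carlo"`, or `"both"`.
#' @param assumption,cde_m See [mediate_combination()].
#' @param n_mc,seed Monte Carlo settings (required for the MC methods).
#' @param conf_level Confidence level for the combination intervals.
#' @return A tibble with columns `estimand`, `estimate`, `se` / `mc_se`,
#'   `ci_low`, `ci_high`, `method`, `assumption`.
#' @examples
#' sim <- simulate_sem(1500, seed = 8)
#' mediate(sim$data, sim$spec, method = "both", n_mc = 20000, seed = 9)
#' @export
mediate <- function(data, spec, method = c("combination", "monte_carlo",
                                           "both"),
                    assumption = "auto", cde_m = 0, n_mc = 100000,
                    seed = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  fit <- fit_sem(data, spec)
  out <- list()
  if (method %in% c("combination", "both")) {
    out$combination <- tibble::as_tibble(
      mediate_combination(fit, assumption = assumption, cde_m = cde_m,
                          conf_level = conf_level))
  }
  if (method %in% c("monte_carlo", "both")) {
    if (is.null(seed)) {
      stop("a seed is required for Monte Carlo g-computation", call. = FALSE)
    }
    out$monte_carlo <- tibble::as_tibble(
      mediate_montecarlo(fit, n_mc = n_mc, seed = seed,
                         assumption = assumption, cde_m = cde_m))
  }
  dplyr::bind_rows(out)
}
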