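#' Full pair score (CD and Sim) for two formulae
#'
#' Convenience wrapper combining [cd_score()] and [sim_score()]. When `dag`
#' is `NULL` or either formula has no mapped DOID, the Sim columns are `NA`.
#'
#' @inheritParams cd_score
#' @inheritParams sim_score
#' @return One-row tibble: `f1`, `f2`, `n_shared`, `cd_raw`, `cd`, `cd_band`,
#'   `sim`, `sim_band`, plus the shared-herb tibble in `shared`.
#' @examples
#' fx <- fixture_case_study()
#' pair_score(fx$formulae, "ssjy", "skt", dag = fx$ontology)
#' @export
pair_score <- function(formulae, f1, f2, dag = NULL, scale = 7.5,
                       method = c("wang", "resnik_norm", "lin"), decay = 0.5) {
  method <- match.arg(method)
  out <- cd_score(formulae, f1, f2, scale)
  sim <- NA_real_
  simb <- factor(NA, levels = c("none", "significant", "high"))
  if (!is.null(dag)) {
    r1 <- get_formula(formulae, f1); r2 <- get_formula(formulae, f2)
    if (length(r1$doids[[1]]) > 0 && length(r2$doids[[1]]) > 0) {
      s <- sim_score(formulae, dag, f1, f2, method, decay)
      sim <- s$sim; simb <- s$sim_band
    }
  }
  out$sim <- sim
  out$sim_band <- simb
  out[, c("f1", "f2", "n_shared", "cd_raw", "cd", "cd_band",
          "sim", "sim_band", "shared")]
}
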