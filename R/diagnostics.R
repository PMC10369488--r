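#' Recovery error of an additive decomposition
#'
#' An additive partitioning strives to reproduce the total wave-function
#' energy at every geometry: the per-point residual
#' `r_j = sum_i E_i(s_j) - E_tot(s_j)` measures the numerical quality of
#' the atomic integrations. A systematic (constant) residual is harmless to
#' REG slopes — they act on gradients — but its size relative to the total
#' energy is the standard quality report.
#'
#' @param dataset A [reg_dataset()] with at least one term.
#' @return An object of class `"recovery_report"`: list with `residuals`
#'   (length `M`), `rmse`, `max_abs` and `percent_of_total`
#'   (`100 * rmse / mean(|E_tot|)`).
#' @export
recovery_error <- function(dataset) {
  stopifnot(inherits(dataset, "reg_dataset"))
  if (n_terms(dataset) < 1L) {
    stop("recovery error needs at least one partitioned term", call. = FALSE)
  }
  residuals <- rowSums(dataset$terms) - dataset$e_total
  rmse <- sqrt(mean(residuals^2))
  structure(
    list(residuals = residuals,
         rmse = rmse,
         max_abs = max(abs(residuals)),
         percent_of_total = 100 * rmse / mean(abs(dataset$e_total)),
         unit = dataset$unit),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery error: RMSE %.6g %s (max |r| %.6g; %.2g%% of total energy)\n",
              x$rmse, x$unit, x$max_abs, x$percent_of_total))
  invisible(x)
}

#' Count the terms of a complete atomic partitioning
#'
#' A system of `n` atoms decomposes into `n` intra-atomic terms plus
#' `n(n-1)/2` classical electrostatic and `n(n-1)/2` exchange-correlation
#' pair terms, i.e. `n^2` terms in total — the number of atomic integrations
#' an exhaustive analysis must pay for. Vectorised over `n_atoms`.
#'
#' @param n_atoms Integer vector, each entry `>= 1`.
#' @return Data frame with columns `n_atoms`, `n_intra`, `n_cl`, `n_xc`,
#'   `n_total`.
#' @examples
#' term_count(133)  # 17689 terms for a 133-atom cluster model
#' @export
term_count <- function(n_atoms) {
  n <- as.numeric(n_atoms)
  if (length(n) < 1L || anyNA(n) || any(n < 1) || any(n != floor(n))) {
    stop("n_atoms must be integer(s) >= 1", call. = FALSE)
  }
  pairs <- n * (n - 1) / 2
  data.frame(n_atoms = n, n_intra = n, n_cl = pairs, n_xc = pairs, n_total = n^2)
}
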