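#' Small-sample-corrected Akaike information criterion
#'
#' AICc under a Gaussian likelihood with unknown common variance for a
#' weighted least-squares fit:
#' \deqn{AICc = n \ln(WRSS/n) + 2k + \frac{2k(k+1)}{n-k-1}.}
#' Used as an estimate of prediction error to rank compartmental models;
#' only free parameters count towards `k`.
#'
#' @param wrss weighted residual sum of squares (> 0).
#' @param n number of fitted frames.
#' @param k number of free parameters; requires `n > k + 1`.
#' @return The AICc score (smaller is better).
#' @examples
#' aicc(10, n = 10, k = 3) # 0 + 6 + 4 = 10
#' @export
aicc <- function(wrss, n, k) {
  if (!is.numeric(wrss) || wrss <= 0) stop("`wrss` must be > 0", call. = FALSE)
  if (n <= k + 1) {
    stop("small-sample correction undefined: need n > k + 1 (n = ", n,
         ", k = ", k, ")", call. = FALSE)
  }
  n * log(wrss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the best compartmental model by AICc
#'
#' Ranks competing fits of the same data by AICc and returns the
#' preferred one. Ties (AICc differing by less than 1e-9) are broken
#' towards the model with fewer free parameters.
#'
#' @param fits a list of [fit_model()] results fitted to identical data
#'   and weights.
#' @return An object of class `model_selection`: `$best` (the selected
#'   `kinetic_fit`) and `$ranking`, a tibble with per-model `aicc` and
#'   `delta_aicc` sorted best-first.
#' @export
select_model <- function(fits) {
  if (!is.list(fits) || length(fits) < 2 ||
      !all(vapply(fits, inherits, logical(1), "kinetic_fit"))) {
    stop("`fits` must be a list of >= 2 kinetic_fit objects", call. = FALSE)
  }
  ref <- fits[[1]]$data
  for (f in fits[-1]) {
    if (nrow(f$data) != nrow(ref) ||
        max(abs(f$data$conc - ref$conc)) > 0 ||
        max(abs(f$data$weight - ref$weight)) > 1e-12) {
      stop("all fits must be on identical data and weights", call. = FALSE)
    }
  }
  ranking <- purrr::map_dfr(fits, glance)
  # order by AICc; near-ties (< 1e-9) go to the smaller k
  ord <- order(ranking$aicc + 1e-12 * ranking$k, ranking$k)
  ranking <- ranking[ord, ]
  tied <- abs(ranking$aicc - ranking$aicc[1]) < 1e-9
  if (sum(tied) > 1) {
    first <- which(tied)[which.min(ranking$k[tied])]
    ranking <- ranking[c(first, setdiff(seq_len(nrow(ranking)), first)), ]
  }
  ranking$delta_aicc <- ranking$aicc - min(ranking$aicc)
  models <- vapply(fits, function(f) f$model, character(1))
  structure(
    list(best = fits[[match(ranking$model[1], models)]], ranking = ranking),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> selected:", x$ranking$model[1], "\n")
  print(x$ranking[, c("model", "k", "wrss", "aicc", "delta_aicc")])
  invisible(x)
}

#' @export
tidy.model_selection <- function(x, ...) {
  dplyr::mutate(x$ranking, selected = dplyr::row_number() == 1L)
}
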