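#' Relative error measures against known truth
#'
#' The three standard benchmark measures for abundance estimators. With
#' `e_i = (t_i - tau_i) / tau_i` the per-genome relative error of estimated
#' count `t_i` against true count `tau_i` over the `N` true genomes:
#' \deqn{RRMSE = 100 \sqrt{\frac{1}{N}\sum_i e_i^2}, \quad
#'       AVGRE = \frac{100}{N}\sum_i |e_i|, \quad
#'       MAXRE = 100 \max_i |e_i|.}
#' All three are reported in percent and are invariant to a common rescaling
#' of `estimated` and `truth`, so counts and relative abundances give the same
#' values when totals match. True genomes missing from the estimate count as
#' 100% error (`t_i = 0`); genomes estimated but absent from the truth are
#' excluded from the measures and reported as false positives.
#'
#' @param estimated named numeric vector of estimated per-genome counts.
#' @param truth named numeric vector of true per-genome counts, all positive.
#' @return An object of class `error_report`: list with `rrmse`, `avgre`,
#'   `maxre` (percent), `n_genomes`, and `false_positives` (character).
#' @examples
#' error_measures(c(g1 = 90, g2 = 110), c(g1 = 100, g2 = 100))
#' @export
error_measures <- function(estimated, truth) {
  if (length(truth) == 0L) stop("truth is empty")
  if (is.null(names(truth)) || is.null(names(estimated)))
    stop("estimated and truth must be named by genome id")
  if (anyNA(truth) || any(truth <= 0)) stop("all true counts must be positive")
  fp <- setdiff(names(estimated), names(truth))
  t_i <- estimated[names(truth)]
  t_i[is.na(t_i)] <- 0
  e <- (t_i - truth) / truth
  structure(list(rrmse = 100 * sqrt(mean(e^2)),
                 avgre = 100 * mean(abs(e)),
                 maxre = 100 * max(abs(e)),
                 n_genomes = length(truth),
                 false_positives = fp),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Error over %d true genomes: RRMSE %.3f%%, AVGRE %.3f%%, MAXRE %.3f%%\n",
              x$n_genomes, x$rrmse, x$avgre, x$maxre))
  if (length(x$false_positives) > 0)
    cat("False positives (excluded from measures):",
        paste(x$false_positives, collapse = ", "), "\n")
  invisible(x)
}
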