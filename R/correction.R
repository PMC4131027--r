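#' Correct read counts via the similarity linear system
#'
#' A genome's alpha-threshold read count `b_j` mixes reads it generated with
#' reads co-assigned to it because of sequence similarity. Writing `t_j` for
#' the reads a genome receives only due to its own presence, the counts
#' satisfy `b = W^T t` where `W` is the similarity matrix over the retained
#' genomes; the corrected counts are obtained by solving this system. Since
#' off-diagonal similarities are strictly below 1, `W^T` is invertible in
#' practice; a reciprocal-condition-number guard rejects near-singular
#' systems (which arise when genomes are practically indistinguishable at
#' the chosen alpha). Genomes whose solution is non-positive are dropped —
#' a genome contributing no reads of its own is not present — and the system
#' is re-solved over the survivors until all corrected counts are positive.
#'
#' @param b named numeric vector of alpha-threshold read counts, as from
#'   [alpha_count_vector()].
#' @param W_sub a [similarity_matrix()] restricted to exactly the genomes of
#'   `b`, in the same order (see [restrict_matrix()]).
#' @param cond_bound maximum tolerated condition number of `W^T`
#'   (default 1e12).
#' @param drop one-pass drop policy: `"all"` drops every non-positive genome
#'   simultaneously (default); `"one"` drops only the most negative one per
#'   pass, for sensitivity analysis.
#' @return A data frame of class `abundance_estimate` with one row per input
#'   genome: `genome_id`, `corrected_count` (`t_j`; `NA` for dropped genomes),
#'   `relative_abundance` (over survivors; `NA` for dropped) and
#'   `dropped_in_correction`.
#' @export
correct_abundance <- function(b, W_sub, cond_bound = 1e12, drop = c("all", "one")) {
  drop <- match.arg(drop)
  stopifnot(inherits(W_sub, "similarity_matrix"))
  ids <- names(b)
  if (is.null(ids) || !identical(ids, W_sub$genome_ids))
    stop("genome order of b and W_sub must be identical")
  surv <- ids
  tval <- NULL
  repeat {
    Wt <- t(W_sub$W[surv, surv, drop = FALSE])
    rc <- rcond(Wt)
    if (!is.finite(rc) || rc < 1 / cond_bound)
      stop("similarity system is numerically singular (condition number > ",
           format(cond_bound),
           "); consider a larger alpha or merging indistinguishable genomes")
    tval <- drop(solve(Wt, b[surv]))
    nonpos <- tval <= 0
    if (!any(nonpos)) break
    out <- if (drop == "all") surv[nonpos] else surv[which.min(tval)]
    surv <- setdiff(surv, out)
    if (length(surv) == 0L)
      stop("all genomes dropped in the correction stage (all corrected counts non-positive)")
  }
  cc <- rel <- stats::setNames(rep(NA_real_, length(ids)), ids)
  cc[surv] <- tval
  rel[surv] <- tval / sum(tval)
  structure(data.frame(genome_id = ids,
                       corrected_count = unname(cc),
                       relative_abundance = unname(rel),
                       dropped_in_correction = !(ids %in% surv),
                       stringsAsFactors = FALSE),
            class = c("abundance_estimate", "data.frame"))
}

#' Forward similarity mixing of true counts
#'
#' The generative direction of the correction model: given true per-genome
#' counts `t`, returns the counts `b = W^T t` that the alpha-threshold
#' assignment would produce. Useful for constructing synthetic count vectors
#' and for round-trip testing against [correct_abundance()].
#'
#' @param t numeric vector of per-genome counts.
#' @param W_sub a [similarity_matrix()] over the same genomes, same order.
#' @return Named numeric vector `b`.
#' @export
forward_counts <- function(t, W_sub) {
  stopifnot(inherits(W_sub, "similarity_matrix"))
  if (length(t) != length(W_sub$genome_ids))
    stop("length of t must match the similarity matrix dimension")
  stats::setNames(drop(crossprod(W_sub$W, t)), W_sub$genome_ids)
}
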