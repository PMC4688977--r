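# Relatedness-based selection of the imputation reference set.

#' Select an imputation reference set by genomic relatedness
#'
#' For each test animal the k most related candidates (by the cross-GRM on
#' the shared low-density panel) are taken; the union is deduplicated. If the
#' union is smaller than the target size, k is escalated (default stride 1)
#' and the selection repeated. If it is larger, candidates with the lowest
#' average relationship to all test animals are removed in one rank-ordered
#' batch until the target size is reached. Ties are broken by higher
#' relationship then lexicographic id, so the output is deterministic.
#'
#' An optional diversity post-filter greedily removes one member of any
#' selected pair whose mutual relationship exceeds a ceiling, backfilling
#' with the next-ranked unselected candidate (by mean relationship to the
#' test set); it is off by default since strong half-sib structure gives it
#' little traction.
#'
#' @param cross_grm an \code{ovimp_cross_grm} (test x candidates).
#' @param k_init initial per-test-animal selection count (default 20).
#' @param n_target target reference size (default 2000); if the candidate
#'   pool is smaller, the full pool is returned with a warning.
#' @param stride escalation increment for k.
#' @param diversity_ceiling optional relationship ceiling among selected
#'   candidates; requires \code{candidate_grm}.
#' @param candidate_grm optional \code{ovimp_grm} over the candidates, used
#'   only by the diversity filter.
#' @return character vector of selected candidate ids, sorted by id; the
#'   terminal k is attached as attribute \code{"k_final"}.
#' @export
select_reference <- function(cross_grm, k_init = 20, n_target = 2000,
                             stride = 1, diversity_ceiling = NULL,
                             candidate_grm = NULL) {
  stopifnot(inherits(cross_grm, "ovimp_cross_grm"),
            k_init >= 1, n_target >= 1, stride >= 1)
  V <- cross_grm$values
  cand <- cross_grm$candidate_ids
  if (length(cand) == 0) stop_ovimp("empty candidate pool")
  if (any(cross_grm$test_ids %in% cand)) {
    stop_ovimp("candidate pool must be disjoint from the test set")
  }
  pool_n <- length(cand)
  if (pool_n <= n_target) {
    if (pool_n < n_target) {
      warning(sprintf("candidate pool (%d) smaller than n_target (%d); returning full pool",
                      pool_n, n_target))
    }
    out <- sort(cand)
    attr(out, "k_final") <- min(k_init, pool_n)
    return(out)
  }

  # per-test-animal candidate ranking: higher relationship first, ties by id
  ranks <- lapply(seq_len(nrow(V)), function(i) {
    ord <- order(-V[i, ], cand)
    cand[ord]
  })

  k <- k_init
  repeat {
    sel <- unique(unlist(lapply(ranks, head, n = k)))
    if (length(sel) >= n_target) break
    if (k >= pool_n) {
      warning("k escalated past candidate pool size; returning full pool")
      out <- sort(cand)
      attr(out, "k_final") <- k
      return(out)
    }
    k <- min(k + stride, pool_n)
  }

  if (length(sel) > n_target) {
    # prune by lowest mean relationship to all test animals, batch by rank
    mean_rel <- colMeans(V[, match(sel, cand), drop = FALSE])
    ord <- order(-mean_rel, sel)
    sel <- sel[ord][seq_len(n_target)]
  }

  if (!is.null(diversity_ceiling)) {
    if (is.null(candidate_grm)) {
      stop_ovimp("diversity filter requires candidate_grm")
    }
    sel <- diversity_filter(sel, cand, V, candidate_grm, diversity_ceiling)
  }

  out <- sort(sel)
  attr(out, "k_final") <- k
  out
}

# Greedy within-set diversity pruning with backfill by next-ranked candidate.
diversity_filter <- function(sel, cand, V, candidate_grm, ceiling) {
  A <- as.matrix(candidate_grm)
  mean_rel <- setNames(colMeans(V), cand)
  backfill <- setdiff(cand[order(-mean_rel[cand], cand)], sel)
  repeat {
    S <- A[sel, sel, drop = FALSE]
    diag(S) <- -Inf
    over <- which(S > ceiling, arr.ind = TRUE)
    if (nrow(over) == 0) break
    i <- over[1, 1]; j <- over[1, 2]
    pair <- c(sel[i], sel[j])
    # drop the pair member with the lower mean relationship to the test set
    drop <- pair[order(mean_rel[pair], pair)][1]
    sel <- setdiff(sel, drop)
    if (length(backfill) > 0) {
      sel <- c(sel, backfill[1])
      backfill <- backfill[-1]
    } else break
  }
  sel
}
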