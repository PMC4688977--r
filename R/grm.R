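# VanRaden genomic relationship matrices: full and test x candidate blocks.

#' Compute a VanRaden genomic relationship matrix
#'
#' Method 1: G = Mc Mc' / (2 * sum p(1-p)), with Mc = M - 2p the genotype
#' matrix centred at twice the allele frequencies. Frequencies default to
#' those estimated from the individuals in the matrix being built (a base
#' population frequency is rarely available). Markers fixed at p = 0 or 1
#' contribute zero to both numerator and denominator. Dosage (non-integer)
#' genotypes are accepted, so G can be built from imputed dosages.
#'
#' @param genotypes individuals x markers matrix in [0, 2]; no missing values
#'   (fill first, e.g. \code{\link{fill_missing}}).
#' @param allele_freqs optional per-marker frequencies to centre and scale by.
#' @return object of class \code{ovimp_grm}: list(ids, values,
#'   allele_freqs_used, scaling_denominator).
#' @export
compute_grm <- function(genotypes, allele_freqs = NULL) {
  if (anyNA(genotypes)) {
    stop_ovimp("compute_grm: missing genotypes present; fill them first")
  }
  M <- as.matrix(genotypes)
  p <- allele_freqs %||% (colMeans(M) / 2)
  stopifnot(length(p) == ncol(M))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_ovimp("all markers monomorphic: zero scaling denominator")
  Mc <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Mc) / denom
  G <- (G + t(G)) / 2
  structure(list(ids = rownames(M) %||% as.character(seq_len(nrow(M))),
                 values = G, allele_freqs_used = p,
                 scaling_denominator = denom),
            class = "ovimp_grm")
}

#' @export
as.matrix.ovimp_grm <- function(x, ...) {
  m <- x$values
  dimnames(m) <- list(x$ids, x$ids)
  m
}

#' @export
print.ovimp_grm <- function(x, ...) {
  cat(sprintf("VanRaden GRM: %d individuals, mean diagonal %.3f\n",
              length(x$ids), mean(diag(x$values))))
  invisible(x)
}

#' Compute a test x candidate genomic-relationship block
#'
#' VanRaden relationships between test-set animals and candidate reference
#' animals from genotypes restricted to the shared (low-density) panel.
#' Allele frequencies are estimated from the pooled test + candidate set, so
#' the block equals the corresponding off-diagonal block of the full GRM of
#' the stacked matrix.
#'
#' @param test_genotypes test individuals x markers matrix.
#' @param candidate_genotypes candidate individuals x markers matrix; must
#'   share the same marker columns.
#' @return object of class \code{ovimp_cross_grm}: list(test_ids,
#'   candidate_ids, values, allele_freqs_used, scaling_denominator).
#' @export
compute_cross_grm <- function(test_genotypes, candidate_genotypes) {
  if (!identical(colnames(test_genotypes), colnames(candidate_genotypes))) {
    stop_ovimp("test and candidate genotypes must share identical marker columns")
  }
  if (anyNA(test_genotypes) || anyNA(candidate_genotypes)) {
    stop_ovimp("missing genotypes present; fill them first")
  }
  Tm <- as.matrix(test_genotypes); Cm <- as.matrix(candidate_genotypes)
  pooled <- rbind(Tm, Cm)
  p <- colMeans(pooled) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_ovimp("all markers monomorphic: zero scaling denominator")
  Tc <- sweep(Tm, 2, 2 * p)
  Cc <- sweep(Cm, 2, 2 * p)
  structure(list(
    test_ids = rownames(Tm) %||% as.character(seq_len(nrow(Tm))),
    candidate_ids = rownames(Cm) %||% as.character(seq_len(nrow(Cm))),
    values = tcrossprod(Tc, Cc) / denom,
    allele_freqs_used = p, scaling_denominator = denom),
    class = "ovimp_cross_grm")
}

#' @export
print.ovimp_cross_grm <- function(x, ...) {
  cat(sprintf("cross-GRM block: %d test x %d candidates, mean %.4f\n",
              length(x$test_ids), length(x$candidate_ids),
              mean(x$values)))
  invisible(x)
}
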