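# Imputation-accuracy statistics: per-individual and per-SNP Pearson
# correlations over the masked (withheld) markers, plus summaries.

#' Per-individual imputation accuracy
#'
#' Pearson correlation between the observed medium-density genotypes and the
#' imputed dosages over the masked markers only — the markers typed at low
#' density are always discarded from the evaluation. If the observed masked
#' vector is constant the correlation is undefined and NA is returned
#' (flagged, excluded from summaries downstream).
#'
#' @param observed_row full observed genotype vector for one individual.
#' @param imputed_row imputed dosages (or best-guess genotypes) for the same
#'   individual.
#' @param mask indices or names of the withheld markers (non-empty).
#' @return Pearson r, or NA when undefined.
#' @export
individual_accuracy <- function(observed_row, imputed_row, mask) {
  if (length(mask) == 0) stop_ovimp("empty mask: no withheld markers to evaluate")
  o <- observed_row[mask]; im <- imputed_row[mask]
  if (anyNA(o)) stop_ovimp("observed genotypes must be complete on the mask")
  safe_cor(o, im)
}

#' Per-SNP imputation accuracy
#'
#' Pearson correlation between observed and imputed values at one masked
#' marker across test individuals; undefined (NA) when either column is
#' constant across the evaluation set.
#'
#' @param observed_col observed genotypes across test individuals.
#' @param imputed_col imputed dosages across the same individuals.
#' @return Pearson r, or NA when undefined.
#' @export
snp_accuracy <- function(observed_col, imputed_col) {
  if (length(observed_col) < 2) stop_ovimp("per-SNP accuracy needs >= 2 individuals")
  safe_cor(observed_col, imputed_col)
}

#' Imputation accuracy table
#'
#' Computes per-individual and per-SNP accuracies of an imputation result
#' against the observed medium-density genotypes, over the masked markers
#' only. Dosages are used by default; \code{use = "best_guess"} reproduces
#' the genotype-on-genotype variant.
#'
#' @param observed full observed genotype matrix (test individuals x all
#'   markers).
#' @param result an \code{ovimp_imputation}.
#' @param mask withheld marker names or indices (defaults to markers not in
#'   the low-density panel of the result's map).
#' @param use "dosage" (default) or "best_guess".
#' @return list of class \code{accuracy_table}: \code{per_individual} and
#'   \code{per_snp} data.frames with an \code{defined} flag, and
#'   \code{summary} for each.
#' @export
imputation_accuracy <- function(observed, result, mask = NULL,
                                use = c("dosage", "best_guess")) {
  use <- match.arg(use)
  stopifnot(inherits(result, "ovimp_imputation"))
  imp <- result[[use]]
  if (is.null(mask)) mask <- result$snp_map$snp_id[result$snp_map$panel != "both"]
  stopifnot(nrow(observed) == nrow(imp))
  r_ind <- vapply(seq_len(nrow(imp)), function(i)
    individual_accuracy(observed[i, ], imp[i, ], mask), numeric(1))
  per_individual <- data.frame(
    id = rownames(imp) %||% as.character(seq_len(nrow(imp))),
    r = r_ind, defined = !is.na(r_ind), stringsAsFactors = FALSE)
  r_snp <- vapply(mask, function(j)
    snp_accuracy(observed[, j], imp[, j]), numeric(1))
  per_snp <- data.frame(snp_id = if (is.character(mask)) mask else
    colnames(imp)[mask], r = r_snp, defined = !is.na(r_snp),
    stringsAsFactors = FALSE)
  structure(list(per_individual = per_individual, per_snp = per_snp,
                 summary = list(individual = summarize_accuracy(r_ind),
                                snp = summarize_accuracy(r_snp))),
            class = "accuracy_table")
}

#' Summarise a vector of accuracies
#'
#' Mean, SD, min and max over defined (non-NA) values, the count of
#' undefined values, and fixed-width histogram bins (width 0.02 on [0, 1])
#' for distribution plots; values outside [0, 1] are counted separately.
#'
#' @param r numeric vector of correlations (NA = undefined).
#' @return list with summary statistics and histogram counts.
#' @export
summarize_accuracy <- function(r) {
  defined <- r[!is.na(r)]
  if (length(defined) == 0) stop_ovimp("all accuracies undefined")
  breaks <- seq(0, 1, by = 0.02)
  inside <- defined[defined >= 0 & defined <= 1]
  counts <- if (length(inside)) {
    h <- graphics::hist(inside, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    h$counts
  } else rep(0L, length(breaks) - 1L)
  list(n = length(defined), n_undefined = sum(is.na(r)),
       mean = mean(defined), sd = if (length(defined) > 1) sd(defined) else 0,
       min = min(defined), max = max(defined),
       hist_breaks = breaks, hist_counts = counts,
       n_outside = length(defined) - length(inside))
}

#' @export
print.accuracy_table <- function(x, ...) {
  s <- x$summary$individual
  cat(sprintf("imputation accuracy: %d individuals, mean r = %.3f (sd %.3f, range %.3f-%.3f)\n",
              s$n, s$mean, s$sd, s$min, s$max))
  s2 <- x$summary$snp
  cat(sprintf("                     %d masked SNPs,  mean r = %.3f (%d undefined)\n",
              s2$n, s2$mean, s2$n_undefined))
  invisible(x)
}
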