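# SNP quality-control cascade and duplicate-sample detection.

#' Quality-control thresholds
#'
#' Default thresholds follow common array QC practice for ovine data:
#' genotype calls with confidence (GC) score < 0.6 are set missing; markers
#' are removed for call rate < 90\%, heterozygosity more than 3 SD from the
#' panel mean, minor allele frequency < 0.01, location on an excluded (sex)
#' chromosome, or Hardy-Weinberg deviation at P < 1e-15; whole samples are
#' removed when their genotype correlation with another sample exceeds 0.98.
#'
#' @param min_call_rate minimum per-marker call rate.
#' @param min_gc_score minimum per-genotype GC score.
#' @param het_sd_limit SD limit for the marker heterozygosity filter.
#' @param min_maf markers with MAF strictly below this are removed.
#' @param hwe_p_floor markers with HWE p-value strictly below this are removed.
#' @param duplicate_r_ceiling sample pairs with correlation above this are
#'   treated as duplicates.
#' @param excluded_chromosomes chromosome labels removed outright.
#' @return list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_gc_score = 0.6,
                          het_sd_limit = 3, min_maf = 0.01,
                          hwe_p_floor = 1e-15, duplicate_r_ceiling = 0.98,
                          excluded_chromosomes = c("X", "Y")) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1, het_sd_limit > 0,
            hwe_p_floor > 0, hwe_p_floor < 1,
            duplicate_r_ceiling >= 0, duplicate_r_ceiling <= 1)
  structure(list(min_call_rate = min_call_rate, min_gc_score = min_gc_score,
                 het_sd_limit = het_sd_limit, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor,
                 duplicate_r_ceiling = duplicate_r_ceiling,
                 excluded_chromosomes = excluded_chromosomes),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed genotype
#' counts against the HWE proportions (p^2, 2pq, q^2) at the sample allele
#' frequency. Monomorphic markers return p = 1. A chi-square (rather than
#' exact) test is used: at the extreme removal floor applied here (1e-15)
#' the distinction is immaterial.
#'
#' @param counts integer vector (n_AA, n_Aa, n_aa).
#' @return list with \code{statistic} and \code{p_value}.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop_ovimp("hwe_test: total genotype count is zero")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(list(statistic = 0, p_value = 1))
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expd)^2 / expd)
  list(statistic = as.numeric(stat),
       p_value = as.numeric(pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Detect duplicate samples by genotype correlation
#'
#' Pearson correlation of 0/1/2 codes over markers non-missing in both
#' members of each pair; pairs with r above the ceiling are flagged and the
#' later-indexed member of each pair is marked for removal (deterministic
#' rule). Pairs with fewer than 2 shared non-missing polymorphic markers are
#' skipped with a warning.
#'
#' @param genotypes samples x markers matrix (NA allowed).
#' @param r_ceiling correlation ceiling (default 0.98).
#' @return data.frame (sample_a, sample_b, r, drop) of flagged pairs.
#' @export
detect_duplicates <- function(genotypes, r_ceiling = 0.98) {
  n <- nrow(genotypes)
  if (n < 2) stop_ovimp("detect_duplicates needs >= 2 samples")
  ids <- rownames(genotypes) %||% as.character(seq_len(n))
  out <- list()
  skipped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(genotypes[i, ]) & !is.na(genotypes[j, ])
      xi <- genotypes[i, ok]; xj <- genotypes[j, ok]
      poly <- sd(xi) > 0 && sd(xj) > 0
      if (sum(ok) < 2 || !poly) { skipped <- skipped + 1L; next }
      r <- cor(xi, xj)
      if (r > r_ceiling) {
        out[[length(out) + 1L]] <- data.frame(
          sample_a = ids[i], sample_b = ids[j], r = r, drop = ids[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0) {
    warning(sprintf("%d sample pair(s) skipped: <2 shared non-missing polymorphic markers",
                    skipped))
  }
  if (length(out) == 0) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      r = numeric(), drop = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

marker_stats <- function(G) {
  n_obs <- colSums(!is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- colMeans(G == 1, na.rm = TRUE)
  list(call_rate = n_obs / nrow(G), p = p, maf = maf, het = het)
}

#' Apply the quality-control cascade
#'
#' Filters are applied in a fixed order that is part of the contract:
#' (1) genotype calls with GC score below the minimum are set missing (skipped
#' and logged when no scores are supplied); (2) markers with low call rate;
#' (3) markers whose heterozygote frequency lies more than
#' \code{het_sd_limit} SDs from the mean over markers surviving stage 2;
#' (4) markers with MAF strictly below the minimum; (5) markers on excluded
#' chromosomes; (6) markers failing HWE; (7) duplicate samples. The report
#' reconciles removed and surviving counts.
#'
#' @param genotypes samples x markers matrix (0/1/2, NA allowed).
#' @param snp_map SNP map aligned to the genotype columns.
#' @param gc_scores optional matrix of per-genotype confidence scores aligned
#'   to \code{genotypes}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with \code{genotypes} (filtered), \code{report}
#'   (class \code{qc_report}).
#' @export
apply_qc <- function(genotypes, snp_map, gc_scores = NULL,
                     thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!identical(colnames(genotypes), snp_map$snp_id)) {
    stop_ovimp("snp_map must match genotype columns in order")
  }
  th <- thresholds
  n_in_markers <- ncol(genotypes)
  n_in_samples <- nrow(genotypes)
  removed <- list()
  G <- genotypes
  map <- snp_map

  # 1. per-genotype GC score
  gc_skipped <- is.null(gc_scores)
  if (!gc_skipped) {
    stopifnot(identical(dim(gc_scores), dim(genotypes)))
    G[gc_scores < th$min_gc_score] <- NA
  }

  drop_markers <- function(G, map, keep, reason) {
    removed[[reason]] <<- map$snp_id[!keep]
    if (!any(keep)) {
      stop_ovimp("QC filter '%s' removed all remaining markers", reason)
    }
    list(G = G[, keep, drop = FALSE], map = map[keep, , drop = FALSE])
  }

  # 2. call rate
  st <- marker_stats(G)
  res <- drop_markers(G, map, st$call_rate >= th$min_call_rate, "call_rate")
  G <- res$G; map <- res$map

  # 3. heterozygosity outliers (marker-level, stats over current survivors)
  st <- marker_stats(G)
  mu <- mean(st$het); sdv <- sd(st$het)
  keep <- if (is.na(sdv) || sdv == 0) rep(TRUE, ncol(G)) else
    abs(st$het - mu) <= th$het_sd_limit * sdv
  res <- drop_markers(G, map, keep, "heterozygosity")
  G <- res$G; map <- res$map

  # 4. MAF (strictly below threshold removed; equality retained)
  st <- marker_stats(G)
  res <- drop_markers(G, map, st$maf >= th$min_maf, "maf")
  G <- res$G; map <- res$map

  # 5. excluded chromosomes
  res <- drop_markers(G, map,
                      !(as.character(map$chrom) %in%
                          as.character(th$excluded_chromosomes)),
                      "chromosome")
  G <- res$G; map <- res$map

  # 6. HWE
  pvals <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2)))$p_value
  }, numeric(1))
  res <- drop_markers(G, map, pvals >= th$hwe_p_floor, "hwe")
  G <- res$G; map <- res$map

  # 7. duplicate samples
  dup <- if (nrow(G) >= 2) detect_duplicates(G, th$duplicate_r_ceiling) else
    data.frame(drop = character())
  dropped_samples <- unique(dup$drop)
  if (length(dropped_samples) > 0) {
    G <- G[!(rownames(G) %in% dropped_samples), , drop = FALSE]
  }

  report <- structure(list(
    input_markers = n_in_markers, input_samples = n_in_samples,
    removed_markers = lapply(removed, as.character),
    removed_marker_counts = vapply(removed, length, integer(1)),
    removed_samples = dropped_samples,
    duplicate_pairs = dup,
    gc_filter_skipped = gc_skipped,
    surviving_markers = ncol(G), surviving_samples = nrow(G)
  ), class = "qc_report")
  stopifnot(sum(report$removed_marker_counts) + report$surviving_markers ==
              n_in_markers)
  list(genotypes = G, snp_map = map, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d -> %d markers, %d -> %d samples\n",
              x$input_markers, x$surviving_markers,
              x$input_samples, x$surviving_samples))
  if (x$gc_filter_skipped) cat("  GC-score filter skipped (no scores supplied)\n")
  for (f in names(x$removed_marker_counts)) {
    cat(sprintf("  %-15s removed %d marker(s)\n", f,
                x$removed_marker_counts[[f]]))
  }
  if (length(x$removed_samples)) {
    cat("  duplicate samples removed:",
        paste(x$removed_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a \code{qc_report}.
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
qc_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  x <- unclass(report)
  x$duplicate_pairs <- as.list(x$duplicate_pairs)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
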