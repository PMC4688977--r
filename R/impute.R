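# Population-based genotype imputation: Li-Stephens copying HMM with
# iterative Viterbi phasing of the reference panel.

#' Li-Stephens imputation parameters
#'
#' The copying HMM switches between reference haplotypes with probability
#' rho_j = 1 - exp(-4 * ne_eff * d_j / H) between adjacent markers at genetic
#' distance d_j Morgans, where H is the number of conditioning haplotypes;
#' copied alleles are miscopied with probability \code{error_rate}. Phasing
#' of the reference panel runs \code{n_iterations} rounds of per-individual
#' Viterbi re-phasing. For large panels the conditioning state space is
#' capped at the most similar haplotypes (\code{max_states} for imputation,
#' \code{phase_states} for phasing), standard practice in large-panel
#' imputation software.
#'
#' @param n_iterations phasing iterations (default 10).
#' @param error_rate per-allele miscopy probability, in (0, 0.5).
#' @param ne_eff effective-size scale of the switch probability.
#' @param per_chromosome impute each chromosome separately (default TRUE;
#'   turning it off runs one chain with a forced recombination break between
#'   chromosomes, which gives identical results).
#' @param max_states cap on conditioning haplotypes per target during
#'   imputation.
#' @param phase_states cap on conditioning haplotypes during phasing.
#' @return list of class \code{ls_params}.
#' @export
ls_params <- function(n_iterations = 10, error_rate = 0.003, ne_eff = 20,
                      per_chromosome = TRUE, max_states = 100,
                      phase_states = 40) {
  stopifnot(n_iterations >= 1, error_rate > 0, error_rate < 0.5, ne_eff > 0,
            max_states >= 2, phase_states >= 2)
  structure(list(n_iterations = n_iterations, error_rate = error_rate,
                 ne_eff = ne_eff, per_chromosome = per_chromosome,
                 max_states = max_states, phase_states = phase_states),
            class = "ls_params")
}

#' Construct a haplotype panel
#'
#' @param haplotypes matrix with two rows per individual (alleles 0/1),
#'   rownames \code{<id>_1} / \code{<id>_2}.
#' @param ids individual ids, in panel order.
#' @return object of class \code{hap_panel}.
#' @export
hap_panel <- function(haplotypes, ids) {
  stopifnot(nrow(haplotypes) == 2 * length(ids),
            all(haplotypes %in% c(0L, 1L)))
  structure(list(haplotypes = haplotypes, ids = ids), class = "hap_panel")
}

#' Extract the true simulated haplotypes of a set of animals as a panel
#'
#' @param pop an \code{ovimp_population}.
#' @param ids animals to include.
#' @return a \code{hap_panel}.
#' @export
true_hap_panel <- function(pop, ids) {
  rows <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
  hap_panel(pop$haplotypes[rows, , drop = FALSE], ids)
}

# Switch probabilities for one chromosome chain.
switch_probs <- function(pos_cm, ne_eff, n_hap) {
  if (length(pos_cm) < 2) return(numeric(0))
  d <- diff(pos_cm) / 100
  d[d <= 0] <- 1e-8
  1 - exp(-4 * ne_eff * d / n_hap)
}

# Chromosome blocks of a map: list of column index vectors. With
# per_chromosome = FALSE, a single block with rho forced to 1 at chromosome
# boundaries (an unconditional switch, equivalent to independent chains).
chrom_blocks <- function(snp_map, per_chromosome) {
  if (per_chromosome) {
    lapply(unique(snp_map$chrom), function(ch) which(snp_map$chrom == ch))
  } else {
    list(seq_len(nrow(snp_map)))
  }
}

block_rho <- function(snp_map, idx, ne_eff, n_hap) {
  sub <- snp_map[idx, ]
  if (length(idx) < 2) return(numeric(0))
  rho <- switch_probs(sub$pos_cm, ne_eff, n_hap)
  boundary <- diff(as.integer(factor(sub$chrom, levels = unique(sub$chrom)))) != 0
  rho[boundary] <- 1
  rho
}

# Distance of every haplotype in matrix A (haps x markers) to each genotype
# row of G (individuals x markers, NA allowed): sum over observed markers of
# |2a - g|. Lower = more similar.
hap_geno_distance <- function(A, G) {
  O <- !is.na(G)
  X <- (1 - G); X[!O] <- 0
  base <- rowSums(G * O, na.rm = TRUE)         # per-individual constant
  D <- 2 * A %*% t(X)                           # haps x individuals
  sweep(D, 2, base, "+")
}

#' Haploid forward-backward over a reference panel
#'
#' Scaled forward-backward on the haplotype-copying HMM: per-marker
#' posteriors over reference haplotypes and posterior probabilities of
#' allele 1 (accounting for the miscopy rate). Missing observations emit
#' uniformly.
#'
#' @param observed_alleles vector of 0/1 with NA for missing, ordered by map
#'   position.
#' @param reference a \code{hap_panel} or haplotype matrix (haps x markers).
#' @param snp_map map for the markers (used to derive switch probabilities);
#'   ignored when \code{rho} is given.
#' @param params an \code{\link{ls_params}}.
#' @param rho optional explicit switch-probability vector (length M - 1).
#' @return list(state_post H x M, allele_post length M, loglik).
#' @export
forward_backward <- function(observed_alleles, reference,
                             snp_map = NULL, params = ls_params(),
                             rho = NULL) {
  A <- if (inherits(reference, "hap_panel")) reference$haplotypes else reference
  A <- matrix(as.integer(A), nrow = nrow(A), dimnames = dimnames(A))
  M <- ncol(A)
  stopifnot(length(observed_alleles) == M, nrow(A) >= 1)
  if (is.null(rho)) {
    if (is.null(snp_map)) stop_ovimp("either snp_map or rho must be supplied")
    rho <- block_rho(snp_map, seq_len(M), params$ne_eff, nrow(A))
  }
  stopifnot(length(rho) == max(M - 1, 0))
  obs <- ifelse(is.na(observed_alleles), -1L, as.integer(observed_alleles))
  .ls_fb_haploid(A, obs, as.numeric(rho), params$error_rate)
}

#' Phase a genotype panel by iterative Viterbi re-phasing
#'
#' Heterozygote phases are initialised at random; for \code{n_iterations}
#' rounds each individual is re-phased by diploid Viterbi decoding against
#' the current haplotypes of the other individuals (capped at the
#' \code{phase_states} most similar). The haplotype pair always sums to the
#' observed genotype; missing genotypes are filled from the decoded states.
#'
#' @param genotypes individuals x markers matrix of 0/1/2 (sporadic NA
#'   allowed).
#' @param snp_map marker map aligned to the columns.
#' @param params an \code{\link{ls_params}}.
#' @param seed integer seed (phase initialisation).
#' @return a \code{hap_panel}.
#' @export
phase_panel <- function(genotypes, snp_map, params = ls_params(), seed = 1) {
  G <- as.matrix(genotypes)
  n <- nrow(G); m <- ncol(G)
  stopifnot(m == nrow(snp_map))
  ids <- rownames(G) %||% as.character(seq_len(n))
  if (n < 2) {
    warning("phasing a single individual: phase is arbitrary (no panel to condition on)")
  }
  eps <- params$error_rate

  with_substream(seed, "phase", {
    p <- colMeans(G, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0.5
    H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      g <- G[i, ]
      h1 <- integer(m); h2 <- integer(m)
      hom2 <- !is.na(g) & g == 2L
      h1[hom2] <- 1L; h2[hom2] <- 1L
      het <- !is.na(g) & g == 1L
      flip <- runif(sum(het)) < 0.5
      h1[het] <- as.integer(flip); h2[het] <- 1L - as.integer(flip)
      mis <- is.na(g)
      if (any(mis)) {
        h1[mis] <- rbinom(sum(mis), 1L, p[mis])
        h2[mis] <- rbinom(sum(mis), 1L, p[mis])
      }
      H1[i, ] <- h1; H2[i, ] <- h2
    }
    if (n == 1) {
      A <- rbind(H1, H2)[c(1, 2), , drop = FALSE]
      rownames(A) <- paste0(ids[1], c("_1", "_2"))
      colnames(A) <- snp_map$snp_id
      return(hap_panel(A, ids))
    }

    blocks <- chrom_blocks(snp_map, params$per_chromosome)
    K <- min(params$phase_states, 2L * (n - 1L))
    for (it in seq_len(params$n_iterations)) {
      A <- matrix(0L, 2L * n, m)
      A[seq(1, 2 * n, 2), ] <- H1
      A[seq(2, 2 * n, 2), ] <- H2
      Dist <- hap_geno_distance(A, G)
      for (i in seq_len(n)) {
        own <- c(2L * i - 1L, 2L * i)
        ord <- order(Dist[, i], seq_len(2L * n))
        cond <- setdiff(ord, own)[seq_len(K)]
        gi <- ifelse(is.na(G[i, ]), -1L, as.integer(G[i, ]))
        for (idx in blocks) {
          refb <- A[cond, idx, drop = FALSE]
          rho <- block_rho(snp_map, idx, params$ne_eff, length(cond))
          vt <- .ls_viterbi_diploid(refb, gi[idx], as.numeric(rho), eps)
          a1 <- refb[cbind(vt$path1, seq_along(idx))]
          a2 <- refb[cbind(vt$path2, seq_along(idx))]
          g <- G[i, idx]
          h1 <- a1; h2 <- a2
          hom <- !is.na(g) & g != 1L
          h1[hom] <- as.integer(g[hom] / 2L); h2[hom] <- h1[hom]
          het <- !is.na(g) & g == 1L
          # uninformative state pair (both copy the same allele): keep the
          # current phase rather than forcing an arbitrary one
          same <- het & (a1 == a2)
          h1[same] <- H1[i, idx][same]
          h2[same] <- 1L - h1[same]
          diff_ <- het & (a1 != a2)
          h1[diff_] <- a1[diff_]; h2[diff_] <- a2[diff_]
          H1[i, idx] <- h1; H2[i, idx] <- h2
        }
      }
    }
    A <- matrix(0L, 2L * n, m)
    A[seq(1, 2 * n, 2), ] <- H1
    A[seq(2, 2 * n, 2), ] <- H2
    rownames(A) <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
    colnames(A) <- snp_map$snp_id
    hap_panel(A, ids)
  })
}

#' Impute one low-density-typed individual against a phased reference
#'
#' The target's typed markers anchor a diploid Li-Stephens chain over ordered
#' pairs of reference haplotypes; the exact pair-HMM forward-backward yields
#' posterior genotype dosages at every untyped marker. Observed genotypes
#' pass through unchanged. For large panels the chain conditions on the
#' \code{max_states} haplotypes most similar to the target at typed markers.
#'
#' @param target_low named genotype vector on the low-density markers
#'   (sporadic NA allowed).
#' @param reference a \code{hap_panel} on the full marker set.
#' @param snp_map full marker map.
#' @param params an \code{\link{ls_params}}.
#' @return list(dosage, best_guess, observed_mask, maxpost), each over the
#'   full marker set.
#' @export
impute_individual <- function(target_low, reference, snp_map,
                              params = ls_params()) {
  stopifnot(inherits(reference, "hap_panel"))
  A <- reference$haplotypes
  m <- nrow(snp_map)
  if (ncol(A) != m) {
    stop_ovimp("reference panel does not cover the full marker map")
  }
  low_ids <- names(target_low)
  if (is.null(low_ids) || !all(low_ids %in% snp_map$snp_id)) {
    stop_ovimp("target markers must be named and present in the map")
  }
  obs_full <- rep(NA_integer_, m)
  names(obs_full) <- snp_map$snp_id
  obs_full[low_ids] <- as.integer(target_low)

  K <- min(params$max_states, nrow(A))
  Dist <- hap_geno_distance(A, matrix(obs_full, nrow = 1))
  cond <- order(Dist[, 1], seq_len(nrow(A)))[seq_len(K)]

  dosage <- numeric(m); maxpost <- numeric(m)
  gi <- ifelse(is.na(obs_full), -1L, obs_full)
  for (idx in chrom_blocks(snp_map, params$per_chromosome)) {
    refb <- A[cond, idx, drop = FALSE]
    storage.mode(refb) <- "integer"
    rho <- block_rho(snp_map, idx, params$ne_eff, length(cond))
    fb <- .ls_fb_diploid(refb, gi[idx], as.numeric(rho), params$error_rate)
    dosage[idx] <- fb$dosage
    maxpost[idx] <- fb$maxpost
  }
  observed <- !is.na(obs_full)
  dosage[observed] <- obs_full[observed]
  best_guess <- as.integer(round(dosage))
  best_guess[observed] <- obs_full[observed]
  names(dosage) <- names(maxpost) <- snp_map$snp_id
  names(best_guess) <- snp_map$snp_id
  list(dosage = dosage, best_guess = best_guess,
       observed_mask = observed, maxpost = maxpost)
}

#' Impute a low-density test set from a medium-density reference set
#'
#' Phases the reference genotypes (\code{n_iterations} rounds), then imputes
#' every test individual chromosome by chromosome. Deterministic under the
#' seed. The reference may also be supplied pre-phased as a
#' \code{hap_panel}, in which case phasing is skipped.
#'
#' @param test_genotypes test individuals x low-density markers (NA allowed).
#' @param reference reference individuals x full markers genotype matrix, or
#'   a \code{hap_panel}.
#' @param snp_map full marker map.
#' @param params an \code{\link{ls_params}}.
#' @param seed integer seed (used by reference phasing).
#' @return object of class \code{ovimp_imputation}: list(dosage, best_guess,
#'   observed_mask, maxpost) matrices (test individuals x full markers), plus
#'   the map.
#' @export
impute_set <- function(test_genotypes, reference, snp_map,
                       params = ls_params(), seed = 1) {
  panel <- if (inherits(reference, "hap_panel")) reference else
    phase_panel(reference, snp_map, params, seed)
  m <- nrow(snp_map)
  n <- nrow(test_genotypes)
  dn <- list(rownames(test_genotypes), snp_map$snp_id)
  out <- list(dosage = matrix(NA_real_, n, m, dimnames = dn),
              best_guess = matrix(NA_integer_, n, m, dimnames = dn),
              observed_mask = matrix(FALSE, n, m, dimnames = dn),
              maxpost = matrix(NA_real_, n, m, dimnames = dn),
              snp_map = snp_map)
  if (n == 0) return(structure(out, class = "ovimp_imputation"))
  for (i in seq_len(n)) {
    res <- impute_individual(test_genotypes[i, ], panel, snp_map, params)
    out$dosage[i, ] <- res$dosage
    out$best_guess[i, ] <- res$best_guess
    out$observed_mask[i, ] <- res$observed_mask
    out$maxpost[i, ] <- res$maxpost
  }
  structure(out, class = "ovimp_imputation")
}

#' @export
print.ovimp_imputation <- function(x, ...) {
  cat(sprintf("imputation result: %d individuals x %d markers (%d observed per individual on average)\n",
              nrow(x$dosage), ncol(x$dosage),
              round(mean(rowSums(x$observed_mask)))))
  invisible(x)
}

#' Switch-error rate between inferred and true phase
#'
#' Fraction of adjacent heterozygote pairs whose parental assignment flips
#' between the inferred and true haplotypes, averaged over individuals
#' (per chromosome, then pooled).
#'
#' @param inferred a \code{hap_panel}.
#' @param truth a \code{hap_panel} with the same individuals and markers.
#' @param snp_map marker map.
#' @return mean switch-error rate across individuals with >= 2 informative
#'   heterozygous sites.
#' @export
switch_error_rate <- function(inferred, truth, snp_map) {
  stopifnot(identical(inferred$ids, truth$ids))
  rates <- c()
  for (i in seq_along(inferred$ids)) {
    ih1 <- inferred$haplotypes[2 * i - 1, ]
    th1 <- truth$haplotypes[2 * i - 1, ]
    th2 <- truth$haplotypes[2 * i, ]
    err <- 0L; tot <- 0L
    for (ch in unique(snp_map$chrom)) {
      idx <- which(snp_map$chrom == ch)
      het <- idx[th1[idx] != th2[idx]]
      if (length(het) < 2) next
      assign1 <- ih1[het] == th1[het]   # TRUE: inferred hap1 copies true hap1
      flips <- sum(assign1[-1] != assign1[-length(assign1)])
      err <- err + flips; tot <- tot + length(het) - 1L
    }
    if (tot > 0) rates <- c(rates, err / tot)
  }
  mean(rates)
}
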