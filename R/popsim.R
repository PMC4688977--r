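# Multi-breed population simulator: breed divergence, recombination,
# half-sib family structure, F1 crosses, nested SNP panels.

#' Define a breed-divergence model
#'
#' Breeds diverge from a common ancestral population under the
#' Balding-Nichols model: at each marker the per-breed allele frequency is
#' drawn from a Beta distribution around the ancestral frequency with spread
#' controlled by the fixation index Fst.
#'
#' @param breed_names character vector of breed labels (>= 1; >= 2 for any
#'   crossbreeding design).
#' @param fst differentiation parameter in [0, 1).
#' @param ancestral_freq_range length-2 numeric (low, high), 0 < low < high < 1,
#'   range of ancestral allele frequencies.
#' @return An object of class \code{breed_model}.
#' @export
breed_model <- function(breed_names = c("Merino", "BorderLeicester",
                                        "PollDorset", "WhiteSuffolk"),
                        fst = 0.15,
                        ancestral_freq_range = c(0.05, 0.95)) {
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0 || fst >= 1) {
    stop_ovimp("fst must be a single value in [0, 1), got %s", format(fst))
  }
  lo <- ancestral_freq_range[1]; hi <- ancestral_freq_range[2]
  if (!(lo > 0 && hi > lo && hi < 1)) {
    stop_ovimp("ancestral_freq_range must satisfy 0 < low < high < 1")
  }
  if (length(breed_names) < 1L || anyDuplicated(breed_names)) {
    stop_ovimp("breed_names must be a non-empty set of unique labels")
  }
  structure(list(breed_names = as.character(breed_names), fst = fst,
                 ancestral_freq_range = c(lo, hi)),
            class = "breed_model")
}

#' Build a SNP map with a nested low-density subpanel
#'
#' Markers are laid out on equally sized chromosomes with positions uniform
#' on the genetic map (1 cM per Mb by construction). A regularly spaced
#' subset is flagged as the nested low-density panel (membership
#' \code{"both"}); the remainder is \code{"50k_only"}. This mirrors a
#' medium-density array with an evenly spaced low-density subset.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers on each chromosome.
#' @param chr_length_cm genetic length of each chromosome in centimorgans.
#' @param low_density_every every \code{low_density_every}-th marker belongs
#'   to the low-density subpanel (must leave a strict subset).
#' @return data.frame with columns snp_id, chrom, pos_bp, pos_cm, panel.
#' @export
make_snp_map <- function(n_chr = 2, markers_per_chr = 250, chr_length_cm = 100,
                         low_density_every = 4) {
  stopifnot(n_chr >= 1, markers_per_chr >= 2, chr_length_cm >= 0)
  maps <- lapply(seq_len(n_chr), function(ch) {
    cm <- seq(0, chr_length_cm, length.out = markers_per_chr)
    data.frame(
      snp_id = sprintf("snp_c%d_%04d", ch, seq_len(markers_per_chr)),
      chrom = ch,
      pos_bp = as.integer(round(cm * 1e6)) + seq_len(markers_per_chr),
      pos_cm = cm,
      panel = ifelse(seq_len(markers_per_chr) %% low_density_every == 1L,
                     "both", "50k_only"),
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  validate_snp_map(map)
  map
}

validate_snp_map <- function(snp_map) {
  stopifnot(all(c("snp_id", "chrom", "pos_bp", "pos_cm", "panel") %in%
                  names(snp_map)))
  for (ch in unique(snp_map$chrom)) {
    sub <- snp_map[snp_map$chrom == ch, ]
    if (any(diff(sub$pos_bp) <= 0)) {
      stop_ovimp("pos_bp must be strictly increasing within chromosome %s", ch)
    }
    if (any(diff(sub$pos_cm) < 0)) {
      stop_ovimp("pos_cm must be non-decreasing within chromosome %s", ch)
    }
  }
  n_both <- sum(snp_map$panel == "both")
  if (n_both >= nrow(snp_map)) {
    stop_ovimp("low-density panel must be a strict subset of all markers")
  }
  invisible(snp_map)
}

#' Simulate per-breed founder allele frequencies
#'
#' Balding-Nichols model: ancestral frequency p is uniform on the configured
#' range; each breed's frequency is Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst),
#' which has mean p and variance Fst * p(1-p). Fst = 0 returns the ancestral
#' frequency for every breed exactly.
#'
#' @param n_snps number of markers (>= 1).
#' @param breed_mod a \code{\link{breed_model}}.
#' @param seed integer seed.
#' @return numeric matrix n_snps x n_breeds of allele frequencies, with the
#'   ancestral frequencies attached as attribute \code{"ancestral"}.
#' @export
simulate_founder_frequencies <- function(n_snps, breed_mod, seed = 1) {
  stopifnot(inherits(breed_mod, "breed_model"), n_snps >= 1)
  with_substream(seed, "founder_freqs", {
    rng <- breed_mod$ancestral_freq_range
    p <- runif(n_snps, rng[1], rng[2])
    fst <- breed_mod$fst
    nb <- length(breed_mod$breed_names)
    if (fst == 0) {
      freqs <- matrix(rep(p, nb), ncol = nb)
    } else {
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      freqs <- vapply(seq_len(nb), function(i) rbeta(n_snps, a, b),
                      numeric(n_snps))
      # guard against exactly-fixed draws so founders stay polymorphic-able
      freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
    }
    colnames(freqs) <- breed_mod$breed_names
    attr(freqs, "ancestral") <- p
    freqs
  })
}

#' Specify a mating design
#'
#' Captures the structure of the resource population: purebred founders per
#' breed, sires nested in flocks with a configurable fraction of shared AI
#' sires connecting flocks, half-sib families of configurable size, and F1
#' cross families (non-Merino sire x Merino dam).
#'
#' @param n_founders named integer vector: purebred founders per breed.
#' @param n_flocks flocks for the purebred Merino population.
#' @param sires_per_flock sires used per flock per breed-progeny block.
#' @param progeny_per_sire progeny per sire (half-sib family size).
#' @param ai_sire_fraction fraction of sire slots in each flock filled from a
#'   shared artificial-insemination pool (connects flocks; default 0.5).
#' @param purebred_progeny named integer vector: purebred progeny per breed.
#' @param f1_progeny named integer vector: F1 progeny per non-Merino sire
#'   breed (each crossed to Merino dams).
#' @param merino_label which breed plays the maternal purebred role in
#'   crosses.
#' @return list of class \code{mating_design}.
#' @export
mating_design <- function(n_founders = c(Merino = 80, BorderLeicester = 24,
                                         PollDorset = 24, WhiteSuffolk = 24),
                          n_flocks = 3,
                          sires_per_flock = 9,
                          progeny_per_sire = 10,
                          ai_sire_fraction = 0.5,
                          purebred_progeny = c(Merino = 420, BorderLeicester = 30,
                                               PollDorset = 30, WhiteSuffolk = 30),
                          f1_progeny = c(BorderLeicester = 140, PollDorset = 140,
                                         WhiteSuffolk = 140),
                          merino_label = "Merino") {
  stopifnot(ai_sire_fraction >= 0, ai_sire_fraction <= 1,
            all(n_founders >= 2), n_flocks >= 1, sires_per_flock >= 1,
            progeny_per_sire >= 1)
  structure(list(n_founders = n_founders, n_flocks = n_flocks,
                 sires_per_flock = sires_per_flock,
                 progeny_per_sire = progeny_per_sire,
                 ai_sire_fraction = ai_sire_fraction,
                 purebred_progeny = purebred_progeny,
                 f1_progeny = f1_progeny,
                 merino_label = merino_label),
            class = "mating_design")
}

# Draw one gamete from a pair of parental haplotypes by recombination on the
# genetic map: crossover count ~ Poisson(map length in Morgans), crossover
# positions uniform on the map (Haldane, no interference).
make_gamete <- function(h1, h2, snp_map) {
  gam <- integer(length(h1))
  for (ch in unique(snp_map$chrom)) {
    idx <- which(snp_map$chrom == ch)
    cm <- snp_map$pos_cm[idx]
    len_m <- (max(cm) - min(cm)) / 100
    n_co <- if (len_m > 0) rpois(1L, len_m) else 0L
    start <- sample.int(2L, 1L)
    if (n_co == 0L) {
      gam[idx] <- if (start == 1L) h1[idx] else h2[idx]
    } else {
      xo <- sort(runif(n_co, min(cm), max(cm)))
      seg <- findInterval(cm, xo)            # 0..n_co
      use1 <- ((seg + start) %% 2L) == 1L
      gam[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  gam
}

#' Simulate a multi-breed population with recorded haplotypes
#'
#' Founders are drawn breed-by-breed from Balding-Nichols allele frequencies
#' (two independent haplotypes each, i.e. founders are in HWE within breed).
#' Purebred progeny are produced in flocks from sires nested in flocks, a
#' configurable fraction of which are shared AI sires used across all flocks;
#' each sire leaves a half-sib family. F1 crosses mate non-Merino sires to
#' Merino dams. Gametes recombine on the cM map with Poisson crossover counts
#' (Haldane, no interference). True haplotypes are retained for every animal.
#'
#' @param breed_mod a \code{\link{breed_model}}.
#' @param snp_map marker map from \code{\link{make_snp_map}}.
#' @param design a \code{\link{mating_design}}.
#' @param seed integer seed.
#' @return list of class \code{ovimp_population} with elements
#'   \code{genotypes} (individuals x markers, 0/1/2), \code{haplotypes}
#'   (2 rows per individual, \code{<id>_1} / \code{<id>_2}),
#'   \code{pedigree} (id, sire, dam, sex, breed proportions \code{prop_*},
#'   flock, birth_year, group), \code{snp_map}, \code{founder_freqs}.
#' @export
simulate_population <- function(breed_mod, snp_map, design = mating_design(),
                                seed = 1) {
  stopifnot(inherits(breed_mod, "breed_model"),
            inherits(design, "mating_design"))
  validate_snp_map(snp_map)
  breeds <- breed_mod$breed_names
  if (!all(names(design$n_founders) %in% breeds)) {
    stop_ovimp("founder breeds must be among breed_model breeds")
  }
  m <- nrow(snp_map)
  freqs <- simulate_founder_frequencies(m, breed_mod, seed)

  with_substream(seed, "population", {
    haps <- list()   # per individual: list(h1, h2)
    ped <- list(id = character(0), sire = character(0), dam = character(0),
                sex = character(0), flock = integer(0),
                birth_year = integer(0), group = character(0),
                props = list())
    add_animal <- function(id, sire, dam, sex, props, flock, birth_year, group,
                           h1, h2) {
      haps[[id]] <<- list(h1 = h1, h2 = h2)
      pr <- setNames(numeric(length(breeds)), breeds)
      pr[names(props)] <- props
      n <- length(ped$id) + 1L
      ped$id[n] <<- id
      ped$sire[n] <<- sire %||% NA_character_
      ped$dam[n] <<- dam %||% NA_character_
      ped$sex[n] <<- sex
      ped$flock[n] <<- flock
      ped$birth_year[n] <<- birth_year
      ped$group[n] <<- group
      ped$props[[n]] <<- pr
      invisible(NULL)
    }

    # --- founders ---
    founders <- list()
    for (b in names(design$n_founders)) {
      nf <- design$n_founders[[b]]
      pb <- freqs[, b]
      ids <- sprintf("%s_F%03d", abbreviate(b, 2), seq_len(nf))
      sex <- rep(c("M", "F"), length.out = nf)
      for (i in seq_len(nf)) {
        h1 <- rbinom(m, 1L, pb); h2 <- rbinom(m, 1L, pb)
        add_animal(ids[i], NULL, NULL, sex[i], setNames(1, b),
                   flock = 0L, birth_year = 2000L, group = "founder",
                   h1 = h1, h2 = h2)
      }
      founders[[b]] <- data.frame(id = ids, sex = sex,
                                  stringsAsFactors = FALSE)
    }

    pick_parents <- function(b, n_sires_needed, n_dams_needed) {
      f <- founders[[b]]
      sires <- f$id[f$sex == "M"]
      dams <- f$id[f$sex == "F"]
      if (length(sires) < n_sires_needed || length(dams) < n_dams_needed) {
        stop_ovimp(
          "design requires %d sires and %d dams of breed %s but only %d/%d founders available",
          n_sires_needed, n_dams_needed, b, length(sires), length(dams))
      }
      list(sires = sires, dams = dams)
    }

    # --- purebred progeny, flocked, shared AI sires ---
    counter <- 0L
    for (b in names(design$purebred_progeny)) {
      n_prog <- design$purebred_progeny[[b]]
      if (n_prog == 0) next
      n_flocks <- if (b == design$merino_label) design$n_flocks else 1L
      n_slots <- ceiling(n_prog / design$progeny_per_sire)
      slots_per_flock <- ceiling(n_slots / n_flocks)
      n_ai <- max(0L, round(design$ai_sire_fraction * slots_per_flock))
      par <- pick_parents(b, n_sires_needed = min(slots_per_flock, n_slots),
                          n_dams_needed = 1L)
      ai_pool <- head(par$sires, max(n_ai, 1L))
      local_pool <- setdiff(par$sires, ai_pool)
      if (length(local_pool) == 0L) local_pool <- par$sires
      made <- 0L
      for (fl in seq_len(n_flocks)) {
        sires_fl <- c(head(ai_pool, n_ai),
                      sample(local_pool, min(slots_per_flock - n_ai,
                                             length(local_pool))))
        if (length(sires_fl) == 0L) sires_fl <- ai_pool[1]
        for (s in sires_fl) {
          if (made >= n_prog) break
          fam <- min(design$progeny_per_sire, n_prog - made)
          dams_s <- sample(par$dams, fam, replace = fam > length(par$dams))
          for (d in dams_s) {
            made <- made + 1L; counter <- counter + 1L
            id <- sprintf("%s_P%04d", abbreviate(b, 2), made)
            g1 <- make_gamete(haps[[s]]$h1, haps[[s]]$h2, snp_map)
            g2 <- make_gamete(haps[[d]]$h1, haps[[d]]$h2, snp_map)
            add_animal(id, s, d, sample(c("M", "F"), 1L), setNames(1, b),
                       flock = fl, birth_year = 2001L,
                       group = sprintf("pure_%s", b), h1 = g1, h2 = g2)
          }
        }
      }
    }

    # --- F1 crosses: non-Merino sire x Merino dam ---
    mer <- design$merino_label
    for (b in names(design$f1_progeny)) {
      n_prog <- design$f1_progeny[[b]]
      if (n_prog == 0) next
      if (b == mer) stop_ovimp("F1 sire breed must differ from %s", mer)
      sires <- founders[[b]]$id[founders[[b]]$sex == "M"]
      dams <- founders[[mer]]$id[founders[[mer]]$sex == "F"]
      if (length(sires) == 0L || length(dams) == 0L) {
        stop_ovimp("design requires %s sires and %s dams for F1 crosses", b, mer)
      }
      n_slots <- ceiling(n_prog / design$progeny_per_sire)
      sires_use <- sample(sires, min(n_slots, length(sires)))
      made <- 0L
      while (made < n_prog) {
        for (s in sires_use) {
          if (made >= n_prog) break
          fam <- min(design$progeny_per_sire, n_prog - made)
          dams_s <- sample(dams, fam, replace = fam > length(dams))
          for (d in dams_s) {
            made <- made + 1L
            id <- sprintf("%sx%s_%04d", abbreviate(b, 2), abbreviate(mer, 2),
                          made)
            g1 <- make_gamete(haps[[s]]$h1, haps[[s]]$h2, snp_map)
            g2 <- make_gamete(haps[[d]]$h1, haps[[d]]$h2, snp_map)
            add_animal(id, s, d, sample(c("M", "F"), 1L),
                       setNames(c(0.5, 0.5), c(b, mer)),
                       flock = 1L + (made %% design$n_flocks),
                       birth_year = 2001L, group = sprintf("f1_%s", b),
                       h1 = g1, h2 = g2)
          }
        }
      }
    }

    ids <- names(haps)
    H <- matrix(0L, nrow = 2L * length(ids), ncol = m)
    rownames(H) <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
    colnames(H) <- snp_map$snp_id
    for (i in seq_along(ids)) {
      H[2L * i - 1L, ] <- haps[[ids[i]]]$h1
      H[2L * i, ] <- haps[[ids[i]]]$h2
    }
    G <- H[seq(1, nrow(H), 2), , drop = FALSE] +
      H[seq(2, nrow(H), 2), , drop = FALSE]
    rownames(G) <- ids
    pedigree <- data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                           sex = ped$sex, flock = ped$flock,
                           birth_year = ped$birth_year, group = ped$group,
                           stringsAsFactors = FALSE)
    prmat <- do.call(rbind, ped$props)
    colnames(prmat) <- paste0("prop_", breeds)
    pedigree <- cbind(pedigree, as.data.frame(prmat))
    rownames(pedigree) <- NULL

    structure(list(genotypes = G, haplotypes = H, pedigree = pedigree,
                   snp_map = snp_map, founder_freqs = freqs),
              class = "ovimp_population")
  })
}

#' @export
print.ovimp_population <- function(x, ...) {
  cat(sprintf("ovimp population: %d animals x %d markers (%d low-density)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$snp_map$panel == "both")))
  tab <- table(x$pedigree$group)
  for (g in names(tab)) cat(sprintf("  %-18s %d\n", g, tab[[g]]))
  invisible(x)
}

#' Breed composition matrix from a pedigree
#'
#' @param pedigree pedigree data.frame from \code{\link{simulate_population}}.
#' @return numeric matrix animals x breeds with rows summing to 1.
#' @export
breed_composition <- function(pedigree) {
  pcols <- grep("^prop_", names(pedigree), value = TRUE)
  Q <- as.matrix(pedigree[, pcols, drop = FALSE])
  rownames(Q) <- pedigree$id
  colnames(Q) <- sub("^prop_", "", pcols)
  if (any(abs(rowSums(Q) - 1) > 1e-9)) {
    stop_ovimp("breed proportions must sum to 1 per animal")
  }
  Q
}

#' Mask genotypes down to the low-density subpanel
#'
#' Extracts the columns whose panel membership is \code{"both"} (the nested
#' low-density panel) and records the withheld column index, emulating
#' low-density genotyping of test animals by masking the remaining markers of
#' the medium-density array. Genotype values are never altered.
#'
#' @param genotypes individuals x markers matrix.
#' @param snp_map SNP map covering all genotype columns.
#' @return list with \code{genotypes} (low-density columns only),
#'   \code{mask} (withheld snp_ids) and \code{mask_idx} (withheld column
#'   positions in the input).
#' @export
mask_to_low_density <- function(genotypes, snp_map) {
  if (!identical(colnames(genotypes), snp_map$snp_id)) {
    stop_ovimp("snp_map must cover the genotype columns in order")
  }
  keep <- snp_map$panel == "both"
  if (!any(keep)) stop_ovimp("low-density subpanel is empty")
  list(genotypes = genotypes[, keep, drop = FALSE],
       mask = snp_map$snp_id[!keep],
       mask_idx = which(!keep))
}

#' Inject sporadic missingness into a genotype matrix
#'
#' @param genotypes matrix of 0/1/2.
#' @param rate per-cell missingness probability (default 0.02, must be <= 0.1).
#' @param seed integer seed.
#' @return matrix with NA at missing cells.
#' @export
inject_missing <- function(genotypes, rate = 0.02, seed = 1) {
  stopifnot(rate >= 0, rate <= 0.1)
  with_substream(seed, "missing", {
    drop <- matrix(runif(length(genotypes)) < rate, nrow = nrow(genotypes))
    genotypes[drop] <- NA
    genotypes
  })
}

#' Simulate per-cell genotype-call confidence (GC) scores
#'
#' Scores lie in [0, 1]; most cells score high, with a configurable fraction
#' of low-confidence calls. These stand in for array GC scores for exercising
#' the quality-control cascade; real array GC semantics are not modelled.
#'
#' @param genotypes matrix whose dimensions the scores must match.
#' @param low_fraction fraction of cells drawn from the low-score regime.
#' @param seed integer seed.
#' @return numeric matrix of scores in [0, 1].
#' @export
simulate_gc_scores <- function(genotypes, low_fraction = 0.01, seed = 1) {
  with_substream(seed, "gc_scores", {
    n <- length(genotypes)
    sc <- 0.6 + 0.4 * rbeta(n, 8, 1)
    low <- runif(n) < low_fraction
    sc[low] <- runif(sum(low), 0, 0.6)
    matrix(sc, nrow = nrow(genotypes), dimnames = dimnames(genotypes))
  })
}

#' Fill sporadic missing genotypes
#'
#' Per-marker fill of missing cells, either with the marker mean dosage
#' (\code{"mean"}, suitable for relationship matrices) or the rounded mean
#' (\code{"round"}, keeps genotypes integer for phasing).
#'
#' @param genotypes matrix with NA for missing.
#' @param method "mean" or "round".
#' @return filled matrix.
#' @export
fill_missing <- function(genotypes, method = c("mean", "round")) {
  method <- match.arg(method)
  if (!anyNA(genotypes)) return(genotypes)
  mns <- colMeans(genotypes, na.rm = TRUE)
  mns[is.nan(mns)] <- 0
  for (j in which(colSums(is.na(genotypes)) > 0)) {
    v <- if (method == "mean") mns[j] else round(mns[j])
    genotypes[is.na(genotypes[, j]), j] <- v
  }
  genotypes
}
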