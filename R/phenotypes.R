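# Phenotype simulation: additive QTL effects, maternal and breed effects,
# fixed effects, and progeny-test EBVs for validation sires.

#' Define a trait model
#'
#' Variance components and fixed-effect structure for simulated phenotypes:
#' y = fixed effects + g + w(dam) + q(breed) + e, with g the additive genetic
#' value from a random subset of markers carrying normal QTL effects
#' (rescaled so the sample variance of g equals \code{var_additive} exactly),
#' w a dam-level maternal effect, and q a breed-level effect applied through
#' breed proportions.
#'
#' @param var_additive additive variance (sigma^2_g).
#' @param var_maternal maternal variance (sigma^2_w).
#' @param var_breed breed-effect variance (sigma^2_q).
#' @param var_residual residual variance (sigma^2_e).
#' @param n_qtl number of markers carrying QTL effects.
#' @param fixed_effect_levels named list mapping each fixed factor to a named
#'   vector of level effects; covariate slopes given as single numbers under
#'   \code{age} and \code{weight}.
#' @return list of class \code{trait_model}.
#' @export
trait_model <- function(var_additive = 0.3, var_maternal = 0,
                        var_breed = 0, var_residual = 0.7,
                        n_qtl = 50,
                        fixed_effect_levels = list(
                          birth_type = c(`1` = 0, `2` = -0.15, `3` = -0.3),
                          rearing_type = c(`1` = 0, `2` = -0.1),
                          gender = c(F = 0, M = 0.25),
                          age = 0.004, weight = 0.01)) {
  v <- c(var_additive, var_maternal, var_breed, var_residual)
  if (any(v < 0)) stop_ovimp("variance components must be >= 0")
  if (all(v == 0) && length(fixed_effect_levels) == 0) {
    stop_ovimp("at least one variance component or fixed effect must be set")
  }
  structure(list(var_additive = var_additive, var_maternal = var_maternal,
                 var_breed = var_breed, var_residual = var_residual,
                 n_qtl = n_qtl, fixed_effect_levels = fixed_effect_levels),
            class = "trait_model")
}

#' Simulate phenotypes and true breeding values
#'
#' QTL markers are a random subset of the medium-density panel; their allele
#' substitution effects are standard normal, and the resulting genetic values
#' are centred and rescaled so their sample variance equals
#' \code{var_additive} exactly (so variance-recovery checks have an exact
#' target). Maternal effects are drawn per dam; animals without a recorded
#' dam get a zero maternal contribution (with one warning). Breed effects are
#' drawn per breed and applied through breed proportions. Fixed effects:
#' birth type, rearing type, gender, age and weight covariates, and a
#' contemporary group formed as flock x birth year x management group.
#'
#' @param pop an \code{ovimp_population}.
#' @param ids animals to phenotype (default: all non-founders).
#' @param trait a \code{\link{trait_model}}.
#' @param seed integer seed.
#' @return list with \code{phenotypes} (data.frame: id, y, fixed-effect
#'   columns, contemporary_group), \code{true_bv} (named vector over all
#'   animals in the population), \code{qtl} (snp ids used).
#' @export
simulate_phenotypes <- function(pop, trait, ids = NULL, seed = 1) {
  stopifnot(inherits(pop, "ovimp_population"), inherits(trait, "trait_model"))
  ped <- pop$pedigree
  if (is.null(ids)) ids <- ped$id[ped$group != "founder"]
  if (!all(ids %in% ped$id)) stop_ovimp("unknown ids in phenotype request")

  with_substream(seed, "phenotypes", {
    G <- pop$genotypes
    all_ids <- rownames(G)
    m <- ncol(G)
    n_qtl <- min(trait$n_qtl, m)

    # additive values over the whole population, exact target variance
    if (trait$var_additive > 0) {
      qtl <- sort(sample.int(m, n_qtl))
      a <- rnorm(n_qtl)
      g <- as.vector(G[, qtl, drop = FALSE] %*% a)
      g <- g - mean(g)
      sdg <- sd(g)
      if (sdg > 0) g <- g * sqrt(trait$var_additive) / sdg
    } else {
      qtl <- integer(0)
      g <- numeric(length(all_ids))
    }
    names(g) <- all_ids

    # maternal effects per dam
    dam_ids <- unique(stats::na.omit(ped$dam))
    w <- setNames(if (trait$var_maternal > 0)
      rnorm(length(dam_ids), 0, sqrt(trait$var_maternal))
      else numeric(length(dam_ids)), dam_ids)

    # breed effects
    Q <- breed_composition(ped)
    q <- setNames(if (trait$var_breed > 0)
      rnorm(ncol(Q), 0, sqrt(trait$var_breed)) else numeric(ncol(Q)),
      colnames(Q))

    sub <- ped[match(ids, ped$id), ]
    fe <- trait$fixed_effect_levels
    pick_level <- function(fac) {
      lv <- names(fe[[fac]])
      factor(sample(lv, length(ids), replace = TRUE), levels = lv)
    }
    birth_type <- if (!is.null(fe$birth_type)) pick_level("birth_type") else
      factor(rep("1", length(ids)))
    rearing_type <- if (!is.null(fe$rearing_type)) pick_level("rearing_type") else
      factor(rep("1", length(ids)))
    gender <- factor(sub$sex, levels = c("F", "M"))
    age <- round(runif(length(ids), 200, 320))
    weight <- round(rnorm(length(ids), 40, 4), 1)
    mgmt <- sample(c("g1", "g2"), length(ids), replace = TRUE)
    cg <- paste(sub$flock, sub$birth_year, mgmt, sep = "_")

    fixed_part <- numeric(length(ids))
    if (!is.null(fe$birth_type)) fixed_part <- fixed_part +
      fe$birth_type[as.character(birth_type)]
    if (!is.null(fe$rearing_type)) fixed_part <- fixed_part +
      fe$rearing_type[as.character(rearing_type)]
    if (!is.null(fe$gender)) fixed_part <- fixed_part +
      fe$gender[as.character(gender)]
    if (!is.null(fe$age)) fixed_part <- fixed_part + fe$age * age
    if (!is.null(fe$weight)) fixed_part <- fixed_part + fe$weight * weight

    has_dam <- !is.na(sub$dam)
    if (!all(has_dam) && trait$var_maternal > 0) {
      warning("some phenotyped animals have no recorded dam; their maternal contribution is 0")
    }
    w_part <- ifelse(has_dam, w[sub$dam], 0)
    q_part <- as.vector(Q[match(ids, rownames(Q)), , drop = FALSE] %*% q)
    e <- if (trait$var_residual > 0)
      rnorm(length(ids), 0, sqrt(trait$var_residual)) else numeric(length(ids))

    y <- as.numeric(fixed_part + g[ids] + w_part + q_part + e)
    phen <- data.frame(id = ids, y = y, birth_type = birth_type,
                       rearing_type = rearing_type, gender = gender,
                       age = age, weight = weight,
                       flock = sub$flock, birth_year = sub$birth_year,
                       mgmt = mgmt, contemporary_group = cg,
                       stringsAsFactors = FALSE)
    list(phenotypes = phen, true_bv = g,
         qtl = colnames(G)[qtl],
         effects = list(maternal = w, breed = q))
  })
}

#' Simulate progeny-test EBVs for validation sires
#'
#' Each sire's reported EBV is built to have a target accuracy r with its
#' true breeding value: reported = sd(bv) * (r z + sqrt(1 - r^2) noise) +
#' mean(bv), with z the standardized true value. Per-sire accuracies are
#' drawn on [min, max] with the configured mean (Beta-shaped), emulating
#' progeny-test breeding values whose published accuracies range 0.70-0.99
#' with mean 0.88.
#'
#' @param true_bv named numeric vector of true breeding values.
#' @param accuracy_spec list(min, mean, max) with 0 < min <= mean <= max <= 1.
#' @param seed integer seed.
#' @return data.frame (id, true_bv, reported_ebv, target_accuracy).
#' @export
simulate_progeny_test_ebv <- function(true_bv,
                                      accuracy_spec = list(min = 0.70,
                                                           mean = 0.88,
                                                           max = 0.99),
                                      seed = 1) {
  a <- accuracy_spec
  if (!(a$min > 0 && a$min <= a$mean && a$mean <= a$max && a$max <= 1)) {
    stop_ovimp("accuracy_spec must satisfy 0 < min <= mean <= max <= 1")
  }
  n <- length(true_bv)
  with_substream(seed, "progeny_ebv", {
    if (a$max == a$min) {
      r <- rep(a$min, n)
    } else {
      mu <- (a$mean - a$min) / (a$max - a$min)
      conc <- 12
      r <- a$min + (a$max - a$min) * rbeta(n, mu * conc, (1 - mu) * conc)
    }
    mbv <- mean(true_bv)
    sbv <- sd(true_bv)
    if (is.na(sbv) || sbv == 0) sbv <- 1
    z <- (true_bv - mbv) / sbv
    noise <- rnorm(n)
    reported <- sbv * (r * z + sqrt(1 - r^2) * noise) + mbv
    data.frame(id = names(true_bv) %||% as.character(seq_len(n)),
               true_bv = as.numeric(true_bv),
               reported_ebv = as.numeric(reported),
               target_accuracy = r, stringsAsFactors = FALSE)
  })
}
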