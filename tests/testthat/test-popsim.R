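# Population simulator: breed divergence, recombination, pedigree structure,
# panel masking, determinism.

test_that("founder frequencies follow the Balding-Nichols model", {
  bm0 <- breed_model(fst = 0)
  f0 <- simulate_founder_frequencies(500, bm0, seed = 1)
  expect_true(all(f0 == attr(f0, "ancestral")))

  # variance across breeds/SNPs at fixed ancestral p: Fst * p(1-p)
  bm <- breed_model(breed_names = c("A", "B"), fst = 0.1,
                    ancestral_freq_range = c(0.4999, 0.5001))
  f <- simulate_founder_frequencies(20000, bm, seed = 2)
  expect_equal(var(as.vector(f)), 0.1 * 0.25, tolerance = 0.05)

  # Hudson Fst from large per-breed haplotype samples recovers fst
  set.seed(3)
  bm2 <- breed_model(breed_names = c("A", "B"), fst = 0.1)
  f2 <- simulate_founder_frequencies(20000, bm2, seed = 3)
  n <- 400
  p1 <- rbinom(nrow(f2), n, f2[, 1]) / n
  p2 <- rbinom(nrow(f2), n, f2[, 2]) / n
  expect_equal(hudson_fst(p1, p2, n, n), 0.1, tolerance = 0.02)

  expect_error(breed_model(fst = 1), "fst")
  expect_error(breed_model(fst = -0.1), "fst")
  expect_error(breed_model(ancestral_freq_range = c(0, 0.9)), "range")
})

test_that("gametes recombine with Poisson crossover counts on the cM map", {
  m <- 101
  map1 <- data.frame(snp_id = paste0("s", 1:m), chrom = 1,
                     pos_bp = 1:m * 1000, pos_cm = seq(0, 100, length.out = m),
                     panel = c(rep("both", 50), rep("50k_only", m - 50)))
  h1 <- rep(0L, m); h2 <- rep(1L, m)

  # zero map length: every gamete is one unrecombined parental haplotype
  map0 <- map1; map0$pos_cm <- 0
  set.seed(1)
  for (i in 1:10) {
    g <- ovimp:::make_gamete(h1, h2, map0)
    expect_true(all(g == 0L) || all(g == 1L))
  }

  # 1 Morgan: mean observed switch count ~ 1 over 10,000 gametes
  set.seed(2)
  switches <- replicate(10000, {
    g <- ovimp:::make_gamete(h1, h2, map1)
    sum(g[-1] != g[-m])
  })
  expect_equal(mean(switches), 1.0, tolerance = 0.05)
})

test_that("the simulated population has consistent haplotypes, pedigree and crosses", {
  bundle <- toy_bundle()
  pop <- bundle$pop
  H <- pop$haplotypes
  expect_identical(unname(H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]),
                   unname(pop$genotypes))

  ped <- pop$pedigree
  Q <- breed_composition(ped)
  expect_true(all(abs(rowSums(Q) - 1) < 1e-9))

  # F1 records: exactly two breeds at 0.5, non-Merino sire x Merino dam
  f1 <- ped[ped$group == "f1_BorderLeicester", ]
  expect_true(all(f1$prop_BorderLeicester == 0.5 & f1$prop_Merino == 0.5))
  sire_rows <- ped[match(f1$sire, ped$id), ]
  dam_rows <- ped[match(f1$dam, ped$id), ]
  expect_true(all(sire_rows$prop_BorderLeicester == 1))
  expect_true(all(dam_rows$prop_Merino == 1))
  expect_true(all(sire_rows$sex == "M") && all(dam_rows$sex == "F"))

  # half-sib family structure: local sires serve one flock (families capped
  # at the design size); shared AI sires serve every flock
  mer <- ped[ped$group == "pure_Merino", ]
  fam <- table(mer$sire)
  des <- toy_design()
  expect_true(all(fam <= des$progeny_per_sire * des$n_flocks))
  expect_gt(length(fam), 5)
  flocks_per_sire <- tapply(mer$flock, mer$sire, function(x)
    length(unique(x)))
  expect_gt(max(flocks_per_sire), 1)   # AI sires connect flocks
  expect_equal(min(flocks_per_sire), 1)

  # infeasible design (more sires required than male founders) errors early
  bad <- toy_design(); bad$purebred_progeny["Merino"] <- 1e6
  expect_error(
    simulate_population(breed_model(), bundle$snp_map, bad, seed = 1),
    "founders|sires|dams")
})

test_that("identical seeds give bit-identical populations", {
  map <- make_snp_map(n_chr = 1, markers_per_chr = 40)
  des <- mating_design(n_founders = c(Merino = 10, BorderLeicester = 6,
                                      PollDorset = 6, WhiteSuffolk = 6),
                       purebred_progeny = c(Merino = 10),
                       f1_progeny = c(BorderLeicester = 6))
  p1 <- simulate_population(breed_model(), map, des, seed = 99)
  p2 <- simulate_population(breed_model(), map, des, seed = 99)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$haplotypes, p2$haplotypes)
  p3 <- simulate_population(breed_model(), map, des, seed = 100)
  expect_false(identical(p1$genotypes, p3$genotypes))
})

test_that("masking to the low-density panel withholds exactly the 50k-only markers", {
  G <- matrix(0:1, nrow = 4, ncol = 10)
  colnames(G) <- paste0("s", 1:10)
  map <- data.frame(snp_id = paste0("s", 1:10), chrom = 1,
                    pos_bp = 1:10, pos_cm = (1:10) / 10,
                    panel = rep(c("both", "50k_only", "50k_only",
                                  "50k_only", "both"), 2))
  masked <- mask_to_low_density(G, map)
  expect_equal(ncol(masked$genotypes), 4)
  expect_equal(length(masked$mask), 6)
  # round trip: restoring the withheld columns reproduces the input exactly
  rebuilt <- matrix(NA, 4, 10, dimnames = dimnames(G))
  rebuilt[, colnames(masked$genotypes)] <- masked$genotypes
  rebuilt[, masked$mask] <- G[, masked$mask]
  expect_identical(rebuilt, G)

  map_bad <- map; map_bad$panel <- "50k_only"
  expect_error(mask_to_low_density(G, map_bad), "empty")
})

test_that("phenotype simulation decomposes variance as configured", {
  # degenerate: zero variances and zero-valued fixed effects -> y is 0
  bundle <- toy_bundle()
  tr0 <- trait_model(var_additive = 0, var_maternal = 0, var_breed = 0,
                     var_residual = 0,
                     fixed_effect_levels = list(gender = c(F = 0, M = 0)))
  ph0 <- simulate_phenotypes(bundle$pop, tr0, seed = 5)
  expect_true(all(ph0$phenotypes$y == 0))

  # h2 recovery on a large population: slope of y on true g ~ 1, h2 ~ 0.3
  map <- make_snp_map(n_chr = 2, markers_per_chr = 60)
  des <- mating_design(n_founders = c(Merino = 60, BorderLeicester = 4,
                                      PollDorset = 4, WhiteSuffolk = 4),
                       progeny_per_sire = 250,
                       purebred_progeny = c(Merino = 5000),
                       f1_progeny = c(BorderLeicester = 0))
  pop <- simulate_population(breed_model(), map, des, seed = 6)
  tr <- trait_model(var_additive = 0.3, var_residual = 0.7,
                    var_maternal = 0, fixed_effect_levels = list())
  ph <- simulate_phenotypes(pop, tr, seed = 6)
  y <- ph$phenotypes$y
  g <- ph$true_bv[ph$phenotypes$id]
  expect_equal(unname(coef(lm(y ~ g))[2]), 1, tolerance = 0.08)
  expect_equal(var(g) / var(y), 0.3, tolerance = 0.03)
  # exact rescaling: population-wide sample variance of g hits sigma2_g
  expect_equal(var(ph$true_bv), 0.3, tolerance = 1e-10)
})

test_that("progeny-test EBVs hit their target accuracies", {
  set.seed(7)
  bv <- setNames(rnorm(2000), paste0("sire", 1:2000))
  # r = 1: reported equals truth exactly
  e1 <- simulate_progeny_test_ebv(bv, list(min = 1, mean = 1, max = 1), seed = 1)
  expect_equal(e1$reported_ebv, unname(bv))

  # fixed r = 0.9: empirical correlation ~ 0.9
  e9 <- simulate_progeny_test_ebv(bv, list(min = 0.9, mean = 0.9, max = 0.9),
                                  seed = 2)
  expect_equal(cor(e9$reported_ebv, e9$true_bv), 0.9, tolerance = 0.02)

  # published-style accuracy range is respected
  er <- simulate_progeny_test_ebv(bv, list(min = 0.70, mean = 0.88,
                                           max = 0.99), seed = 3)
  expect_true(all(er$target_accuracy >= 0.70 & er$target_accuracy <= 0.99))
  expect_equal(mean(er$target_accuracy), 0.88, tolerance = 0.02)

  expect_error(simulate_progeny_test_ebv(bv, list(min = 0, mean = 0.5,
                                                  max = 0.9)), "accuracy")
})
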