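# Li-Stephens imputation engine: forward-backward vs path enumeration,
# diploid dosages vs pair enumeration, phasing quality, determinism.

test_that("haploid forward-backward equals brute-force path enumeration", {
  set.seed(41)
  for (rep in 1:40) {
    H <- sample(1:4, 1); M <- sample(2:6, 1)
    ref <- rand_ref(H, M, seed = 41000 + rep)
    obs <- rbinom(M, 1, 0.5); obs[runif(M) < 0.25] <- NA
    rho <- runif(M - 1, 0.01, 0.9)
    eps <- runif(1, 0.001, 0.2)
    fb <- forward_backward(obs, ref, rho = rho,
                           params = ls_params(error_rate = eps))
    expect_lt(max(abs(fb$state_post - enum_fb_haploid(ref, obs, rho, eps))),
              1e-9)
    expect_equal(colSums(fb$state_post), rep(1, M), tolerance = 1e-10)
  }
})

test_that("single-haplotype reference gives a degenerate posterior", {
  ref <- matrix(c(1L, 0L, 1L, 1L), nrow = 1)
  obs <- c(NA, NA, NA, NA)
  fb <- forward_backward(obs, ref, rho = rep(0.2, 3),
                         params = ls_params(error_rate = 0.001))
  expect_equal(as.vector(fb$state_post), rep(1, 4))
  expect_equal(round(fb$allele_post), c(1, 0, 1, 1))
})

test_that("a target matching one reference haplotype is confidently copied", {
  set.seed(42)
  ref <- rand_ref(4, 10, seed = 4242)
  ref[1, ] <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1)   # make row 1 distinctive
  obs <- ref[1, ]
  fb <- forward_backward(obs, ref, rho = rep(0.004, 9),
                         params = ls_params(error_rate = 0.001))
  dup <- apply(ref, 1, identical, y = ref[1, ])
  expect_true(all(colSums(fb$state_post[dup, , drop = FALSE]) > 0.99))
})

test_that("diploid dosages equal ordered-pair path enumeration", {
  set.seed(43)
  for (rep in 1:12) {
    H <- sample(2:3, 1); M <- sample(2:4, 1)
    ref <- rand_ref(H, M, seed = 43000 + rep)
    g <- rbinom(M, 2, 0.5); g[runif(M) < 0.3] <- NA
    rho <- runif(M - 1, 0.05, 0.8)
    eps <- runif(1, 0.001, 0.1)
    fb <- ovimp:::.ls_fb_diploid(ref, ifelse(is.na(g), -1L, as.integer(g)),
                                 rho, eps)
    want <- enum_fb_diploid(ref, g, rho, eps)
    expect_lt(max(abs(fb$dosage - want)), 1e-9)
    # certify the dense pair-state oracle against true path enumeration
    expect_lt(max(abs(dense_fb_diploid(ref, g, rho, eps) - want)), 1e-9)
  }
})

test_that("impute_individual recovers a perfect-panel target exactly", {
  # both true haplotypes present in the reference, tiny error rate:
  # best-guess genotypes equal the truth at every masked marker
  map <- make_snp_map(n_chr = 2, markers_per_chr = 40, chr_length_cm = 20,
                      low_density_every = 4)
  set.seed(44)
  base <- matrix(rbinom(16 * 80, 1, 0.5), 16, 80)
  colnames(base) <- map$snp_id
  h1 <- base[1, ]; h2 <- base[2, ]
  ids <- paste0("r", 1:8)
  rownames(base) <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
  panel <- hap_panel(base, ids)
  truth <- h1 + h2
  low <- truth[map$panel == "both"]
  res <- impute_individual(low, panel, map,
                           ls_params(error_rate = 1e-4, ne_eff = 5))
  expect_identical(unname(res$best_guess), unname(truth))
  expect_equal(individual_accuracy(truth, res$best_guess,
                                   map$snp_id[map$panel != "both"]), 1)
  # observed markers pass through as exact dosages
  expect_equal(unname(res$dosage[map$panel == "both"]), unname(low))
})

test_that("impute_individual matches diploid enumeration on a recombinant toy", {
  # 6-haplotype reference, 12 markers, 4 typed; target recombines two
  # reference haplotypes mid-chromosome
  set.seed(45)
  ref <- rand_ref(6, 12, seed = 4545)
  map <- data.frame(snp_id = sprintf("s%02d", 1:12), chrom = 1,
                    pos_bp = 1:12 * 1000, pos_cm = seq(0, 55, by = 5),
                    panel = rep(c("both", "50k_only", "50k_only"), 4))
  colnames(ref) <- map$snp_id
  ids <- paste0("r", 1:3)
  rownames(ref) <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
  h1 <- c(ref[1, 1:6], ref[3, 7:12])     # recombinant of hap 1 and hap 3
  h2 <- ref[5, ]
  truth <- h1 + h2
  low <- truth[map$panel == "both"]
  params <- ls_params(error_rate = 0.01, ne_eff = 50)
  res <- impute_individual(low, hap_panel(ref, ids), map, params)

  obs_full <- rep(NA_integer_, 12)
  obs_full[map$panel == "both"] <- low
  rho <- 1 - exp(-4 * 50 * (diff(map$pos_cm) / 100) / 6)
  want <- dense_fb_diploid(ref, obs_full, rho, 0.01)
  masked <- map$panel != "both"
  expect_lt(max(abs(res$dosage[masked] - want[masked])), 1e-8)
})

test_that("per-chromosome and single-chain imputation agree", {
  map <- make_snp_map(n_chr = 2, markers_per_chr = 25, low_density_every = 5)
  set.seed(46)
  H <- matrix(rbinom(12 * 50, 1, 0.5), 12, 50)
  colnames(H) <- map$snp_id
  ids <- paste0("r", 1:6)
  rownames(H) <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
  panel <- hap_panel(H, ids)
  truth <- H[1, ] + H[4, ]
  low <- truth[map$panel == "both"]
  a <- impute_individual(low, panel, map, ls_params(per_chromosome = TRUE))
  b <- impute_individual(low, panel, map, ls_params(per_chromosome = FALSE))
  expect_equal(a$dosage, b$dosage, tolerance = 1e-12)
})

test_that("dosages respect bounds and typed-marker pass-through", {
  bundle <- toy_bundle()
  map <- bundle$snp_map
  ids <- bundle$groups$merino_pure
  panel <- true_hap_panel(bundle$pop, ids[31:70])
  test_ids <- ids[1:5]
  low <- mask_to_low_density(bundle$pop$genotypes[test_ids, , drop = FALSE],
                             map)
  res <- impute_set(low$genotypes, panel, map, fast_params(), seed = 2)
  expect_true(all(res$dosage >= 0 & res$dosage <= 2))
  typed <- map$panel == "both"
  expect_equal(unname(res$dosage[, typed]),
               unname(bundle$pop$genotypes[test_ids, typed] * 1.0))
  expect_true(all(res$best_guess %in% 0:2))
  # empty test set: empty result, no error
  res0 <- impute_set(low$genotypes[integer(0), , drop = FALSE], panel, map,
                     fast_params(), seed = 2)
  expect_equal(nrow(res0$dosage), 0)
})

test_that("phasing recovers haplotypes with low switch error and is deterministic", {
  # switch-error bar evaluated at panel scale: 200 individuals x 500 markers
  full <- simulate_study_population(seed = 12)
  ids <- full$groups$merino_pure[1:200]
  G <- full$pop$genotypes[ids, , drop = FALSE]
  p1 <- phase_panel(G, full$snp_map, ls_params(), seed = 9)

  # haplotype pairs always sum to the genotypes
  expect_identical(unname(p1$haplotypes[seq(1, 400, 2), ] +
                            p1$haplotypes[seq(2, 400, 2), ]), unname(G))

  truth <- true_hap_panel(full$pop, ids)
  ser <- switch_error_rate(p1, truth, full$snp_map)
  expect_lt(ser, 0.05)

  # determinism under the seed, on a smaller panel
  bundle <- toy_bundle()
  map <- bundle$snp_map
  ids2 <- bundle$groups$merino_pure[1:40]
  G2 <- bundle$pop$genotypes[ids2, , drop = FALSE]
  pa <- phase_panel(G2, map, fast_params(), seed = 9)
  pb <- phase_panel(G2, map, fast_params(), seed = 9)
  expect_identical(pa$haplotypes, pb$haplotypes)

  # an individual with <= 1 het per chromosome has a determined phase
  g1 <- matrix(0L, 1, nrow(map), dimnames = list("solo", map$snp_id))
  g1[1, c(3, 130)] <- 1L                  # one het on each chromosome
  ph <- quietly_(phase_panel(g1, map, ls_params(n_iterations = 1), seed = 1))
  expect_identical(unname(ph$haplotypes[1, ] + ph$haplotypes[2, ]),
                   unname(g1[1, ]))
})

test_that("imputation is seed-deterministic end to end", {
  bundle <- toy_bundle()
  map <- bundle$snp_map
  ids <- bundle$groups$merino_pure
  refG <- bundle$pop$genotypes[ids[11:40], , drop = FALSE]
  low <- mask_to_low_density(bundle$pop$genotypes[ids[1:3], , drop = FALSE],
                             map)
  a <- impute_set(low$genotypes, refG, map, fast_params(), seed = 5)
  b <- impute_set(low$genotypes, refG, map, fast_params(), seed = 5)
  expect_identical(a$dosage, b$dosage)
})
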