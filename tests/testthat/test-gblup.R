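# Mixed-model machinery: design construction, REML (spectral + AI/EM),
# MME solutions vs dense conditional-mean algebra, validation statistics.

toy_phen <- function(n = 16) {
  # patterns chosen so no fixed-effect column is aliased with another
  mgmt <- rep(c("g1", "g2"), each = max(n %/% 4, 1), length.out = n)
  flock <- rep(1:2, each = max(n %/% 2, 1), length.out = n)
  data.frame(id = paste0("a", seq_len(n)),
             y = rnorm(n),
             birth_type = factor(rep(c("1", "2"), length.out = n)),
             rearing_type = factor(rep("1", n)),
             gender = rep(c("F", "F", "M", "M"), length.out = n),
             age = 200 + (seq_len(n) * 37) %% 97,
             weight = 35 + (seq_len(n)^2 %% 11),
             flock = flock, birth_year = 2001,
             mgmt = mgmt,
             contemporary_group = paste(flock, 2001, mgmt, sep = "_"),
             stringsAsFactors = FALSE)
}

test_that("build_design constructs the documented fixed-effect matrix", {
  set.seed(61)
  ph <- toy_phen(16)
  spec <- build_design(ph, toy_ped(ph$id), ph$id)
  # hand-built design: intercept + birth_type2 + genderM + age + weight +
  # 3 contemporary-group contrasts (4 levels); rearing_type collapses
  X <- spec$X
  expect_true("(Intercept)" %in% colnames(X))
  expect_false(any(grepl("rearing", colnames(X))))
  expect_equal(qr(X)$rank, ncol(X))
  manual <- model.matrix(~ birth_type + gender + contemporary_group +
                           age + weight,
                         transform(ph, birth_type = factor(birth_type),
                                   gender = factor(gender),
                                   contemporary_group =
                                     factor(contemporary_group)))
  expect_setequal(colnames(X), colnames(manual))
  expect_equal(unname(X[, sort(colnames(X))]),
               unname(manual[, sort(colnames(X))]))

  # 2 flocks x 2 years -> 4 contemporary groups -> 3 columns
  ph2 <- toy_phen(16)
  ph2$birth_year <- rep(c(2001, 2002), each = 4, length.out = 16)
  ph2$contemporary_group <- paste(ph2$flock, ph2$birth_year, "g1", sep = "_")
  spec2 <- build_design(ph2, toy_ped(ph2$id), ph2$id)
  expect_equal(sum(grepl("contemporary", colnames(spec2$X))), 3)

  # single contemporary group and single gender collapse into the intercept
  ph3 <- toy_phen(16)
  ph3$gender <- "F"; ph3$contemporary_group <- "1_2001_g1"
  spec3 <- build_design(ph3, toy_ped(ph3$id), ph3$id)
  expect_false(any(grepl("gender|contemporary", colnames(spec3$X))))
  expect_equal(qr(spec3$X)$rank, ncol(spec3$X))

  # unresolvable phenotype row errors with the offending id
  expect_error(build_design(ph, toy_ped(ph$id[-1]), ph$id), "a1")
  expect_error(build_design(ph, toy_ped(ph$id), ph$id[-1]), "not among")
})

test_that("spectral REML equals closed-form one-way ANOVA REML on balanced data", {
  set.seed(62)
  q <- 12; nrep <- 8; n <- q * nrep
  sa2 <- 2.0; se2 <- 1.0
  a <- rnorm(q, 0, sqrt(sa2))
  grp <- rep(seq_len(q), each = nrep)
  y <- 5 + a[grp] + rnorm(n, 0, sqrt(se2))
  ph <- data.frame(id = paste0("g", grp), y = y, birth_type = "1",
                   rearing_type = "1", gender = "F", age = 0, weight = 0,
                   flock = 1, birth_year = 2001, mgmt = "g1",
                   contemporary_group = "cg", stringsAsFactors = FALSE)
  # Z maps records to q group effects with G = I
  spec <- build_design(ph, toy_ped(paste0("g", 1:q)), paste0("g", 1:q))
  vc <- reml_estimate(spec, diag(q))

  # closed form: se2 = MSE; sa2 = (MSB - MSE) / nrep
  ybar <- tapply(y, grp, mean)
  msb <- nrep * sum((ybar - mean(y))^2) / (q - 1)
  mse <- sum((y - ybar[grp])^2) / (n - q)
  expect_equal(vc$sigma2[["e"]], mse, tolerance = 1e-5)
  expect_equal(vc$sigma2[["g"]], (msb - mse) / nrep, tolerance = 1e-4)
})

test_that("AI-REML with EM fallback matches the spectral path and is monotone under EM", {
  set.seed(63)
  n <- 120; m <- 150
  M <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(paste0("a", 1:n), NULL))
  G <- compute_grm(M)
  g <- as.vector(t(chol(as.matrix(G) + diag(1e-6, n))) %*% rnorm(n)) * 0.6
  y <- 2 + g + rnorm(n, 0, 0.8)
  ph <- toy_phen(16)[rep(1, n), ]
  ph$id <- paste0("a", 1:n); ph$y <- y
  ph$birth_type <- "1"; ph$gender <- "F"; ph$contemporary_group <- "cg"
  ph$age <- 0; ph$weight <- 0
  rownames(ph) <- NULL
  spec <- build_design(ph, toy_ped(ph$id), ph$id)

  vs <- reml_estimate(spec, G, method = "auto")
  va <- reml_estimate(spec, G, method = "ai")
  expect_equal(va$sigma2[["g"]], vs$sigma2[["g"]], tolerance = 1e-3)
  expect_equal(va$sigma2[["e"]], vs$sigma2[["e"]], tolerance = 1e-3)

  ve <- reml_estimate(spec, G, method = "em", max_rounds = 40)
  expect_true(all(diff(ve$trace) > -1e-6))   # EM: non-decreasing loglik
})

test_that("REML flags boundary components and degenerate responses", {
  set.seed(64)
  # y exactly in the column space of X: residual collapses to the boundary
  n <- 30
  ph <- toy_phen(16)[rep(1, n), ]
  ph$id <- paste0("a", 1:n)
  ph$birth_type <- "1"; ph$gender <- "F"; ph$contemporary_group <- "cg"
  ph$age <- seq_len(n); ph$weight <- 0
  ph$y <- 3 + 0.1 * ph$age
  rownames(ph) <- NULL
  spec <- build_design(ph, toy_ped(ph$id), ph$id)
  vc <- reml_estimate(spec, diag(n))
  expect_true(vc$boundary[["e"]] || vc$sigma2[["e"]] < 1e-6)
})

test_that("MME solutions equal dense joint-normal conditional means", {
  set.seed(65)
  for (rep in 1:6) {
    n <- sample(20:60, 1)
    m <- 80
    M <- matrix(rbinom(n * m, 2, runif(1, 0.3, 0.6)), n, m,
                dimnames = list(paste0("a", 1:n), NULL))
    G <- compute_grm(M)
    Gm <- as.matrix(G) + diag(1e-6, n)
    y <- rnorm(n)
    ph <- data.frame(id = paste0("a", 1:n), y = y, birth_type = "1",
                     rearing_type = "1",
                     gender = rep(c("F", "M"), length.out = n),
                     age = runif(n, 200, 300), weight = 0, flock = 1,
                     birth_year = 2001, mgmt = "g1",
                     contemporary_group = "cg", stringsAsFactors = FALSE)
    spec <- build_design(ph, toy_ped(ph$id), ph$id)
    sg2 <- runif(1, 0.2, 2); se2 <- runif(1, 0.2, 2)
    vc <- structure(list(sigma2 = c(g = sg2, e = se2), converged = TRUE,
                         boundary = c(g = FALSE, e = FALSE), loglik = 0),
                    class = "variance_components")
    sol <- solve_mme(spec, vc, Gm)
    want <- dense_blup(y, spec$X, spec$Z, Gm, sg2, se2)
    expect_lt(max(abs(sol$gebv$gebv - want)), 1e-8)
  }
})

test_that("closed-form single-record BLUP shrinkage holds with G = I", {
  set.seed(66)
  n <- 5
  y <- rnorm(n, 10, 2)
  ph <- data.frame(id = paste0("a", 1:n), y = y, birth_type = "1",
                   rearing_type = "1", gender = "F", age = 0, weight = 0,
                   flock = 1, birth_year = 2001, mgmt = "g1",
                   contemporary_group = "cg", stringsAsFactors = FALSE)
  spec <- build_design(ph, toy_ped(ph$id), ph$id)
  sg2 <- 0.7; se2 <- 1.3
  vc <- structure(list(sigma2 = c(g = sg2, e = se2), converged = TRUE,
                       boundary = c(g = FALSE, e = FALSE), loglik = 0),
                  class = "variance_components")
  sol <- solve_mme(spec, vc, diag(n))
  # intercept-only model, single record per animal, G = I:
  # ghat_i = (y_i - mu_hat) * sg2 / (sg2 + se2)  (equicorrelation exact form
  # uses the GLS mean, which here equals the plain mean)
  shrink <- sg2 / (sg2 + se2)
  expect_equal(sol$gebv$gebv, (y - mean(y)) * shrink, tolerance = 1e-6)

  # ridge limit: additive variance ~ 0 shrinks every GEBV to ~ 0
  vc0 <- structure(list(sigma2 = c(g = 1e-10, e = 1), converged = TRUE,
                        boundary = c(g = FALSE, e = FALSE), loglik = 0),
                   class = "variance_components")
  sol0 <- solve_mme(spec, vc0, diag(n))
  expect_lt(max(abs(sol0$gebv$gebv)), 1e-8)
})

test_that("GEBV validation accuracy and matrix correlations behave", {
  set.seed(67)
  gt <- structure(list(gebv = data.frame(id = paste0("s", 1:6),
                                         gebv = rnorm(6))),
                  class = "gebv_table")
  ebv <- data.frame(id = paste0("s", 1:6),
                    reported_ebv = gt$gebv$gebv, true_bv = 0,
                    target_accuracy = 1)
  expect_equal(as.numeric(gebv_accuracy(gt, ebv)), 1)
  ebv$reported_ebv <- -gt$gebv$gebv
  expect_equal(as.numeric(gebv_accuracy(gt, ebv)), -1)
  ebv$reported_ebv <- rnorm(6)
  expect_equal(as.numeric(gebv_accuracy(gt, ebv)),
               pearson(gt$gebv$gebv, ebv$reported_ebv))
  expect_equal(attr(gebv_accuracy(gt, ebv), "n"), 6)
  expect_error(gebv_accuracy(gt, data.frame(id = "zz", reported_ebv = 1)),
               "overlap")

  # GRM correlations: identity, affine invariance, oracle agreement
  M <- matrix(rbinom(10 * 60, 2, 0.4), 10, 60,
              dimnames = list(paste0("a", 1:10), NULL))
  A <- compute_grm(M)
  expect_equal(matrix_correlation(A, A), 1)
  B <- A; B$values <- 2.5 * A$values + 0.3
  expect_equal(matrix_correlation(A, B), 1)
  noisy <- M + matrix(rnorm(length(M), 0, 0.3), nrow(M))
  C <- compute_grm(noisy)
  ut <- upper.tri(A$values, diag = TRUE)
  expect_equal(matrix_correlation(A, C),
               pearson(A$values[ut], C$values[ut]))
  D <- compute_grm(M[c(2, 1, 3:10), ])
  expect_error(matrix_correlation(A, D), "id")
})

test_that("variance components are recovered in a g+w model with planted zeros", {
  ratios <- vapply(1:3, function(rep) {
    set.seed(680 + rep)
    n <- 400; m <- 300
    M <- matrix(rbinom(n * m, 2, 0.45), n, m,
                dimnames = list(paste0("a", 1:n), NULL))
    G <- compute_grm(M)
    g <- as.vector(t(chol(as.matrix(G) + diag(1e-6, n))) %*% rnorm(n))
    g <- g / sd(g) * sqrt(0.4)
    y <- 1 + g + rnorm(n, 0, sqrt(0.6))
    dams <- paste0("d", rep(1:80, each = 5))
    ph <- data.frame(id = paste0("a", 1:n), y = y, birth_type = "1",
                     rearing_type = "1", gender = "F", age = 0, weight = 0,
                     flock = 1, birth_year = 2001, mgmt = "g1",
                     contemporary_group = "cg", stringsAsFactors = FALSE)
    ped <- toy_ped(ph$id, dam = dams)
    spec <- build_design(ph, ped, ph$id)
    expect_false(is.null(spec$W))
    vc <- reml_estimate(spec, G)           # maternal variance truly 0
    # estimate stays small (constrained >= 0, sampling noise at 80 dams)
    expect_lt(vc$sigma2[["w"]], 0.1)
    vc$sigma2[["g"]] / sum(vc$sigma2[c("g", "e")])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.4), 0.06)
})
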