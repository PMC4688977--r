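# Independent brute-force oracles used across the suite. These deliberately
# use naive loops/enumeration, never the package's own computational path.

# --- haploid Li-Stephens posterior by full path enumeration -----------------
enum_fb_haploid <- function(ref, obs, rho, eps) {
  H <- nrow(ref); M <- ncol(ref)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), M)))
  pp <- apply(paths, 1, function(pt) {
    pr <- 1 / H
    for (j in seq_len(M)) {
      if (j > 1) {
        pr <- pr * if (pt[j] == pt[j - 1]) 1 - rho[j - 1] + rho[j - 1] / H else
          rho[j - 1] / H
      }
      if (!is.na(obs[j])) {
        pr <- pr * if (ref[pt[j], j] == obs[j]) 1 - eps else eps
      }
    }
    pr
  })
  post <- matrix(0, H, M)
  for (j in seq_len(M)) {
    for (k in seq_len(H)) post[k, j] <- sum(pp[paths[, j] == k])
  }
  sweep(post, 2, colSums(post), "/")
}

# --- diploid dosages by ordered-pair path enumeration -----------------------
enum_fb_diploid <- function(ref, g, rho, eps) {
  H <- nrow(ref); M <- ncol(ref); q <- 1 - eps
  em <- function(gj, s) {
    if (is.na(gj)) return(1)
    ev <- switch(s + 1,
                 c(q * q, 2 * q * eps, eps * eps),
                 c(q * eps, q * q + eps * eps, q * eps),
                 c(eps * eps, 2 * q * eps, q * q))
    ev[gj + 1]
  }
  dec <- function(s) c((s - 1) %/% H + 1, (s - 1) %% H + 1)
  tp <- function(a, b, r) if (a == b) 1 - r + r / H else r / H
  pairs <- as.matrix(expand.grid(rep(list(seq_len(H * H)), M)))
  pp <- apply(pairs, 1, function(pt) {
    pr <- 1 / (H * H)
    for (j in seq_len(M)) {
      kl <- dec(pt[j])
      if (j > 1) {
        kl0 <- dec(pt[j - 1])
        pr <- pr * tp(kl0[1], kl[1], rho[j - 1]) * tp(kl0[2], kl[2], rho[j - 1])
      }
      pr <- pr * em(g[j], ref[kl[1], j] + ref[kl[2], j])
    }
    pr
  })
  pp <- pp / sum(pp)
  dos <- numeric(M)
  for (j in seq_len(M)) {
    for (s in seq_len(H * H)) {
      kl <- dec(s)
      mk <- if (ref[kl[1], j] == 1) q else eps
      ml <- if (ref[kl[2], j] == 1) q else eps
      dos[j] <- dos[j] + sum(pp[pairs[, j] == s]) * (mk + ml)
    }
  }
  dos
}

# --- exact diploid posterior over explicit ordered-pair states --------------
# Dense-matrix marginalisation over the full (H^2)-state pair chain: explicit
# transition and emission matrices, plain alpha/beta products, no scaling and
# no factorisation. Independent of the package's kernels; agrees with true
# path enumeration (certified on tiny instances in test-impute).
dense_fb_diploid <- function(ref, g, rho, eps) {
  H <- nrow(ref); M <- ncol(ref); q <- 1 - eps; S <- H * H
  dec <- cbind(rep(seq_len(H), each = H), rep(seq_len(H), H))
  em_col <- function(j) {
    vapply(seq_len(S), function(s) {
      if (is.na(g[j])) return(1)
      a <- ref[dec[s, 1], j]; b <- ref[dec[s, 2], j]
      sum(vapply(0:1, function(x1) {
        x2 <- g[j] - x1
        if (x2 < 0 || x2 > 1) return(0)
        (if (x1 == a) q else eps) * (if (x2 == b) q else eps)
      }, numeric(1)))
    }, numeric(1))
  }
  tmat <- function(r) {
    t1 <- matrix(r / H, H, H); diag(t1) <- 1 - r + r / H
    outer(seq_len(S), seq_len(S), Vectorize(function(s1, s2) {
      t1[dec[s1, 1], dec[s2, 1]] * t1[dec[s1, 2], dec[s2, 2]]
    }))
  }
  alpha <- matrix(0, S, M); beta <- matrix(0, S, M)
  alpha[, 1] <- em_col(1) / S
  for (j in 2:M) alpha[, j] <- as.vector(t(tmat(rho[j - 1])) %*%
                                           alpha[, j - 1]) * em_col(j)
  beta[, M] <- 1
  for (j in (M - 1):1) beta[, j] <- as.vector(tmat(rho[j]) %*%
                                                (em_col(j + 1) * beta[, j + 1]))
  dos <- numeric(M)
  for (j in seq_len(M)) {
    post <- alpha[, j] * beta[, j]
    post <- post / sum(post)
    mk <- ifelse(ref[dec[, 1], j] == 1, q, eps)
    ml <- ifelse(ref[dec[, 2], j] == 1, q, eps)
    dos[j] <- sum(post * (mk + ml))
  }
  dos
}

# --- VanRaden GRM by explicit double loop -----------------------------------
brute_grm <- function(M, p = colMeans(M) / 2) {
  n <- nrow(M)
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (m in seq_len(ncol(M))) {
        s <- s + (M[i, m] - 2 * p[m]) * (M[j, m] - 2 * p[m])
      }
      G[i, j] <- s / denom
    }
  }
  G
}

# --- reference selection by direct re-implementation ------------------------
brute_select <- function(V, test_ids, cand_ids, k_init, n_target, stride = 1) {
  pool <- length(cand_ids)
  if (pool <= n_target) return(sort(cand_ids))
  k <- k_init
  repeat {
    sel <- character(0)
    for (i in seq_along(test_ids)) {
      df <- data.frame(id = cand_ids, rel = V[i, ], stringsAsFactors = FALSE)
      df <- df[order(-df$rel, df$id), ]
      sel <- union(sel, df$id[seq_len(k)])
    }
    if (length(sel) >= n_target) break
    if (k >= pool) return(sort(cand_ids))
    k <- min(k + stride, pool)
  }
  if (length(sel) > n_target) {
    mr <- vapply(sel, function(s) mean(V[, match(s, cand_ids)]), numeric(1))
    ord <- order(-mr, sel)
    sel <- sel[ord][seq_len(n_target)]
  }
  sort(sel)
}

# --- Hudson Fst estimator from two haplotype samples ------------------------
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# --- textbook Pearson correlation -------------------------------------------
pearson <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    ((n - 1) * sqrt(var(x)) * sqrt(var(y)))
}

# --- GEBV by dense joint-normal conditional mean ----------------------------
# ghat = sg2 G Z' Vinv (y - X bhat_GLS), the conditional mean of g given y.
dense_blup <- function(y, X, Z, G, sg2, se2, extra = list()) {
  V <- sg2 * Z %*% G %*% t(Z) + se2 * diag(length(y))
  for (ex in extra) V <- V + ex$s2 * tcrossprod(ex$Z)
  Vinv <- solve(V)
  b <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% y)
  as.vector(sg2 * G %*% t(Z) %*% Vinv %*% (y - X %*% b))
}

# --- small random diploid toy instances -------------------------------------
rand_ref <- function(H, M, seed) {
  set.seed(seed)
  matrix(rbinom(H * M, 1, 0.5), H, M)
}

# quiet wrapper for runs whose warnings are expected and irrelevant
quietly_ <- function(expr) suppressWarnings(expr)
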