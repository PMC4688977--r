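# Genomic prediction: mixed-model design construction, REML variance
# components (spectral fast path + AI-REML with EM fallback), Henderson's
# mixed-model equations, and GEBV validation statistics.
#
# Model: y = Xb + Zg + Ww + Z1Qq + e, with g ~ N(0, G sg2), w ~ N(0, I sw2),
# q ~ N(0, I sq2), e ~ N(0, I se2).

#' Build the mixed-model design for genomic prediction
#'
#' Fixed effects are birth type, rearing type and gender (class effects,
#' reference-level coding), age and weight (covariates), and contemporary
#' group (flock x birth year x management group). Factors with fewer than
#' two observed levels collapse into the intercept; any remaining aliased
#' columns are dropped to full rank. Z relates phenotyped animals to the
#' genotyped animals carrying additive effects; W relates them to their dams
#' (zero row when the dam is unrecorded); the breed-proportion covariates
#' Z1Q are included only when more than one breed is present.
#'
#' @param phenotypes data.frame from \code{\link{simulate_phenotypes}} (or
#'   with the same columns).
#' @param pedigree pedigree data.frame (for dams and breed proportions).
#' @param geno_ids ids of the genotyped animals that carry additive effects
#'   (order defines the GEBV order); must contain all phenotyped animals.
#' @return list of class \code{ovimp_mm}: y, X, Z, W (or NULL), QZ (or
#'   NULL), ids, geno_ids, dam_ids.
#' @export
build_design <- function(phenotypes, pedigree, geno_ids) {
  ph <- phenotypes
  if (!all(ph$id %in% geno_ids)) {
    bad <- setdiff(ph$id, geno_ids)[1]
    stop_ovimp("phenotyped animal '%s' is not among the genotyped ids", bad)
  }
  n <- nrow(ph)
  df <- data.frame(
    birth_type = factor(ph$birth_type),
    rearing_type = factor(ph$rearing_type),
    gender = factor(ph$gender),
    contemporary_group = factor(ph$contemporary_group),
    age = as.numeric(ph$age), weight = as.numeric(ph$weight))
  keep_factor <- vapply(df, function(v) !is.factor(v) || nlevels(droplevels(v)) > 1,
                        logical(1))
  terms <- names(df)[keep_factor]
  X <- if (length(terms) > 0) {
    model.matrix(stats::reformulate(terms), droplevels(df))
  } else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  Z <- matrix(0, n, length(geno_ids), dimnames = list(ph$id, geno_ids))
  Z[cbind(seq_len(n), match(ph$id, geno_ids))] <- 1

  ped_idx <- match(ph$id, pedigree$id)
  if (anyNA(ped_idx)) {
    stop_ovimp("phenotype row for '%s' cannot be resolved in the pedigree",
               ph$id[which(is.na(ped_idx))[1]])
  }
  dams <- pedigree$dam[ped_idx]
  dam_ids <- sort(unique(dams[!is.na(dams)]))
  W <- NULL
  if (length(dam_ids) > 0) {
    W <- matrix(0, n, length(dam_ids), dimnames = list(ph$id, dam_ids))
    ok <- !is.na(dams)
    W[cbind(which(ok), match(dams[ok], dam_ids))] <- 1
  }

  Q <- breed_composition(pedigree)[ped_idx, , drop = FALSE]
  multi <- vapply(seq_len(ncol(Q)), function(j) var(Q[, j]) > 0, logical(1))
  QZ <- if (sum(colMeans(Q) > 0) > 1 && any(multi)) {
    Q[, colMeans(Q) > 0, drop = FALSE]
  } else NULL

  structure(list(y = as.numeric(ph$y), X = X, Z = Z, W = W, QZ = QZ,
                 ids = ph$id, geno_ids = geno_ids, dam_ids = dam_ids),
            class = "ovimp_mm")
}

# Observation-level covariance structures for the active random terms.
mm_structures <- function(spec, G) {
  stopifnot(inherits(spec, "ovimp_mm"))
  Gm <- as.matrix(G)
  if (is.null(colnames(Gm))) {
    stopifnot(nrow(Gm) == length(spec$geno_ids),
              ncol(Gm) == length(spec$geno_ids))
    dimnames(Gm) <- list(spec$geno_ids, spec$geno_ids)
  } else if (!identical(colnames(Gm), spec$geno_ids)) {
    Gm <- Gm[spec$geno_ids, spec$geno_ids]
  }
  Vs <- list(g = spec$Z %*% Gm %*% t(spec$Z))
  if (!is.null(spec$W)) Vs$w <- tcrossprod(spec$W)
  if (!is.null(spec$QZ)) Vs$q <- tcrossprod(spec$QZ)
  Vs$e <- diag(length(spec$y))
  list(Vs = Vs, G = Gm)
}

reml_loglik <- function(y, X, V) {
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  chx <- chol(XtVX)
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(VinvX, y)))
  Py <- Vinv %*% y - VinvX %*% beta
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P_apply = Py, Vinv = Vinv, VinvX = VinvX,
       XtVX_chol = chx)
}

#' REML estimation of variance components
#'
#' Two-component models (additive + residual) are solved exactly by a
#' spectral profile: the additive covariance is eigendecomposed, the model
#' rotated to independence, and the restricted likelihood maximised over the
#' variance ratio in one dimension. Models with maternal and/or breed
#' components use average-information REML with EM-REML fallback whenever an
#' AI update leaves the parameter space or decreases the restricted
#' likelihood. Convergence: maximum relative component change < 1e-6 (or
#' \code{max_rounds}). Estimates are clamped at 1e-8 x the phenotypic
#' variance and flagged as boundary.
#'
#' @param spec an \code{ovimp_mm} from \code{\link{build_design}}.
#' @param G genomic relationship matrix (\code{ovimp_grm} or matrix) over
#'   \code{spec$geno_ids}.
#' @param method "auto" (spectral when possible), "ai" or "em".
#' @param tol relative-change convergence tolerance.
#' @param max_rounds iteration cap.
#' @return list of class \code{variance_components}: sigma2 (named: g, w, q,
#'   e as present), converged, boundary, loglik, trace.
#' @export
reml_estimate <- function(spec, G, method = c("auto", "ai", "em"),
                          tol = 1e-6, max_rounds = 200) {
  method <- match.arg(method)
  st <- mm_structures(spec, G)
  Vs <- st$Vs
  y <- spec$y; X <- spec$X
  n <- length(y)
  if (n <= ncol(X)) stop_ovimp("more fixed-effect columns than observations")
  vy <- var(y)
  floor_v <- 1e-8 * vy

  if (method == "auto" && length(Vs) == 2) {
    return(reml_spectral(y, X, Vs$g, floor_v))
  }

  k <- length(Vs)
  qs <- c(g = ncol(spec$Z), w = if (!is.null(spec$W)) ncol(spec$W),
          q = if (!is.null(spec$QZ)) ncol(spec$QZ), e = n)[names(Vs)]
  sigma2 <- setNames(rep(vy / k, k), names(Vs))
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE

  build_V <- function(s) Reduce(`+`, Map(`*`, Vs, s))

  for (round in seq_len(max_rounds)) {
    fit <- reml_loglik(y, X, build_V(sigma2))
    Py <- fit$P_apply
    # P %*% v without forming P
    Pmult <- function(v) fit$Vinv %*% v - fit$VinvX %*%
      backsolve(fit$XtVX_chol,
                forwardsolve(t(fit$XtVX_chol), crossprod(fit$VinvX, v)))
    P <- Pmult(diag(n))
    score <- vapply(names(Vs), function(i) {
      -0.5 * (sum(P * Vs[[i]]) - as.numeric(crossprod(Py, Vs[[i]] %*% Py)))
    }, numeric(1))
    U <- vapply(names(Vs), function(i) as.vector(Vs[[i]] %*% Py),
                numeric(n))
    AI <- 0.5 * crossprod(U, P %*% U)

    em_update <- function() {
      sapply(names(Vs), function(i) {
        yPViPy <- as.numeric(crossprod(Py, Vs[[i]] %*% Py))
        sigma2[[i]] + (sigma2[[i]]^2 / qs[[i]]) *
          (yPViPy - sum(P * Vs[[i]]))
      })
    }

    prop <- if (method == "em") em_update() else {
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      cand <- if (is.null(delta)) NULL else sigma2 + as.numeric(delta)
      if (is.null(cand) || any(cand < 0)) em_update() else cand
    }
    prop <- pmax(prop, floor_v)
    ll_new <- reml_loglik(y, X, build_V(prop))$ll
    if (method != "em" && ll_new < fit$ll - 1e-8) {
      prop <- pmax(em_update(), floor_v)
      ll_new <- reml_loglik(y, X, build_V(prop))$ll
    }
    rel <- max(abs(prop - sigma2) / pmax(sigma2, floor_v))
    sigma2 <- setNames(prop, names(Vs))
    trace <- c(trace, ll_new)
    if (rel < tol) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  structure(list(sigma2 = sigma2, converged = converged,
                 boundary = sigma2 <= floor_v * (1 + 1e-6),
                 loglik = trace[length(trace)], trace = trace),
            class = "variance_components")
}

# Exact REML for y = Xb + g + e with g ~ N(0, K sg2): eigendecompose K,
# rotate, profile the restricted likelihood over lambda = sg2/se2.
reml_spectral <- function(y, X, K, floor_v) {
  n <- length(y)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  p <- ncol(X)
  nll <- function(loglambda) {
    lam <- exp(loglambda)
    wts <- 1 / (1 + lam * d)
    XtWX <- crossprod(Xt, wts * Xt)
    chx <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(chx)) return(1e10)
    beta <- backsolve(chx, forwardsolve(t(chx), crossprod(Xt, wts * yt)))
    r <- yt - Xt %*% beta
    rss <- sum(wts * r^2)
    se2 <- rss / (n - p)
    0.5 * ((n - p) * log(se2) + sum(log(1 + lam * d)) +
             2 * sum(log(diag(chx))) + (n - p))
  }
  opt <- optimize(nll, interval = c(-25, 25))
  lam <- exp(opt$minimum)
  wts <- 1 / (1 + lam * d)
  XtWX <- crossprod(Xt, wts * Xt)
  beta <- solve(XtWX, crossprod(Xt, wts * yt))
  rss <- sum(wts * (yt - Xt %*% beta)^2)
  se2 <- max(rss / (n - p), floor_v)
  sg2 <- max(lam * se2, floor_v)
  structure(list(sigma2 = c(g = sg2, e = se2), converged = TRUE,
                 boundary = c(g = sg2 <= floor_v * (1 + 1e-6),
                              e = se2 <= floor_v * (1 + 1e-6)),
                 loglik = -opt$objective - 0.5 * (n - p) * log(2 * pi),
                 trace = -opt$objective),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("REML variance components",
      if (!x$converged) "(NOT converged)" else "", "\n")
  for (i in names(x$sigma2)) {
    cat(sprintf("  sigma2_%s = %.5f%s\n", i, x$sigma2[[i]],
                if (x$boundary[[i]]) " [boundary]" else ""))
  }
  invisible(x)
}

#' Solve Henderson's mixed-model equations
#'
#' Joint solutions for fixed effects and all random effects at the given
#' variance components; the additive solutions are the GEBVs. Components at
#' the boundary drop their term from the equations.
#'
#' @param spec an \code{ovimp_mm}.
#' @param components a \code{variance_components}.
#' @param G genomic relationship matrix over \code{spec$geno_ids}.
#' @param ridge diagonal ridge added to G before inversion.
#' @return list of class \code{gebv_table}: gebv data.frame (id, gebv),
#'   fixed (named vector), maternal, breed.
#' @export
solve_mme <- function(spec, components, G, ridge = 1e-8) {
  stopifnot(inherits(spec, "ovimp_mm"),
            inherits(components, "variance_components"))
  st <- mm_structures(spec, G)
  Gm <- st$G
  s2 <- components$sigma2
  se2 <- s2[["e"]]
  use_w <- !is.null(spec$W) && "w" %in% names(s2) && !components$boundary[["w"]]
  use_q <- !is.null(spec$QZ) && "q" %in% names(s2) && !components$boundary[["q"]]
  if (components$boundary[["g"]]) {
    warning("additive variance at boundary; GEBVs fully shrunken")
  }

  X <- spec$X; Z <- spec$Z; y <- spec$y
  blocks <- list(X = X, Z = Z)
  if (use_w) blocks$W <- spec$W
  if (use_q) blocks$Q <- spec$QZ
  Big <- do.call(cbind, blocks)
  C <- crossprod(Big)
  rhs <- crossprod(Big, y)

  ix <- seq_len(ncol(X))
  iz <- ncol(X) + seq_len(ncol(Z))
  Ginv <- tryCatch(solve(Gm), error = function(e) NULL)
  if (is.null(Ginv)) {
    Ginv <- tryCatch(solve(Gm + diag(ridge, nrow(Gm))), error = function(e)
      stop_ovimp("G is singular even after ridge"))
  }
  C[iz, iz] <- C[iz, iz] + Ginv * (se2 / s2[["g"]])
  off <- ncol(X) + ncol(Z)
  if (use_w) {
    iw <- off + seq_len(ncol(spec$W)); off <- off + ncol(spec$W)
    C[iw, iw] <- C[iw, iw] + diag(ncol(spec$W)) * (se2 / s2[["w"]])
  }
  if (use_q) {
    iq <- off + seq_len(ncol(spec$QZ))
    C[iq, iq] <- C[iq, iq] + diag(ncol(spec$QZ)) * (se2 / s2[["q"]])
  }
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop_ovimp("singular MME coefficient matrix (rank %d of %d)",
               qr(C)$rank, ncol(C)))
  sol <- as.numeric(sol)
  out <- list(gebv = data.frame(id = spec$geno_ids, gebv = sol[iz],
                                stringsAsFactors = FALSE),
              fixed = setNames(sol[ix], colnames(X)),
              maternal = if (use_w)
                setNames(sol[ncol(X) + ncol(Z) + seq_len(ncol(spec$W))],
                         colnames(spec$W)) else NULL,
              breed = if (use_q)
                setNames(sol[length(sol) - ncol(spec$QZ) + seq_len(ncol(spec$QZ))],
                         colnames(spec$QZ)) else NULL)
  structure(out, class = "gebv_table")
}

#' @export
print.gebv_table <- function(x, ...) {
  cat(sprintf("GEBV table: %d animals, gebv sd %.4f\n",
              nrow(x$gebv), sd(x$gebv$gebv)))
  invisible(x)
}

#' GEBV validation accuracy
#'
#' Pearson correlation between GEBVs and accurate (progeny-test) breeding
#' values over the validation animals present in both tables.
#'
#' @param gebv a \code{gebv_table} (or data.frame with id, gebv).
#' @param validation_ebvs data.frame with id and reported_ebv.
#' @return Pearson r with the intersection size as attribute \code{"n"}.
#' @export
gebv_accuracy <- function(gebv, validation_ebvs) {
  gt <- if (inherits(gebv, "gebv_table")) gebv$gebv else gebv
  common <- intersect(gt$id, validation_ebvs$id)
  if (length(common) == 0) stop_ovimp("no overlap between GEBV and validation ids")
  if (length(common) < 3) stop_ovimp("need >= 3 validation animals, got %d",
                                     length(common))
  r <- cor(gt$gebv[match(common, gt$id)],
           validation_ebvs$reported_ebv[match(common, validation_ebvs$id)])
  attr(r, "n") <- length(common)
  r
}

#' Correlation between two GRMs or two GEBV tables
#'
#' For relationship matrices, the Pearson correlation over the vectorised
#' upper triangle including the diagonal; for GEBV tables, over the aligned
#' GEBV vectors. The id sets must match.
#'
#' @param A,B two \code{ovimp_grm}s or two \code{gebv_table}s.
#' @return Pearson r.
#' @export
matrix_correlation <- function(A, B) {
  if (inherits(A, "ovimp_grm") && inherits(B, "ovimp_grm")) {
    if (!identical(A$ids, B$ids)) stop_ovimp("GRM id sets differ")
    ut <- upper.tri(A$values, diag = TRUE)
    return(cor(A$values[ut], B$values[ut]))
  }
  if (inherits(A, "gebv_table") && inherits(B, "gebv_table")) {
    if (!identical(A$gebv$id, B$gebv$id)) stop_ovimp("GEBV id sets differ")
    return(cor(A$gebv$gebv, B$gebv$gebv))
  }
  stop_ovimp("A and B must both be GRMs or both GEBV tables")
}
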