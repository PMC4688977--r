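# Scenario orchestration: desk-scale analogue of the imputation study grid
# (test-set composition x reference composition/size x random vs selected
# reference), plus the genomic-prediction comparison across genotype sources.

#' Simulate the standard study population bundle
#'
#' A desk-scale analogue of a multi-breed resource flock: purebred Merinos
#' with half-sib families in AI-connected flocks, three F1 cross types
#' (Border Leicester, Poll Dorset and White Suffolk sires over Merino ewes),
#' non-Merino purebreds, a nested low/medium-density panel pair, phenotypes
#' on the purebred Merino progeny, and progeny-test EBVs for the Merino
#' validation sires. Default sizes are roughly one tenth of a
#' 20k-animal resource flock's scenario grid so a full grid runs in minutes;
#' larger designs remain valid configuration.
#'
#' @param seed integer seed.
#' @param breed_mod a \code{\link{breed_model}}.
#' @param snp_map a marker map (default: 2 chromosomes x 250 markers,
#'   100 cM each, every 4th marker on the low-density panel).
#' @param design a \code{\link{mating_design}}.
#' @param trait a \code{\link{trait_model}}.
#' @param ebv_accuracy accuracy spec for validation-sire EBVs.
#' @return list of class \code{ovimp_bundle}: pop, phenotypes, true_bv,
#'   validation_ebvs, groups (id vectors per composition), snp_map.
#' @export
simulate_study_population <- function(seed = 1,
                                      breed_mod = breed_model(),
                                      snp_map = make_snp_map(),
                                      design = mating_design(),
                                      trait = trait_model(var_maternal = 0.05,
                                                          var_residual = 0.65),
                                      ebv_accuracy = list(min = 0.70,
                                                          mean = 0.88,
                                                          max = 0.99)) {
  pop <- simulate_population(breed_mod, snp_map, design, seed)
  ped <- pop$pedigree
  mer <- design$merino_label

  groups <- list(
    merino_pure = ped$id[ped$group == sprintf("pure_%s", mer)],
    nonmerino_pure = ped$id[ped$group %in%
      paste0("pure_", setdiff(names(design$n_founders), mer)) |
      (ped$group == "founder" & ped[[paste0("prop_", mer)]] == 0)]
  )
  for (b in names(design$f1_progeny)) {
    groups[[tolower(sprintf("%sxm", abbreviate(b, 2)))]] <-
      ped$id[ped$group == sprintf("f1_%s", b)]
  }
  cross_groups <- setdiff(names(groups), c("merino_pure", "nonmerino_pure"))
  groups$mixed_crossbred <- unlist(groups[cross_groups], use.names = FALSE)

  phen <- simulate_phenotypes(pop, trait, ids = groups$merino_pure,
                              seed = seed)
  # validation sires: Merino founder males actually used as sires
  mer_prog <- ped[ped$group == sprintf("pure_%s", mer), ]
  sires <- sort(unique(mer_prog$sire))
  ebvs <- simulate_progeny_test_ebv(phen$true_bv[sires], ebv_accuracy,
                                    seed = seed)

  structure(list(pop = pop, phenotypes = phen$phenotypes,
                 true_bv = phen$true_bv, qtl = phen$qtl,
                 validation_ebvs = ebvs, validation_sires = sires,
                 groups = groups, snp_map = snp_map),
            class = "ovimp_bundle")
}

#' @export
print.ovimp_bundle <- function(x, ...) {
  cat("study population bundle\n")
  print(x$pop)
  cat(sprintf("  phenotyped: %d; validation sires: %d\n",
              nrow(x$phenotypes), length(x$validation_sires)))
  invisible(x)
}

#' Scenario configuration
#'
#' @param test_composition group label for the test set (one of the bundle's
#'   groups, e.g. "merino_pure", "mixed_crossbred", "blxm").
#' @param n_test test-set size.
#' @param ref_composition group label for the candidate reference pool; for
#'   \code{ref_type = "selected"} the pool is every non-test animal (the
#'   whole flock).
#' @param n_ref reference size ("all" uses the entire pool).
#' @param ref_type "random" or "selected" (relatedness-based selection on the
#'   low-density cross-GRM).
#' @param params an \code{\link{ls_params}}.
#' @param seed integer seed for this scenario's sampling and phasing.
#' @return list of class \code{scenario_config}.
#' @export
scenario_config <- function(test_composition, n_test,
                            ref_composition = test_composition,
                            n_ref = 100, ref_type = c("random", "selected"),
                            params = ls_params(), seed = 1) {
  ref_type <- match.arg(ref_type)
  structure(list(test_composition = test_composition, n_test = n_test,
                 ref_composition = ref_composition, n_ref = n_ref,
                 ref_type = ref_type, params = params, seed = seed),
            class = "scenario_config")
}

sample_ids <- function(pool, n, seed, tag) {
  if (length(pool) < n) {
    stop_ovimp("requested %d animals but pool has only %d", n, length(pool))
  }
  with_substream(seed, tag, sort(sample(pool, n)))
}

#' Run one imputation scenario end to end
#'
#' Samples the test set, masks it to the low-density panel, forms the
#' reference set (random from the configured pool, or selected from all
#' non-test animals by genomic relatedness on the shared low-density
#' genotypes), phases the reference, imputes the test set and scores
#' per-individual and per-SNP accuracy against the withheld genotypes.
#' Rerunning with the same configuration is bit-identical.
#'
#' @param bundle an \code{ovimp_bundle}.
#' @param config a \code{\link{scenario_config}}.
#' @return list of class \code{scenario_report}.
#' @export
run_scenario <- function(bundle, config) {
  stopifnot(inherits(bundle, "ovimp_bundle"),
            inherits(config, "scenario_config"))
  pop <- bundle$pop
  map <- bundle$snp_map
  seed <- config$seed

  test_pool <- bundle$groups[[config$test_composition]]
  if (is.null(test_pool)) {
    stop_ovimp("unknown test composition '%s'", config$test_composition)
  }
  # feasibility checks before any compute
  test_ids <- sample_ids(test_pool, config$n_test, seed, "test")
  if (config$ref_type == "random") {
    ref_pool <- setdiff(bundle$groups[[config$ref_composition]], test_ids)
    if (is.null(bundle$groups[[config$ref_composition]])) {
      stop_ovimp("unknown reference composition '%s'", config$ref_composition)
    }
    n_ref <- if (identical(config$n_ref, "all")) length(ref_pool) else config$n_ref
    ref_ids <- sample_ids(ref_pool, n_ref, seed, "ref")
  } else {
    ref_pool <- setdiff(rownames(pop$genotypes), test_ids)
    n_ref <- if (identical(config$n_ref, "all")) length(ref_pool) else config$n_ref
    low <- mask_to_low_density(pop$genotypes, map)
    cg <- compute_cross_grm(low$genotypes[test_ids, , drop = FALSE],
                            low$genotypes[ref_pool, , drop = FALSE])
    ref_ids <- as.character(select_reference(cg, k_init = 20,
                                             n_target = n_ref))
  }

  low <- mask_to_low_density(pop$genotypes[test_ids, , drop = FALSE], map)
  res <- impute_set(low$genotypes,
                    pop$genotypes[ref_ids, , drop = FALSE],
                    map, config$params, seed = substream_seed(seed, "impute"))
  acc <- imputation_accuracy(pop$genotypes[test_ids, , drop = FALSE], res,
                             mask = low$mask)
  cfg_json <- jsonlite::toJSON(config[c("test_composition", "n_test",
                                        "ref_composition", "n_ref",
                                        "ref_type", "seed")],
                               auto_unbox = TRUE)
  structure(list(config = config,
                 config_hash = sprintf("%08x",
                                       sum(utf8ToInt(cfg_json) *
                                             seq_along(utf8ToInt(cfg_json))) %%
                                         4294967291),
                 seed = seed, test_ids = test_ids, ref_ids = ref_ids,
                 accuracy = acc, imputation = res),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario %s (n=%d) <- %s %s (n=%d), seed %d\n",
              x$config$test_composition, x$config$n_test, x$config$ref_type,
              x$config$ref_composition, length(x$ref_ids), x$seed))
  print(x$accuracy)
  invisible(x)
}

#' Genomic-prediction comparison across genotype sources
#'
#' Fits the GBLUP mixed model to the bundle's phenotypes using relationship
#' matrices from different genotype sources for the prediction reference
#' animals (observed medium-density, imputed dosages of varying accuracy,
#' observed low-density), with the validation sires carried at their
#' observed genotypes, and scores each source by the correlation between the
#' sires' GEBVs and their progeny-test EBVs.
#'
#' @param bundle an \code{ovimp_bundle}.
#' @param sources named list; each element is either the character
#'   \code{"observed_50k"} / \code{"observed_12k"} or an
#'   \code{ovimp_imputation} over the phenotyped animals.
#' @param pheno_ids optional subset of phenotyped animals to use as the
#'   prediction reference population (default: all phenotyped animals).
#' @return list with \code{table} (source, gebv_accuracy, mean_imputation_r),
#'   \code{gebv_tables}, \code{grms}, and pairwise correlation matrices
#'   \code{gebv_cor} / \code{grm_cor}.
#' @export
run_prediction_comparison <- function(bundle, sources, pheno_ids = NULL) {
  pop <- bundle$pop
  map <- bundle$snp_map
  phen <- bundle$phenotypes
  if (!is.null(pheno_ids)) {
    stopifnot(all(pheno_ids %in% phen$id))
    phen <- phen[phen$id %in% pheno_ids, , drop = FALSE]
  }
  pheno_ids <- phen$id
  sires <- bundle$validation_sires
  geno_ids <- c(pheno_ids, setdiff(sires, pheno_ids))
  low_cols <- map$panel == "both"

  source_matrix <- function(src) {
    if (identical(src, "observed_50k")) {
      list(M = pop$genotypes[geno_ids, , drop = FALSE], mean_r = NA_real_)
    } else if (identical(src, "observed_12k")) {
      list(M = pop$genotypes[geno_ids, low_cols, drop = FALSE],
           mean_r = NA_real_)
    } else if (inherits(src, "ovimp_imputation")) {
      if (!all(pheno_ids %in% rownames(src$dosage))) {
        stop_ovimp("imputation source must cover all phenotyped animals")
      }
      M <- pop$genotypes[geno_ids, , drop = FALSE]
      M[pheno_ids, ] <- src$dosage[pheno_ids, , drop = FALSE]
      acc <- imputation_accuracy(pop$genotypes[pheno_ids, , drop = FALSE],
                                 structure(list(
                                   dosage = src$dosage[pheno_ids, , drop = FALSE],
                                   best_guess = src$best_guess[pheno_ids, , drop = FALSE],
                                   observed_mask = src$observed_mask[pheno_ids, , drop = FALSE],
                                   maxpost = src$maxpost[pheno_ids, , drop = FALSE],
                                   snp_map = map), class = "ovimp_imputation"))
      list(M = M, mean_r = acc$summary$individual$mean)
    } else stop_ovimp("unknown genotype source")
  }

  spec <- build_design(phen, pop$pedigree, geno_ids)
  rows <- list(); gebvs <- list(); grms <- list()
  for (nm in names(sources)) {
    sm <- source_matrix(sources[[nm]])
    grm <- compute_grm(sm$M)
    vc <- reml_estimate(spec, grm)
    gt <- solve_mme(spec, vc, grm)
    r <- gebv_accuracy(gt, bundle$validation_ebvs)
    rows[[nm]] <- data.frame(source = nm, gebv_accuracy = as.numeric(r),
                             n_validation = attr(r, "n"),
                             mean_imputation_r = sm$mean_r,
                             sigma2_g = vc$sigma2[["g"]],
                             sigma2_e = vc$sigma2[["e"]],
                             stringsAsFactors = FALSE)
    gebvs[[nm]] <- gt; grms[[nm]] <- grm
  }
  k <- length(gebvs)
  gc_ <- matrix(NA_real_, k, k, dimnames = list(names(gebvs), names(gebvs)))
  rc_ <- gc_
  for (i in seq_len(k)) for (j in seq_len(k)) {
    gc_[i, j] <- matrix_correlation(gebvs[[i]], gebvs[[j]])
    rc_[i, j] <- matrix_correlation(grms[[i]], grms[[j]])
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       gebv_tables = gebvs, grms = grms, gebv_cor = gc_, grm_cor = rc_)
}

#' Write consolidated scenario reports
#'
#' Emits a per-scenario summary table, per-scenario histogram bins of the
#' individual accuracies (fixed width 0.02), and a JSON run record carrying
#' every summary, config hash and seed.
#'
#' @param reports list of \code{scenario_report}s.
#' @param dir output directory (created if needed).
#' @param prediction optional result of
#'   \code{\link{run_prediction_comparison}} to include as a
#'   Table-1-style grid.
#' @return invisibly, the summary data.frame.
#' @export
write_report <- function(reports, dir, prediction = NULL) {
  if (length(reports) == 0) stop_ovimp("no run reports to write")
  stopifnot(all(vapply(reports, inherits, logical(1), "scenario_report")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- do.call(rbind, lapply(reports, function(r) {
    s <- r$accuracy$summary$individual
    data.frame(test = r$config$test_composition, n_test = r$config$n_test,
               ref = r$config$ref_composition, ref_type = r$config$ref_type,
               n_ref = length(r$ref_ids), seed = r$seed,
               config_hash = r$config_hash,
               mean_r = s$mean, sd_r = s$sd, min_r = s$min, max_r = s$max,
               n_undefined = s$n_undefined, stringsAsFactors = FALSE)
  }))
  write.table(summ, file.path(dir, "scenario_summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  hist_tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    s <- reports[[i]]$accuracy$summary$individual
    data.frame(scenario = i, bin_low = s$hist_breaks[-length(s$hist_breaks)],
               bin_high = s$hist_breaks[-1], count = s$hist_counts)
  }))
  write.table(hist_tab, file.path(dir, "accuracy_histograms.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  rec <- list(scenarios = lapply(reports, function(r) list(
    config_hash = r$config_hash, seed = r$seed,
    summary = r$accuracy$summary$individual[
      c("n", "n_undefined", "mean", "sd", "min", "max")])))
  if (!is.null(prediction)) {
    write.table(prediction$table, file.path(dir, "gebv_accuracy.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    rec$prediction <- list(table = prediction$table,
                           gebv_cor = prediction$gebv_cor,
                           grm_cor = prediction$grm_cor)
  }
  jsonlite::write_json(rec, file.path(dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}
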