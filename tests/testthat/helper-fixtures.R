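# Programmatic fixtures: the planted-violation QC panel and a small study
# population bundle shared across pipeline tests.

# 12-marker panel with one planted violation of each QC rule, n = 80 samples.
# Clean markers give each sample a unique (marker-triple, allele-combo)
# pattern so no sample pair is spuriously correlated; sample 80 is then made
# a genotype-duplicate of sample 1 on the clean markers.
#
# Planted violations (thresholds: defaults with het_sd_limit = 2):
#   m07 call rate 70/80 < 0.9                   -> call_rate
#   m08 10 cells with GC < 0.6 -> call rate     -> call_rate (via GC masking)
#   m09 heterozygosity 0.9, > 2 SD above mean   -> heterozygosity
#   m10 MAF 1/160 < 0.01                        -> maf
#   m11 on chromosome X                         -> chromosome
#   m12 no heterozygotes, HWE chi2 = 80         -> hwe
# Survivors: m01-m06 and 79 samples (s80 dropped as duplicate of s01).
build_qc_fixture <- function() {
  n <- 80
  clean <- matrix(0L, n, 6)
  triples <- utils::combn(6, 3)          # 20 triples
  combos <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1), c(1, 1, 2))
  s <- 0
  for (tr in seq_len(ncol(triples))) {
    for (cb in seq_len(nrow(combos))) {
      s <- s + 1
      clean[s, triples[, tr]] <- combos[cb, ]
    }
  }
  stopifnot(s == n)
  clean[n, ] <- clean[1, ]               # planted duplicate pair (s01, s80)

  m07 <- rep(c(0L, 1L, 0L, 2L), 20)     # content irrelevant: removed by call rate
  m07[seq_len(10)] <- NA
  m08 <- rep(c(0L, 1L, 1L, 0L), 20)     # masked via GC at 10 cells
  m09 <- c(rep(1L, 72), rep(0L, 4), rep(2L, 4))          # het 0.9
  m10 <- c(rep(0L, 4), 1L, rep(0L, n - 5))               # MAF 1/160
  m11 <- rep(c(0L, 1L, 0L, 0L, 1L), 16)                  # clean but on X
  m12 <- c(rep(0L, 56), rep(2L, 24))                     # (56, 0, 24): chi2 = 80

  G <- cbind(clean, m07, m08, m09, m10, m11, m12)
  colnames(G) <- sprintf("m%02d", 1:12)
  rownames(G) <- sprintf("s%02d", seq_len(n))
  map <- data.frame(snp_id = colnames(G),
                    chrom = c(rep("1", 10), "X", "1"),
                    pos_bp = seq_len(12) * 1000,
                    pos_cm = seq_len(12) * 0.001,
                    panel = c(rep("both", 4), rep("50k_only", 8)),
                    stringsAsFactors = FALSE)
  gc <- matrix(1, n, 12, dimnames = dimnames(G))
  gc[seq_len(10), "m08"] <- 0.3
  list(genotypes = G, snp_map = map, gc_scores = gc,
       thresholds = qc_thresholds(het_sd_limit = 2,
                                  excluded_chromosomes = "X"),
       expected = list(
         call_rate = c("m07", "m08"), heterozygosity = "m09",
         maf = "m10", chromosome = "m11", hwe = "m12",
         survivors = sprintf("m%02d", 1:6),
         dropped_sample = "s80"))
}

# Small study bundle for pipeline-level tests (cheaper than the default).
toy_design <- function() {
  mating_design(
    n_founders = c(Merino = 40, BorderLeicester = 16, PollDorset = 16,
                   WhiteSuffolk = 16),
    n_flocks = 3, sires_per_flock = 5, progeny_per_sire = 10,
    purebred_progeny = c(Merino = 130, BorderLeicester = 16,
                         PollDorset = 16, WhiteSuffolk = 16),
    f1_progeny = c(BorderLeicester = 40, PollDorset = 40, WhiteSuffolk = 40))
}

toy_bundle_cache <- new.env(parent = emptyenv())

toy_bundle <- function(seed = 11) {
  key <- paste0("b", seed)
  if (is.null(toy_bundle_cache[[key]])) {
    toy_bundle_cache[[key]] <- simulate_study_population(
      seed = seed,
      snp_map = make_snp_map(n_chr = 2, markers_per_chr = 120,
                             chr_length_cm = 100, low_density_every = 4),
      design = toy_design())
  }
  toy_bundle_cache[[key]]
}

fast_params <- function(...) {
  ls_params(n_iterations = 4, phase_states = 30, max_states = 60, ...)
}

# deterministic subsample of an id pool
sample_pool <- function(pool, n, seed) {
  set.seed(seed)
  sort(sample(pool, n))
}

# wrap a raw relationship block as a cross-GRM object
make_cross <- function(V, test_ids, cand_ids) {
  structure(list(test_ids = test_ids, candidate_ids = cand_ids,
                 values = V, allele_freqs_used = NULL,
                 scaling_denominator = 1), class = "ovimp_cross_grm")
}

# minimal single-breed pedigree for mixed-model tests
toy_ped <- function(ids, dam = NA_character_) {
  data.frame(id = ids, sire = NA_character_, dam = dam, sex = "F",
             flock = 1, birth_year = 2001, group = "x",
             prop_Merino = 1, stringsAsFactors = FALSE)
}
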