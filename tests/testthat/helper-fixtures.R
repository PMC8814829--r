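# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# The six enrichment magnitudes reported for the strongly exosome-enriched
# miRNAs, used as planted effect sizes throughout.
ENRICHMENT_FOLDS <- c(1467.35, 30.06, 25.43, 13.95, 13.94, 13.58)

# Full-depth two-condition study: 40 hairpins, 10 UTRs, 3 vs 3 replicates
# at 1e5 reads each, six planted enrichment folds, default junk classes.
e2e_fixture <- function() {
  if (!is.null(.fixtures$e2e)) return(.fixtures$e2e)
  ref <- make_reference(40, 10, seed = 2024)
  fold <- setNames(ENRICHMENT_FOLDS, ref$matures$name[1:6])
  truth <- make_truth(ref, fold = fold, depth = 1e5, seed = 2024)
  dir <- file.path(tempdir(), "exomir-e2e")
  sim <- simulate_libraries(ref, truth, dir)
  .fixtures$e2e <- list(ref = ref, truth = truth, sim = sim)
  .fixtures$e2e
}

# Cleaned libraries + count matrix for the e2e fixture.
e2e_counts_fixture <- function() {
  if (!is.null(.fixtures$e2e_counts)) return(.fixtures$e2e_counts)
  fx <- e2e_fixture()
  qc <- lapply(seq_len(nrow(fx$sim$manifest)), function(i) {
    clean_library(fx$sim$manifest$path[i], fx$truth$adapter,
                  fx$ref$contaminants)
  })
  names(qc) <- paste0(fx$sim$manifest$condition, "_",
                      fx$sim$manifest$replicate)
  alns <- lapply(qc, function(x) align_reads(x$reads, fx$ref))
  counts <- count_mature(alns, fx$ref)
  .fixtures$e2e_counts <- list(qc = qc, alignments = alns, counts = counts)
  .fixtures$e2e_counts
}

# Small, fast simulation for property-style QC tests.
small_sim_fixture <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  ref <- make_reference(12, 4, seed = 77)
  truth <- make_truth(ref, depth = 5000, seed = 77)
  dir <- file.path(tempdir(), "exomir-small")
  sim <- simulate_libraries(ref, truth, dir)
  .fixtures$small <- list(ref = ref, truth = truth, sim = sim)
  .fixtures$small
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic random sequence independent of the ambient RNG state
random_seq_fixed <- function(n, seed) {
  state <- .Random.seed
  on.exit(.Random.seed <<- state)
  set.seed(seed)
  random_seq(n)
}

# planted class encoded in simulated read ids ("cond-rep:serial:class[:which]")
planted_class <- function(ids) {
  vapply(strsplit(ids, ":", fixed = TRUE), `[`, "", 3)
}

planted_junk_kind <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  vapply(parts, function(p) if (p[3] == "junk") p[4] else NA_character_, "")
}
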