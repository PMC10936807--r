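# simulations shared across test files, built once per session

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# the benchmark world: ~8 Mb diploid genome at human-like het SNV density
# (1/1500 bp), MinION-like read law (25 kb +/- 20 kb, accuracy 0.98,
# sub:ins:del 23:31:46), depth chosen to yield >= 2000 phaseable reads
acceptance_sim <- function() cached("acc", {
  cfg <- sim_config(genome_length = 8e6, het_snv_rate = 1 / 1500, depth = 4,
                    seed = 1)
  simulate_diploid_dataset(cfg, file.path(tempdir(), "haplotagr-acc-sim"))
})

acceptance_run <- function() cached("acc_run", {
  sim <- acceptance_sim()
  res <- haplotag_bam(sim$bam, sim$store, fdr = 0, llr_threshold = 0)
  ev <- evaluate_tagging(res$decisions, sim$truth, sim$store)
  list(sim = sim, res = res, ev = ev)
})

# a deliberately harsher world (short, error-rich reads) that produces
# enough wrong haplotags for rank-based tests to have power
stress_run <- function() cached("stress", {
  cfg <- sim_config(genome_length = 1e6, het_snv_rate = 1 / 1500, depth = 4,
                    length_mean = 3000, length_sd = 2000,
                    accuracy_mean = 0.78, accuracy_sd = 0.04, seed = 99)
  sim <- simulate_diploid_dataset(cfg, file.path(tempdir(), "haplotagr-stress-sim"))
  res <- haplotag_bam(sim$bam, sim$store, fdr = 0, llr_threshold = 0)
  ev <- evaluate_tagging(res$decisions, sim$truth, sim$store)
  list(sim = sim, res = res, ev = ev)
})

# small generic dataset for engine-level tests
small_sim <- function() cached("small", {
  cfg <- sim_config(genome_length = 6e5, het_snv_rate = 1 / 1500, depth = 4,
                    seed = 11)
  simulate_diploid_dataset(cfg, file.path(tempdir(), "haplotagr-small-sim"))
})
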