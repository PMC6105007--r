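# Shared fixtures, built once per test session. Everything is
# generated in code under tempdir(); nothing is stored in the
# repository.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the standard 24-cell experiment with UMI errors, no barcode errors
fx_sim <- function() {
  fixture("sim", function() {
    simulate_experiment(file.path(tempdir(), "fx_exp"), seed = 42L)
  })
}

# a complete pipeline run over fx_sim()
fx_run <- function() {
  fixture("run", function() {
    sim <- fx_sim()
    cfg <- pipeline_config(
      out_dir = file.path(tempdir(), "fx_run"),
      bam = sim$bam, r1 = sim$r1, r2 = sim$r2,
      annotation = sim$gtf, whitelist = sim$whitelist,
      structure = sim$structure, comp = 1L, seed = 7L)
    res <- suppressMessages(run_pipeline(cfg))
    res$out_dir <- cfg$out_dir
    res
  })
}

# 2,000 alignments with a prescribed status mixture
fx_aln <- function() {
  fixture("aln", function() {
    simulate_alignments(file.path(tempdir(), "fx_aln"),
                        n_reads = 2000L, seed = 11L)
  })
}

# 96-cell experiment with one barcode error in a third of the reads
fx_demux <- function() {
  fixture("demux", function() {
    simulate_experiment(
      file.path(tempdir(), "fx_demux"),
      n_cells = 96L, n_genes = 5L, n_ercc = 4L,
      barcode_len = 10L, lambda = 1.3, lambda_ercc = 0.3,
      bc_error_frac = 0.3, seed = 19L)
  })
}
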