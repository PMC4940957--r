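# Shared synthetic fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

tiny_cfg <- function() synth_config(n_coding = 16L, n_noncoding = 16L,
                                    length_range = c(300L, 900L), seed = 5L)

tiny_set <- function() fixture("tiny_set", function() {
  cfg <- tiny_cfg()
  g <- gen_transcripts(cfg)
  list(cfg = cfg, transcripts = g$transcripts, truth = g$truth,
       dbs = gen_peptide_dbs(g$transcripts, g$truth, cfg),
       genome = gen_genome(g$transcripts, cfg))
})
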