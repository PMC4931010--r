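# Shared small simulation configurations. The short fragment range (15-70 nt
# at read length 100) guarantees the linker of every chimeric insert is
# sequenced by at least one mate, so category recovery is information-
# theoretically possible; the general default range (15-300) is exercised in
# the end-to-end regression where unparseable chimeras only reduce yield.
small_cfg <- function(seed = 7, n_read_pairs = 1000, error_rate = 0,
                      duplicate_rate = 0, n_structure_genes = 0, ...) {
  sim_config(seed = seed, n_read_pairs = n_read_pairs,
             error_rate = error_rate, duplicate_rate = duplicate_rate,
             frag_len = list(meanlog = log(40), sdlog = 0.4,
                             min = 15L, max = 70L),
             n_structure_genes = n_structure_genes, ...)
}

# cache references across tests within one run
.ref_cache <- new.env()
cached_reference <- function(cfg, key) {
  if (is.null(.ref_cache[[key]])) .ref_cache[[key]] <- make_reference(cfg)
  .ref_cache[[key]]
}
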