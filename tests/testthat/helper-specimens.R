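# Builders used across test files.

make_specimen <- function(id, glu, phe, ..., extra_d15N = NULL) {
  d15N <- c(Glu = glu, Phe = phe, extra_d15N)
  specimen(id, profile = aa_profile(d15N = d15N), ...)
}

# A three-level marine chain with an avian top step and no noise. The
# plankton regime spans exactly TP 1 -> 2, which is the domain on which
# the multi-TDF estimator is the exact inverse of the generator.
noiseless_bird_chain <- function(n_per_level = 1, seed = 1L) {
  food_chain_config(
    levels = data.frame(name = c("producer", "zooplankton", "bird"),
                        tp_true = c(1, 2, 3.4),
                        tdf_type = c(NA, "plankton", "bird"),
                        stringsAsFactors = FALSE),
    noise_sd_aa = 0, noise_sd_bulk = 0,
    n_per_level = n_per_level, seed = seed)
}

fish_fixture <- function() load_specimens(csia_fixture("table1_fish"))
bird_fixture <- function() load_specimens(csia_fixture("table2_birds"))
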