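.datatable.aware <- TRUE

# quiet R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  "sample_id", "N", "gene", "v_identity", "j_identity", "v_call", "j_call",
  "junction_aa", "n_sequences", ".", "..prop_cols"
))
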