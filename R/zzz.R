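# let data.table's [ syntax work without importing the whole namespace
.datatable.aware <- TRUE

# non-standard-evaluation symbols used inside data.table expressions
utils::globalVariables(c(".", ".N", "cluster_id", "x", "y", "w", "t"))
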