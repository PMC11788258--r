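# Minimal-overhead tibble constructor for hot paths: columns are assumed
# valid, equal-length vectors.
fast_tbl <- function(cols) {
  n <- length(cols[[1]])
  structure(cols, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(n))
}
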