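# Shared builders for small in-code fixtures.

# Study-style metadata: n_ctrl control replicates + one replicate per
# treatment level at every time point.
make_md <- function(times = c(24, 30, 36, 42, 48, 54, 60, 72, 84, 96),
                    levels = "C_medium", n_ctrl = 2L,
                    scenario = "late") {
  md <- do.call(rbind, lapply(times, function(t) {
    lev <- c(rep("control", n_ctrl), levels)
    data.frame(time_hpf = t, concentration_level = lev,
               replicate = c(seq_len(n_ctrl), rep(1L, length(levels))),
               stringsAsFactors = FALSE)
  }))
  md$exposure_start <- scenario
  md$sample_id <- sprintf("s%02d", seq_len(nrow(md)))
  md[, c("sample_id", "time_hpf", "concentration_level",
         "exposure_start", "replicate")]
}

# Difference band with prescribed constant (or vector) bounds.
const_band <- function(grid, lo, hi, gene_id = "g1", level = "C_medium") {
  auci:::make_band(grid, rep_len(lo, length(grid)), rep_len(hi, length(grid)),
                   gene_id = gene_id, level = level)
}

# Plain numeric matrix from an expr_matrix (drops the class/scale tag).
vals_of <- function(x) {
  out <- unclass(x)
  attr(out, "scale_tag") <- NULL
  out
}

# Tiny expression table written to a temp file; returns the path.
write_temp_table <- function(df, ext = ".tsv", sep = "\t") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
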