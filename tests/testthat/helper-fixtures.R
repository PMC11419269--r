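# Brute-force interval-union oracle: mark covered residues on an indicator
# vector and read off runs, bridging gaps of at most `gap` uncovered
# residues. Independent of the package's clustering implementation.
oracle_union <- function(starts, ends, gap) {
  idx <- sort(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
  brk <- which(diff(idx) > gap + 1)
  data.frame(start = idx[c(1L, brk + 1L)],
             end = idx[c(brk, length(idx))])
}

# wrap plain spans as a good-hit table for cluster_hits()
spans_as_hits <- function(starts, ends, id = "seq") {
  data.frame(target_id = id, target_start = starts, target_end = ends,
             is_good = TRUE)
}

bundled_seq <- function(file) {
  unname(read_fasta(trem2map_extdata(file)))
}

# analyte series used for the high-affinity ligands (62.5 - 1000 nM)
nm_series <- c(62.5, 125, 250, 500, 1000) * 1e-9
# wide series used for the steady-state ligand (0.012 - 50 uM, 2-fold)
um_series <- 50e-6 / 2^(12:0)
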