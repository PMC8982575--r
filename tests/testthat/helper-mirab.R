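# shared fixtures, all generated in code

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random but structurally valid cassette (canonical loop and flanks)
random_cassette <- function() {
  cassette(sense = random_dna(22), guide = random_dna(22))
}

# random in-frame CDS of n_codons sense codons plus a terminal stop
random_cds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste0(paste(sample(sense, n_codons, replace = TRUE), collapse = ""), "TAA")
}

table2 <- mirab_oligos()

# independent brute-force oracle for panel feasibility: try every injective
# label -> channel map directly
exhaustive_feasible <- function(labels, inst) {
  tab <- load_channel_table()
  usable <- lapply(sub("^GFP$", "EGFP", labels), function(l)
    intersect(unique(tab$channel[tab$label == l]), inst$channels))
  assign_next <- function(i, taken) {
    if (i > length(labels)) return(TRUE)
    for (ch in setdiff(usable[[i]], taken)) {
      if (assign_next(i + 1L, c(taken, ch))) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, character())
}
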