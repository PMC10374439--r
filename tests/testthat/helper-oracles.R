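# Independent brute-force oracles and small fixture builders shared across
# the test files.  These deliberately re-derive results from first
# principles, without reusing the package's implementation paths.

DNA <- c("A", "C", "G", "T")

# brute-force PAM partition: literal pattern matching on the three printed
# class definitions
oracle_pam_class <- function(pam) {
  vapply(strsplit(pam, ""), function(b) {
    if (b[2] != "G") "nonNG"
    else if (b[3] == "G") "NGG"
    else "NGH"
  }, "")
}

# brute-force mismatch classifier: explicit lookup over all 12 ordered
# (spacer RNA base, protospacer DNA base) mismatches
oracle_mismatch_class <- local({
  tab <- c("A>G" = "nonwobble_transition", "A>C" = "transversion",
           "A>T" = "transversion",
           "C>T" = "nonwobble_transition", "C>A" = "transversion",
           "C>G" = "transversion",
           "G>A" = "wobble", "G>C" = "transversion", "G>T" = "transversion",
           "U>C" = "wobble", "U>A" = "transversion", "U>G" = "transversion")
  function(spacer_base, proto_base) unname(tab[paste0(spacer_base, ">", proto_base)])
})

# linear scan from the PAM-distal end (position 20 inward)
oracle_distal_run <- function(positions) {
  run <- 0L
  for (p in 20:1) {
    if (p %in% positions) run <- run + 1L else break
  }
  run
}

rand_dna_str <- function(len) paste(sample(DNA, len, replace = TRUE),
                                    collapse = "")

# a small hand-built two-pair library with chosen barcodes (for assignment
# edge cases)
tiny_library <- function(barcodes = c("AAAAAAAA", "CCCCAAAA")) {
  ctx <- c(paste0("ACGT", "ACGTACGTACGTACGTACGT", "TGG", "CAT"),
           paste0("TTAA", "GGCCGGCCGGCCGGCCGGCC", "AGG", "GTC"))
  GuideTargetLibrary(data.frame(
    pair_id = c("p1", "p2"), guide_id = c("g1", "g2"),
    spacer = substr(ctx, 5, 24), context = ctx,
    expression_system = "tRNA_N20", barcode = barcodes,
    stringsAsFactors = FALSE))
}

# tiny on-target architecture for fast optimizer tests (same code paths,
# reduced width)
tiny_on_config <- function() {
  onTargetConfig(conv_filters = 16L, conv_width = 5L,
                 fc_sizes = c(32L, 32L, 16L), embedding_dim = 16L,
                 dropout = 0.2)
}

tiny_off_config <- function() {
  offTargetConfig(variant = "sniper2L", conv_filters = 16L,
                  fc_sizes = c(32L, 32L, 32L, 16L), dropout = 0.2)
}
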