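# Shared fixtures built in code.

extdata <- function(name) system.file("extdata", name, package = "nlakes")

# Three-slice profile with simple round numbers for hand calculation.
tiny_profile <- function() {
  data.frame(
    site = "tiny",
    slice_top_cm = c(0, 1, 2), slice_bottom_cm = c(1, 2, 3),
    bulk_density_g_cm3 = c(0.2, 0.25, 0.4),
    pb210_total = c(520, 270, 120), pb210_sd = c(10, 8, 6),
    ra226 = c(20, 20, 20), ra226_sd = c(2, 2, 2),
    cs137 = c(5, 40, 10), cs137_sd = c(1, 2, 1)
  )
}

# Ten lakes, each with a lake-specific rank-abundance order; surface and
# bottom samples differ only by multinomial counting noise, so within-lake
# resemblance exceeds between-lake resemblance.
paired_communities <- function(n_lakes = 10, n_taxa = 40, valves = 500,
                               seed = 1) {
  set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  base <- 0.25 * 0.75^(seq_len(n_taxa) - 1)
  rows <- list()
  for (l in seq_len(n_lakes)) {
    p <- sample(base / sum(base))
    for (end in c("s", "b")) {
      rows[[paste0("L", l, "_", end)]] <- rmultinom(1, valves, p)[, 1]
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- taxa
  m
}

# TRUE iff leaves labelled a and b merge directly in the hclust tree.
are_siblings <- function(hc, a, b) {
  ia <- match(a, hc$labels)
  ib <- match(b, hc$labels)
  any(apply(hc$merge, 1, function(r) all(sort(r) == sort(c(-ia, -ib)))))
}
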