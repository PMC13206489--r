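# Shared fixtures. All synthetic tables are seeded so every oracle value
# asserted in the tests is reproducible.

# Minimal hand-built table: one locus, two equifrequent alleles. With
# theta = 0 every probability below is exact dyadic arithmetic.
toy_table <- function() {
  df <- data.frame(locus = "A",
                   allele = c("a", "b"),
                   frequency = c(0.5, 0.5),
                   n_typed = 1000)
  apply_pmin(freq_table(df))
}

# Two loci with unequal ladders, exact frequencies, no p_min flooring.
two_locus_table <- function() {
  df <- data.frame(
    locus = c("A", "A", "B", "B", "B"),
    allele = c("a", "b", "x", "y", "z"),
    frequency = c(0.5, 0.5, 0.2, 0.3, 0.5),
    n_typed = 1000)
  apply_pmin(freq_table(df))
}

# Seeded synthetic panels, memoized per (n_loci, seed) because the larger
# fixtures feed several test files.
.fixture_store <- new.env(parent = emptyenv())

fixture_panel <- function(n_loci = 6L, seed = 101L) {
  key <- sprintf("p%d_%d", n_loci, seed)
  if (is.null(.fixture_store[[key]])) {
    set.seed(seed)
    .fixture_store[[key]] <- apply_pmin(synth_freq_table(n_loci = n_loci))
  }
  .fixture_store[[key]]
}

panel24 <- function() fixture_panel(24L, 42L)
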