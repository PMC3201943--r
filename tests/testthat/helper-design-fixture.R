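# deterministic random DNA with roughly balanced base composition
rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# a two-species fixture: identical flanks around a (CA)10 repeat except a
# deliberately diverged segment in the downstream flank; `div` gives the
# diverged segment's reference coordinates
make_design_fixture <- function() {
  up <- rand_dna(120, 41)
  dn <- rand_dna(120, 42)
  ssr <- strrep("CA", 10)
  ref <- paste0(up, ssr, dn)
  dn_div <- dn
  substr(dn_div, 41, 80) <- rand_dna(40, 43)
  other <- paste0(up, ssr, dn_div)
  div_lo <- 120 + 20 + 41; div_hi <- 120 + 20 + 80
  list(ref = ref, other = other, div = c(div_lo, div_hi))
}
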