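# Build a chain_ensemble directly from coordinate matrices (metres); used to
# exercise the estimator on hand-constructed conformations.
make_ensemble <- function(...) {
  structure(list(conformations = list(...)), class = "chain_ensemble")
}

# A straight chain of n points along z with total length L (metres).
straight_chain <- function(L, n = 11L) {
  cbind(0, 0, seq(0, L, length.out = n))
}
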