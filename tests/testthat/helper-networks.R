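# Small hand-built networks used across the tests.

# n-gene identity BN: every state is a fixed point.
identity_bn <- function(n, m = 0, p = 0) {
  pbn(lapply(seq_len(n), function(i) list(boolean_function(i, c(0, 1)))),
    m = m, p = p
  )
}

# 1-gene negation: the 2-cycle 1 <-> 2.
negation_bn <- function() {
  pbn(list(list(boolean_function(1, c(1, 0)))))
}

# both genes copy gene 1: fixed points 00 and 11, states 01/10 unreachable.
copy_gene1_bn <- function() {
  pbn(list(
    list(boolean_function(1, c(0, 1))),
    list(boolean_function(1, c(0, 1)))
  ))
}

# 1-gene PBN: copy itself w.p. 0.6, negate w.p. 0.4.
coin_pbn <- function(p = 0) {
  pbn(list(list(
    boolean_function(1, c(0, 1), c = 0.6),
    boolean_function(1, c(1, 0), c = 0.4)
  )), p = p)
}

# 1 gene, 1 control: the gene copies the control bit.
controllable_toy <- function() {
  pbn(list(list(boolean_function(2, c(0, 1)))), m = 1)
}

# 1 gene, 1 control: negation, control ignored (parent list must still be valid).
uncontrollable_toy <- function() {
  pbn(list(list(boolean_function(1, c(1, 0)))), m = 1)
}
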