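# Shared fixtures, all built in code.

# chain A -> B -> C with configurable signs
chain_net <- function(signs = c(1, 1)) {
  signed_network(data.frame(source = c("A", "B"), target = c("B", "C"),
                            sign = signs))
}

# A -> B -> C with a negative feedback loop C -| B
feedback_net <- function() {
  signed_network(data.frame(source = c("A", "B", "C"),
                            target = c("B", "C", "B"),
                            sign = c(1, 1, -1)))
}

# random signed multigraph on n nodes with m edge slots (self-edges and
# parallel opposite-sign edges possible); duplicates collapse silently
random_net <- function(n, m) {
  edges <- data.frame(source = paste0("V", sample(n, m, replace = TRUE)),
                      target = paste0("V", sample(n, m, replace = TRUE)),
                      sign = sample(c(1L, -1L), m, replace = TRUE))
  suppressWarnings(signed_network(edges, nodes = paste0("V", seq_len(n))))
}

# a ternary state built directly (for contract tests that need exact values)
make_state <- function(values, clamped = character(0)) {
  structure(list(values = values, clamped = clamped, iterations = 1L),
            class = "ternary_state")
}

write_sif <- function(lines) {
  f <- tempfile(fileext = ".sif")
  writeLines(lines, f)
  f
}
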