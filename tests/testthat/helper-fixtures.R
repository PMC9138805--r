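# Shared fixtures. The full default library is cached because several files
# use it and assembly enumerates 1230 transitions.

.fixture_env <- new.env(parent = emptyenv())

full_library <- function() {
  if (is.null(.fixture_env$lib)) {
    .fixture_env$lib <- assemble_library()
  }
  .fixture_env$lib
}

# a small well-separated library: `n` single-transition species with wide
# retention spacing, for fast simulator tests
tiny_library <- function(n = 10, rt_from = 2, rt_by = 2) {
  tibble::tibble(
    transition_id = sprintf("t%02d", seq_len(n)),
    species = sprintf("t%02d", seq_len(n)),
    lipid_class = "PC",
    ion_mode = "negative",
    q1 = 700 + seq_len(n),
    q3 = 255.2330,
    product = "FA16:0",
    expected_rt = rt_from + rt_by * (seq_len(n) - 1),
    dp = -80, ep = -10, ce = -50, cxp = -15,
    is_internal_standard = FALSE
  )
}

# independent element-mass oracle for [DERIVED] mass checks (summation kept
# separate from the package's parser/adder)
oracle_mass <- function(C = 0, H = 0, D = 0, N = 0, O = 0, P = 0) {
  C * 12 + H * 1.0078250 + D * 2.0141018 + N * 14.0030740 +
    O * 15.9949146 + P * 30.9737615
}
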