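# Absolute-tolerance comparison (expect_equal's tolerance is relative).
expect_within <- function(actual, expected, tol) {
  act <- testthat::quasi_label(rlang::enquo(actual))
  diff <- max(abs(actual - expected))
  testthat::expect(
    length(actual) == length(expected) && diff <= tol,
    sprintf("%s differs from expected by %.6g (absolute tolerance %g)",
            act$lab, diff, tol))
  invisible(actual)
}
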