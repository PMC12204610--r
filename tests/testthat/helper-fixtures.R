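# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tinySim <- function() cached("tinySim", makeFixture("tiny"))

tinyImages <- function() cached("tinyImages", {
  sim <- tinySim()
  suppressMessages(buildPseudoImages(sim$targets, sim$dnase, sim$methyl))
})

# A small-width architecture for fast tests; same stage structure as the
# default, full 128-position frame so real pseudo-images fit.
smallConfig <- function(...) {
  do.call(modelConfig, utils::modifyList(
    list(mixconv_out_channels = 4L, compress_channels = 8L,
         conv_channels = c(8L, 8L), trunk_widths = 32L,
         branch_widths = 8L),
    list(...)))
}

# An even smaller frame for gradient checks (images not needed there).
microConfig <- function(...) {
  do.call(modelConfig, utils::modifyList(
    list(length = 16L, mixconv_kernels = c(1L, 3L),
         mixconv_out_channels = 3L, compress_channels = 4L,
         conv_channels = c(4L, 4L), trunk_widths = 8L,
         branch_widths = 5L),
    list(...)))
}

randomParams <- function(model, sd = 0.3, seed = 99L) {
  withr::with_seed(seed,
    lapply(model@params, function(x) { x[] <- stats::rnorm(length(x), sd = sd); x }))
}

# One minimal hand-written record used across io/encoder tests.
handRecordDf <- function() {
  data.frame(record_id = "r1",
             wild_seq = "ACGTACGTAA", edited_seq = "ACGTACGTAA",
             proto_start = 0L, proto_end = 4L,
             pam_start = 4L, pam_end = 6L,
             pbs_start = 6L, pbs_end = 8L,
             rt_start = 7L, rt_end = 10L,
             stringsAsFactors = FALSE)
}
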