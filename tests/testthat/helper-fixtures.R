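# Shared fixtures and independent oracles for the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

balafon <- build_balafon_fixture()

# A brute-force matching oracle, deliberately written as a naive scan that
# scores every entry and resolves ties explicitly: collect all matching
# entries, keep those with the maximal score, take the lowest id.
oracle_match_id <- function(complaint, kb) {
  ids <- integer()
  scores <- integer()
  for (g in kb$guide) {
    ok <- TRUE
    score <- 0L
    for (d in c("cause", "specificity", "environment", "activity")) {
      pat <- g$pattern[[d]]
      if (is.null(pat)) next
      if (complaint[[d]] %in% pat) {
        score <- score + 1L
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      ids <- c(ids, g$id)
      scores <- c(scores, score)
    }
  }
  if (!length(ids)) return(NA_integer_)
  winners <- ids[scores == max(scores)]
  min(winners)
}

# a tiny but valid knowledge base: one parameter, one guide entry
minimal_kb <- function() {
  knowledge_base(
    parameters = list(
      parameter_spec("MCL", "dynamic", "dB", c(0, 120), 50, 6)),
    guide = list(
      guide_entry(1, list(cause = 0L), list(solution("C"))))
  )
}

# complaint constructor shorthand used throughout the tests
cpl <- function(cause, spec = 0, env = 4, act = 0, freq = 0, disc = 0) {
  complaint_descriptor(cause, spec, env, act, freq, disc)
}
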