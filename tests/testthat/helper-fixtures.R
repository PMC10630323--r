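# shared test fixtures, built once per test run

take_pairs <- function(p, i) {
  structure(unclass(p)[i], class = "cycle_pairs",
            L = attr(p, "L"), fs = attr(p, "fs"), lag = attr(p, "lag"))
}

# hand-construct a cycle_pairs object from coefficient-domain data so the
# regression layer can be tested against planted truth
pairs_from_matrices <- function(P, E, L) {
  stopifnot(nrow(P) == nrow(E))
  pairs <- lapply(seq_len(nrow(P)), function(i) {
    list(ppg = idct_reconstruct(P[i, ], L),
         ecg = idct_reconstruct(E[i, ], L),
         r_index = 1L, len = L, start = 1L)
  })
  structure(pairs, class = "cycle_pairs", L = L, fs = 125, lag = 0L)
}

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- force(expr)
  fixture_cache[[name]]
}

# a clean 30 s paired recording reused across detection/detrending tests
fixture_recording <- function() {
  cached("rec30", gen_paired_recording(
    sim_config(duration = 30, hr = 75, noise_sd = 0.02, seed = 4)
  ))
}
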