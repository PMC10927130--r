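# Shared fixtures, built in code.

# small three-group cohort reused across tests (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        n_per_group = c(CTRL = 18L, MDD = 18L, CD = 18L), seed = 42L)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

# deterministic uniform response table: every picture of every category
# keypressed `count` times with the given valence
uniform_responses <- function(id = "p1", count = 5L, valence = "inc",
                              n_categories = 4L, n_pictures = 20L) {
  other <- setdiff(c("inc", "dec"), valence)
  do.call(rbind, lapply(seq_len(n_categories), function(cc) {
    data.frame(participant_id = id, category = cc,
               picture = rep(seq_len(n_pictures), 2L),
               valence = rep(c(valence, other), each = n_pictures),
               keypresses = rep(c(count, 0L), each = n_pictures))
  }))
}

# responses with distinct per-category uniform counts on both sides,
# constructed so all RPT fits are well defined
structured_responses <- function(id = "p1", inc_counts = c(2L, 4L, 6L, 8L),
                                 dec_counts = c(3L, 5L, 7L, 9L)) {
  do.call(rbind, lapply(seq_along(inc_counts), function(cc) {
    # half the pictures approached, half avoided; counts vary mildly
    # within category so entropy and sd are nonzero
    inc <- c(rep(inc_counts[cc], 8L), inc_counts[cc] + 1L, 0L,
             rep(0L, 10L))
    dec <- c(rep(0L, 10L), rep(dec_counts[cc], 8L), dec_counts[cc] + 1L,
             0L)
    data.frame(participant_id = id, category = cc,
               picture = rep(1:20, 2L),
               valence = rep(c("inc", "dec"), each = 20L),
               keypresses = c(inc, dec))
  }))
}
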