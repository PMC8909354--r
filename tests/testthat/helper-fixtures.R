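# Shared in-code fixtures: small scored case sets and rating panels built
# programmatically, no files on disk.

# Minimal scored case set from a vector of mean percentiles.
make_cases <- function(mP, ids = sprintf("C%02d", seq_along(mP))) {
  data.frame(case_id = ids, mP = mP,
             is2 = classify_two_level(mP),
             decile_bin = decile_bin(mP),
             stringsAsFactors = FALSE)
}

# Long density table for a single case.
make_profile <- function(case_id, cd3_ct, cd3_im, cd8_ct, cd8_im) {
  data.frame(case_id = case_id,
             marker = c("CD3", "CD3", "CD8", "CD8"),
             region = c("CT", "IM", "CT", "IM"),
             density = c(cd3_ct, cd3_im, cd8_ct, cd8_im),
             stringsAsFactors = FALSE)
}

# Ratings panel where every rater matches the reference except the
# (case, rater) pairs listed in `flips` (data.frame case_id, rater_id).
make_panel <- function(cases, rater_ids, phase, flips = NULL) {
  grid <- expand.grid(case_id = cases$case_id, rater_id = rater_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ref <- as.character(cases$is2)[match(grid$case_id, cases$case_id)]
  call <- ref
  if (!is.null(flips)) {
    hit <- paste(grid$case_id, grid$rater_id) %in%
      paste(flips$case_id, flips$rater_id)
    call[hit] <- ifelse(ref[hit] == "Low", "High", "Low")
  }
  data.frame(case_id = grid$case_id, rater_id = grid$rater_id,
             phase = phase,
             call3 = ifelse(call == "Low", "Low", "High"),
             tscore2 = factor(call, levels = c("Low", "High")),
             stringsAsFactors = FALSE)
}

# A 50-case reference set spread over the score range, 5 per decile bin,
# deterministic (no RNG): two Low deciles plus part of the third, as in a
# stratified design.
make_cases50 <- function() {
  mP <- as.vector(vapply(0:9, function(b) 10 * b + c(1, 3, 5, 7, 9),
                         numeric(5)))
  make_cases(mP)
}
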