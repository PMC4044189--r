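# shared fixtures and independent oracles

# construct a dipole_field by hand (bypassing the sampler) for render tests
make_field <- function(x, y, orientation, polarity, is_signal = TRUE,
                       field_side = 14.4) {
  structure(
    data.frame(x_deg = x, y_deg = y, orientation_rad = orientation,
               polarity = as.integer(polarity),
               is_signal = rep_len(is_signal, length(x))),
    class = c("dipole_field", "data.frame"), field_side = field_side)
}

empty_field <- function(field_side = 14.4) {
  make_field(numeric(0), numeric(0), numeric(0), integer(0), logical(0),
             field_side)
}

# bitmask of the ordered adjacent condition pairs in one sequence, over
# the n^2 possible (from, to) codes (independent checker for the
# counterbalancing property)
pair_mask <- function(seq_vec, n) {
  codes <- (seq_vec[-length(seq_vec)] - 1L) * n + seq_vec[-1] - 1L
  Reduce(bitwOr, bitwShiftL(1L, codes), 0L)
}

# brute-force check that a set of sequences has every ordered pair of
# distinct conditions exactly once among within-sequence adjacencies
is_row_complete <- function(seqs, n) {
  counts <- matrix(0L, n, n)
  for (s in seqs) {
    for (i in seq_len(length(s) - 1L)) {
      counts[s[i], s[i + 1L]] <- counts[s[i], s[i + 1L]] + 1L
    }
  }
  all(diag(counts) == 0L) && all(counts[row(counts) != col(counts)] == 1L)
}

# all permutations of 1:n, via recursive insertion (oracle-side copy)
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(nrow(sub)), function(s) {
    t(sapply(seq_len(n), function(pos) append(sub[s, ], n, after = pos - 1L)))
  }))
}

# small protocol for fast GLM tests: 2 conditions, short blocks
tiny_protocol <- function(n_runs = 1) {
  block_protocol(n_conditions = 2, block_duration = 8, sequences_per_run = 2,
                 pre_blank = 4, tr = 2, n_runs = n_runs,
                 censor_volumes_per_run = 2)
}

tiny_timeline <- function() {
  build_run_timeline(tiny_protocol(), list(c(1L, 2L), c(2L, 1L)))
}
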