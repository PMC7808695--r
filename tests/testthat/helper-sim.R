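# Shared fixtures, memoised so several test files can reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Default study-like dataset (5 samples, 3 source populations).
default_dataset <- function(seed = 7) {
  cached(paste0("default_", seed), {
    simulate_dataset(sim_config(seed = seed))
  })
}

## One-sample config focused on a single compartment / question.
one_sample_cfg <- function(seed, sex = "XX", endogenous = 0.9, coverage_x = 1,
                           mean_fragment_bp = 42, deamination_rate_5p = 0.25,
                           deamination_decay = 0.55, seq_error_rate = 5e-4,
                           contamination_fraction = 0, dup_rate = 0,
                           genome = c(auto = 20000L, X = 5000L, Y = 2000L,
                                      MT = 5000L),
                           mt_copy_number = 10, n_snps = 50L, ...) {
  sim_config(
    seed = seed, genome = genome, n_snps = n_snps,
    read_specs = data.frame(
      sample = "s1", sex = sex, endogenous = endogenous,
      coverage_x = coverage_x, mean_fragment_bp = mean_fragment_bp,
      deamination_rate_5p = deamination_rate_5p,
      deamination_decay = deamination_decay, seq_error_rate = seq_error_rate,
      contamination_fraction = contamination_fraction, dup_rate = dup_rate
    ),
    admixed_specs = data.frame(sample = "s1", q_pop1 = 1, q_pop2 = 0,
                               q_pop3 = 0),
    mt_copy_number = mt_copy_number, ...
  )
}

## Hand-built read set: one read per row of the given fields.
make_reads <- function(contig, pos, strand, seq, mapq = 37L, qual = NULL,
                       sample_id = "manual") {
  n <- length(pos)
  if (is.null(qual)) {
    qual <- vapply(nchar(seq), function(L) strrep("F", L), character(1))
  }
  aln_reads(data.frame(contig = contig, pos = pos, strand = strand,
                       seq = seq, qual = qual, mapq = mapq),
            sample_id = sample_id)
}

## Best label-permutation accuracy of a clustering against truth.
perm_accuracy <- function(cluster, truth) {
  labs <- unique(truth)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_along(labs))) {
    mapped <- labs[p][cluster]
    best <- max(best, mean(mapped == truth))
  }
  best
}
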