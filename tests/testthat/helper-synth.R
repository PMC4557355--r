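# Shared fixtures, all generated in code.

# Ideal staircase trace: m downward steps of the given sizes at `pos`
# (last frame of the old level), ending at zero, plus optional Gaussian
# noise. Step positions are drawn with a minimum separation so every step
# is resolvable by construction.
make_staircase <- function(m, step_size = 1000, noise_sd = 0, n_frames = 500,
                           min_sep = 6, sizes = rep(step_size, m)) {
  repeat {
    pos <- sort(sample(seq(20, n_frames - 20), m))
    if (m == 1 || min(diff(pos)) >= min_sep) break
  }
  x <- numeric(n_frames)
  cur <- sum(sizes)
  last <- 1
  for (i in seq_len(m)) {
    x[last:pos[i]] <- cur
    last <- pos[i] + 1
    cur <- cur - sizes[i]
  }
  x[last:n_frames] <- cur
  if (noise_sd > 0) x <- x + rnorm(n_frames, 0, noise_sd)
  x
}

# Count steps through the full filter + census path.
count_staircase <- function(x, monomer_counts = 1000, params = ck_params()) {
  f <- ck_filter(x, params)
  count_steps(f, monomer_counts / max(f), params, raw = x)$n_steps
}

# Single-species ground truth shorthand.
pure_species <- function(n) stats::setNames(1, n)

# The reference study mixture: dimers, tetramers, hexamers.
study_mix <- stats::setNames(c(0, 0.45, 0, 0.35, 0, 0.20), 1:6)
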