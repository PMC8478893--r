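# Shared fixtures: small controlled genomes and assay pairs built in code.

# Genome of identical loci with a prescribed standing load, for drift tests.
flat_genome <- function(L = 500, s = 0.5, h = 0.1, q = 0.02, u = 0) {
  genome_manual(s = rep(s, L), h = rep(h, L), u = u, q_hat = q)
}

# Independent iterative oracle for Wright's F: one-generation accumulation
# F_t = F_{t-1} + (1 - F_{t-1}) / (2 Ne).
iter_wright <- function(ne, t_max) {
  f <- numeric(t_max + 1)
  for (i in seq_len(t_max)) f[i + 1] <- f[i] + (1 - f[i]) / (2 * ne)
  f
}

# Synthetic assay pair with plenty of pairs for point-estimate checks.
big_assay_pair <- function(delta_true, n = 10000, seed = 1, p0 = 87) {
  generate_assay_pair(synth_config(delta_true, p0 = p0, n_out = n,
                                   n_in = n, seed = seed))
}
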