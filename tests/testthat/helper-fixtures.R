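# Shared fixtures and independent brute-force oracles. The oracles here are
# deliberately naive re-implementations (double loops over sites and pairs)
# so that the package's vectorized code is checked against a separate path.

AA20 <- aa_alphabet()

tiny_cfg <- function(...) {
  model_config(hidden_dim = 16L, k = 8L, ff_mult = 2L, n_rbf = 8L,
               relpos_clip = 8L, ...)
}

# desk-scale training configuration: small enough to train on a laptop CPU
# in minutes, large enough to memorize a handful of 30-residue folds
desk_cfg <- function(...) {
  model_config(hidden_dim = 64L, k = 16L, ff_mult = 2L,
               activation = "relu", ...)
}

desk_dataset <- function(n_fix = 5L, n_res = 30L) {
  topos <- rep(c("helix", "helix", "strand", "hairpin", "hairpin"),
               length.out = n_fix)
  lapply(seq_len(n_fix), function(i) {
    bb <- make_synthetic_backbone(n_res, topos[i], i)
    list(id = bb$id, structure = bb,
         sequence = int_to_aa(with_seed_(100 + i,
                                         sample(20L, n_res, replace = TRUE))))
  })
}

with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent Potts energy: explicit double loop, no shared code with the
# package implementation
brute_energy <- function(pm, s) {
  tot <- 0
  for (i in seq_len(pm$n_sites)) tot <- tot + pm$h[i, s[i]]
  if (nrow(pm$edges)) for (e in seq_len(nrow(pm$edges))) {
    i <- pm$edges[e, 1]; j <- pm$edges[e, 2]
    tab <- matrix(pm$J[e, ], 20, 20, byrow = TRUE)
    tot <- tot + tab[s[i], s[j]]
  }
  tot
}

# enumeration oracle for the pair conditional: set (s[i], s[j]) = (a, b) for
# all 400 combinations, score full sequences, softmax
brute_pair_conditional <- function(pm, s, i, j) {
  En <- matrix(NA_real_, 20, 20)
  for (a in 1:20) for (b in 1:20) {
    s2 <- s; s2[i] <- a; s2[j] <- b
    En[a, b] <- brute_energy(pm, s2)
  }
  p <- exp(En - max(En))
  p / sum(p)
}

brute_site_conditional <- function(pm, s, i) {
  En <- vapply(1:20, function(a) { s2 <- s; s2[i] <- a; brute_energy(pm, s2) },
               numeric(1))
  p <- exp(En - max(En))
  p / sum(p)
}

random_seq <- function(n, seed) with_seed_(seed, sample(20L, n, replace = TRUE))
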