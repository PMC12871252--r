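test_that("pearson matches the textbook formula and guards its domain", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  for (t in 1:5) {
    a <- with_seed_(t, rnorm(50)); b <- with_seed_(100 + t, rnorm(50))
    two_pass <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson(a, b), two_pass, tolerance = 1e-12)
  }
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance in x")
  expect_error(pearson(1:5, rep(2, 5)), "zero variance in y")
  expect_error(pearson(1:4, 1:5), "length mismatch")
})

test_that("potts scoring equals brute-force energy differences", {
  pm <- make_random_potts(12, seed = 88)
  s <- random_seq(12, 89)
  wt <- int_to_aa(s)
  muts <- lapply(1:20, function(t) {
    i <- with_seed_(500 + t, sample(12, 1))
    m <- with_seed_(600 + t, sample(setdiff(1:20, s[i]), 1))
    mutation_record(AA20[s[i]], i, AA20[m], ddG_expt = rnorm(1), protein_id = "p")
  })
  rep <- score_mutations(pm, wt, muts, scorer = "potts")
  expect_equal(nrow(rep$predictions), 20L)
  for (r in seq_len(20)) {
    mr <- muts[[r]]
    s2 <- s; s2[mr$position] <- aa_to_int(mr$mut_aa)
    expect_equal(rep$predictions$predicted[r],
                 brute_energy(pm, s2) - brute_energy(pm, s),
                 tolerance = 1e-9)
  }
})

test_that("a wild-type 'mutation' scores 0 under both scorers", {
  pm <- make_random_potts(8, seed = 3)
  s <- random_seq(8, 4)
  wt <- int_to_aa(s)
  mr <- mutation_record(AA20[s[5]], 5, AA20[s[5]], 0.1, "p")
  expect_equal(score_mutations(pm, wt, list(mr))$predictions$predicted, 0)
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(8, "helix", 1)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  node <- list(params = init_model_params(cfg, seed = 1), cfg = cfg, graph = g)
  expect_equal(score_mutations(node, wt, list(mr),
                               scorer = "node")$predictions$predicted, 0)
})

test_that("an affine experimental column gives r = 1 and sign flips work", {
  pm <- make_random_potts(10, seed = 17)
  s <- random_seq(10, 18)
  wt <- int_to_aa(s)
  muts <- lapply(1:8, function(t) {
    i <- t; m <- ((s[i] + 4) %% 20) + 1L
    mutation_record(AA20[s[i]], i, AA20[m], protein_id = "p")
  })
  base <- score_mutations(pm, wt, muts, scorer = "potts")
  affine <- lapply(seq_along(muts), function(r)
    modifyList(muts[[r]],
               list(ddG_expt = 3 * base$predictions$predicted[r] - 2)))
  class(affine[[1]]) <- "mutation_record"
  rep2 <- score_mutations(pm, wt, affine, scorer = "potts")
  expect_equal(rep2$pooled_r, 1.0, tolerance = 1e-9)
  expect_equal(rep2$per_protein$r, 1.0, tolerance = 1e-9)
  rep3 <- score_mutations(pm, wt, affine, scorer = "potts",
                          flip_expt_sign = TRUE)
  expect_equal(rep3$pooled_r, -1.0, tolerance = 1e-9)
})

test_that("unresolvable and mismatched rows are skipped with reasons", {
  pm <- make_random_potts(5, seed = 2)
  s <- random_seq(5, 2)
  wt <- int_to_aa(s)
  bad_wt <- mutation_record(AA20[(s[2] %% 20) + 1], 2, "A", 1, "p")
  bb <- make_synthetic_backbone(5, "helix", 0)
  bb$resno <- c(10L, 11L, 12L, 13L, 14L)   # author numbering offset
  off_map <- mutation_record(AA20[s[3]], 99, "W", 1, "p")
  good <- mutation_record(AA20[s[3]], 12, "W", 1, "p")
  rep <- score_mutations(pm, wt, list(bad_wt, off_map, good),
                         scorer = "potts", structure = bb)
  expect_equal(nrow(rep$skipped), 2L)
  expect_match(rep$skipped$reason[1], "unresolvable|mismatch")
  expect_equal(nrow(rep$predictions), 1L)
  expect_equal(rep$predictions$position, 12L)  # author numbering reported
  # empty table -> empty report, not a crash
  empty <- score_mutations(pm, wt, list(), scorer = "potts")
  expect_equal(nrow(empty$predictions), 0L)
})

test_that("node scorer: sites decoded before the mutation contribute zero", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(10, "hairpin", 3)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 7)
  s <- random_seq(10, 7)
  ord <- decoding_order(10, 0, g$id)
  pos <- ord[6]                      # mutate a mid-order site
  s2 <- s; s2[pos] <- ((s[pos] + 5) %% 20) + 1L
  enc <- encode(g, p, cfg)
  lp_of <- function(sv) {
    lg <- decode_logits(enc, cfg, ord, sv)
    mx <- apply(lg, 1, max)
    lg - mx - log(rowSums(exp(lg - mx)))
  }
  lp1 <- lp_of(s); lp2 <- lp_of(s2)
  delta <- lp2[cbind(1:10, s2)] - lp1[cbind(1:10, s)]
  expect_true(all(delta[ord[1:5]] == 0))
  # and the report's node score equals the summed per-site changes
  mr <- mutation_record(AA20[s[pos]], pos, AA20[s2[pos]], protein_id = "p")
  rep <- score_mutations(list(params = p, cfg = cfg, graph = g),
                         int_to_aa(s), list(mr), scorer = "node", seed = 0)
  expect_equal(rep$predictions$predicted, sum(delta), tolerance = 1e-9)
})

test_that("design export round-trips metadata and handles empty input", {
  pm <- make_random_potts(6, seed = 5)
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(6, "helix", 2)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 2)
  d1 <- sample_sequence(p, cfg, g, temperature = 0.1, seed = 1)
  d1 <- local_optimize(pm, d1, mode = "single_pass")
  d2 <- sample_sequence(p, cfg, g, temperature = 0.1, seed = 2)
  d2 <- local_optimize(pm, d2, mode = "single_pass")
  tf <- tempfile(fileext = ".fasta")
  export_designs(list(d1, d2), tf, seed = 1, optimize = "pass")
  recs <- Biostrings::readAAStringSet(tf)
  expect_length(recs, 2L)
  expect_identical(as.character(recs[[1]]), d1$sequence)
  meta <- parse_design_header(names(recs)[1])
  expect_equal(meta$temperature, 0.1)
  expect_equal(meta$optimize, "pass")
  expect_equal(meta$potts_initial, d1$potts_score_initial, tolerance = 1e-6)
  expect_equal(meta$potts_final, d1$potts_score_final, tolerance = 1e-6)
  # empty list -> empty file, success
  tf2 <- tempfile(fileext = ".fasta")
  export_designs(list(), tf2)
  expect_true(file.exists(tf2))
  expect_equal(file.info(tf2)$size, 0)
})

test_that("reports are deterministic for fixed inputs", {
  pm <- make_random_potts(7, seed = 10)
  s <- random_seq(7, 10)
  muts <- lapply(1:5, function(i)
    mutation_record(AA20[s[i]], i, AA20[((s[i] + 2) %% 20) + 1], rnorm(1), "p"))
  r1 <- score_mutations(pm, int_to_aa(s), muts)
  r2 <- score_mutations(pm, int_to_aa(s), muts)
  expect_identical(r1$predictions, r2$predictions)
})
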