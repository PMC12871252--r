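test_that("eval-mode encoding is deterministic; dropout breaks it in train mode", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(14, "helix", 2)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 3)
  e1 <- encode(g, p, cfg)
  e2 <- encode(g, p, cfg)
  expect_identical(e1$h, e2$h)
  expect_identical(e1$e, e2$e)
  expect_true(all(is.finite(e1$h)))
  set.seed(1); t1 <- encode(g, p, cfg, train = TRUE)
  set.seed(2); t2 <- encode(g, p, cfg, train = TRUE)
  expect_false(identical(t1$h, t2$h))
})

test_that("encoder is equivariant to node relabelling", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(20, "hairpin", 1)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 5)
  perm <- with_seed_(7, sample(20))
  inv <- integer(20); inv[perm] <- seq_len(20)
  # relabel the graph arrays directly (features travel with their edges)
  g2 <- g
  g2$neighbors <- matrix(inv[g$neighbors[perm, ]], nrow = 20)
  reorder_rows <- as.vector(t(matrix(seq_len(20 * g$k_eff), ncol = g$k_eff,
                                     byrow = TRUE)[perm, , drop = FALSE]))
  g2$edge_feat <- g$edge_feat[reorder_rows, , drop = FALSE]
  g2$self_feat <- g$self_feat[perm, , drop = FALSE]
  g2$edge_mask <- g$edge_mask[reorder_rows]
  g2$ca_nbr_dist <- g$ca_nbr_dist[perm, , drop = FALSE]
  g2$valid <- g$valid[perm]; g2$chain <- g$chain[perm]
  e1 <- encode(g, p, cfg)
  e2 <- encode(g2, p, cfg)
  expect_equal(e2$h, e1$h[perm, ], tolerance = 1e-10)
})

test_that("a zero Potts head yields the zero Potts model; shapes contract", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(10, "strand", 1)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 1)
  p$potts_head$W[] <- 0; p$potts_head$b[] <- 0
  pm <- extract_potts(encode(g, p, cfg), cfg)
  expect_s3_class(pm, "potts_model")
  expect_true(all(pm$h == 0) && all(pm$J == 0))
  expect_equal(nrow(pm$h), 10L)
  expect_equal(ncol(pm$h), 20L)
  expect_equal(ncol(pm$J), 400L)
  expect_equal(nrow(pm$J), nrow(pm$edges))
})

test_that("extracted J is exactly symmetric and energies rotation-invariant", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(13, "hairpin", 6)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 8)
  pm <- extract_potts(encode(g, p, cfg), cfg)
  for (t in 1:25) {
    i <- sample(13, 1); j <- sample(setdiff(1:13, i), 1)
    a <- sample(20, 1); b <- sample(20, 1)
    expect_identical(potts_pair_energy(pm, i, j, a, b),
                     potts_pair_energy(pm, j, i, b, a))
  }
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  bb2 <- bb
  for (a in 1:4) bb2$coords[, a, ] <- bb$coords[, a, ] %*% R +
      matrix(c(4, 4, -9), 13, 3, byrow = TRUE)
  pm2 <- extract_potts(encode(build_knn_graph(bb2, k = cfg$k,
                                              n_rbf = cfg$n_rbf,
                                              relpos_clip = cfg$relpos_clip),
                              p, cfg), cfg)
  for (t in 1:10) {
    s <- int_to_aa(random_seq(13, 400 + t))
    expect_lt(abs(potts_energy(pm, s) - potts_energy(pm2, s)), 1e-4)
  }
})

test_that("decoder logits are causal in the decoding order", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(12, "helix", 4)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 2)
  enc <- encode(g, p, cfg)
  ord <- decoding_order(12, 9, g$id)
  s1 <- random_seq(12, 1)
  # changing every residue except the first-decoded leaves its logits
  # bit-identical
  s2 <- ((s1 + 6) %% 20) + 1L
  s2[ord[1]] <- s1[ord[1]]
  l1 <- decode_logits(enc, cfg, ord, s1)
  l2 <- decode_logits(enc, cfg, ord, s2)
  expect_identical(l1[ord[1], ], l2[ord[1], ])
  # changing a residue that precedes site i (and is a graph neighbour of
  # it) changes i's logits
  rank <- integer(12); rank[ord] <- seq_len(12)
  found <- FALSE
  for (i in seq_len(12)) {
    nb <- g$neighbors[i, ]
    pre <- nb[rank[nb] < rank[i]]
    if (length(pre)) {
      j <- pre[1]
      s3 <- s1; s3[j] <- ((s1[j] + 3) %% 20) + 1L
      l3 <- decode_logits(enc, cfg, ord, s3)
      expect_false(identical(l1[i, ], l3[i, ]))
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_error(decode_logits(enc, cfg, ord, s1[-1]), "mismatch")
  expect_error(decode_logits(enc, cfg, c(1L, ord), s1), "permutation")
})

test_that("decoding orders are reproducible permutations keyed by protein", {
  o1 <- decoding_order(25, 3, "prot_a")
  o2 <- decoding_order(25, 3, "prot_a")
  o3 <- decoding_order(25, 3, "prot_b")
  o4 <- decoding_order(25, 4, "prot_a")
  expect_identical(o1, o2)
  expect_setequal(o1, 1:25)
  expect_false(identical(as.integer(o1), as.integer(o3)))
  expect_false(identical(as.integer(o1), as.integer(o4)))
})

test_that("variant gating controls decoder and Potts head parameters", {
  po <- init_model_params(model_config(hidden_dim = 16, variant = "potts_only"))
  expect_null(po$dec); expect_null(po$out); expect_null(po$seq_embed)
  expect_false(is.null(po$potts_head))
  no <- init_model_params(model_config(hidden_dim = 16, variant = "node_only"))
  expect_null(no$potts_head)
  expect_false(is.null(no$dec))
  cfg_no <- model_config(hidden_dim = 16, variant = "node_only", k = 4)
  bb <- make_synthetic_backbone(8, "helix", 0)
  g <- build_knn_graph(bb, k = 4)
  expect_error(extract_potts(encode(g, no, cfg_no), cfg_no), "no Potts head")
  cfg_po <- model_config(hidden_dim = 16, variant = "potts_only", k = 4)
  expect_error(decode_logits(encode(g, init_model_params(cfg_po), cfg_po),
                             cfg_po, sample(8), random_seq(8, 1)),
               "no autoregressive decoder")
})

test_that("checkpoints round-trip parameters and config", {
  cfg <- tiny_cfg()
  p <- init_model_params(cfg, seed = 11)
  tf <- tempfile(fileext = ".ckpt")
  save_checkpoint(p, cfg, tf, extra = list(epoch = 7L))
  ck <- load_checkpoint(tf)
  expect_identical(ck$params, p)
  expect_equal(ck$cfg$hidden_dim, cfg$hidden_dim)
  expect_equal(ck$extra$epoch, 7L)
  tf2 <- tempfile(); saveRDS(list(1), tf2)
  expect_error(load_checkpoint(tf2), "format error")
})
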