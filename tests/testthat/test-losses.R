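test_that("node loss matches its closed forms and is linear in the mask", {
  n <- 100L
  s <- random_seq(n, 5)
  unif <- matrix(0, n, 20)
  expect_equal(loss_node(unif, s), n * log(20) / 2000, tolerance = 1e-9)
  expect_equal(loss_node(unif, s), 0.1497866, tolerance = 1e-6)

  onehot <- matrix(-1e4, n, 20)
  onehot[cbind(seq_len(n), s)] <- 1e4
  expect_lt(loss_node(onehot, s), 1e-8)

  half <- rep(c(TRUE, FALSE), n / 2)
  expect_equal(loss_node(unif, s, half), loss_node(unif, s) / 2,
               tolerance = 1e-12)
  expect_error(loss_node(unif, s[-1]), "mismatch")
})

test_that("edge loss equals ln(400) for the zero model and 0 for a certain one", {
  for (n in c(5, 12)) {
    z <- potts_model(matrix(0, n, 20), t(combn(n, 2)),
                     matrix(0, choose(n, 2), 400))
    s <- int_to_aa(random_seq(n, n))
    expect_equal(loss_edge(z, s), log(400), tolerance = 1e-9)
  }
  # a model that puts ~all probability on the native pair at every edge
  n <- 6; s <- random_seq(n, 9)
  h <- matrix(0, n, 20); h[cbind(1:n, s)] <- 50
  pm <- potts_model(h, t(combn(n, 2)), matrix(0, choose(n, 2), 400))
  expect_lt(loss_edge(pm, int_to_aa(s)), 1e-6)
})

test_that("edge loss equals a brute-force 400-way enumeration per edge", {
  pm <- make_random_potts(10, seed = 41)
  s <- random_seq(10, 42)
  acc <- 0
  for (e in seq_len(nrow(pm$edges))) {
    p <- brute_pair_conditional(pm, s, pm$edges[e, 1], pm$edges[e, 2])
    acc <- acc - log(p[s[pm$edges[e, 1]], s[pm$edges[e, 2]]])
  }
  expect_equal(loss_edge(pm, int_to_aa(s)), acc / nrow(pm$edges),
               tolerance = 1e-6)
})

test_that("single-site loss matches enumeration and its closed forms", {
  n <- 100L
  z <- potts_model(matrix(0, n, 20), cbind(1:(n - 1), 2:n),
                   matrix(0, n - 1L, 400))
  s <- random_seq(n, 3)
  expect_equal(loss_single_site(z, int_to_aa(s)), n * log(20) / 2000,
               tolerance = 1e-9)

  pm <- make_random_potts(8, seed = 4)
  s8 <- random_seq(8, 44)
  acc <- 0
  for (i in 1:8) acc <- acc - log(brute_site_conditional(pm, s8, i)[s8[i]])
  expect_equal(loss_single_site(pm, int_to_aa(s8)), acc / 2000,
               tolerance = 1e-6)

  h <- matrix(0, 8, 20); h[cbind(1:8, s8)] <- 60
  dom <- potts_model(h, pm$edges, pm$J * 0)
  expect_lt(loss_single_site(dom, int_to_aa(s8)), 1e-6)
})

test_that("gap masking removes sites and incident edges without touching others", {
  pm <- make_random_potts(7, seed = 6)
  s <- random_seq(7, 7)
  mask <- rep(TRUE, 7); mask[3] <- FALSE
  # term-level check: unaffected edges keep their conditional terms
  lf <- loss_edge(pm, int_to_aa(s), mask)
  edges_kept <- which(pm$edges[, 1] != 3 & pm$edges[, 2] != 3)
  acc <- 0
  sub <- as.numeric(mask)
  for (e in edges_kept) {
    i <- pm$edges[e, 1]; j <- pm$edges[e, 2]
    # enumeration with site 3 dropped from every conditioning sum
    En <- matrix(NA_real_, 20, 20)
    for (a in 1:20) for (b in 1:20) {
      s2 <- s; s2[i] <- a; s2[j] <- b
      tot <- 0
      for (k in 1:7) tot <- tot + pm$h[k, s2[k]]
      for (ee in seq_len(nrow(pm$edges))) {
        ii <- pm$edges[ee, 1]; jj <- pm$edges[ee, 2]
        w <- 1
        if (ii != i && ii != j) w <- w * sub[ii]
        if (jj != i && jj != j) w <- w * sub[jj]
        tab <- matrix(pm$J[ee, ], 20, 20, byrow = TRUE)
        tot <- tot + w * tab[s2[ii], s2[jj]]
      }
      En[a, b] <- tot
    }
    p <- exp(En - max(En)); p <- p / sum(p)
    acc <- acc - log(p[s[i], s[j]])
  }
  expect_equal(lf, acc / length(edges_kept), tolerance = 1e-6)
  # zero unmasked edges -> 0 with a warning
  expect_warning(
    val <- loss_edge(pm, int_to_aa(s), rep(FALSE, 7)), "no unmasked edges")
  expect_equal(val, 0)
})

test_that("tape losses match finite differences for h, J, and logits", {
  vof <- pottsfold:::vof
  n <- 6
  pm <- make_random_potts(n, seed = 19, J_sd = 0.3)
  s <- random_seq(n, 20)
  mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  eval_loss <- function(h, J, what) {
    pmx <- potts_model(h, pm$edges, J)
    if (what == "edge") loss_edge(pmx, int_to_aa(s), mask)
    else loss_single_site(pmx, int_to_aa(s), mask)
  }
  for (what in c("edge", "ss")) {
    tape <- pottsfold:::ad_tape()
    href <- pottsfold:::ad_leaf(tape, pm$h)
    Jref <- pottsfold:::ad_leaf(tape, pm$J)
    hJ <- list(h = href, J = Jref, edges = pm$edges)
    loss <- if (what == "edge")
      pottsfold:::tape_loss_edge(hJ, s, mask)$loss
    else pottsfold:::tape_loss_single_site(hJ, s, mask)
    expect_equal(vof(loss)[1, 1], eval_loss(pm$h, pm$J, what),
                 tolerance = 1e-10)
    gradfn <- pottsfold:::ad_backward(loss)
    gh <- gradfn(href); gJ <- gradfn(Jref)
    eps <- 1e-5
    for (t in 1:6) {
      i <- sample(length(pm$h), 1)
      hp <- pm$h; hp[i] <- hp[i] + eps
      hm <- pm$h; hm[i] <- hm[i] - eps
      fd <- (eval_loss(hp, pm$J, what) - eval_loss(hm, pm$J, what)) / (2 * eps)
      expect_equal(gh[i], fd, tolerance = 1e-4)
      j <- sample(length(pm$J), 1)
      Jp <- pm$J; Jp[j] <- Jp[j] + eps
      Jm <- pm$J; Jm[j] <- Jm[j] - eps
      fdJ <- (eval_loss(pm$h, Jp, what) - eval_loss(pm$h, Jm, what)) / (2 * eps)
      expect_equal(gJ[j], fdJ, tolerance = 1e-4)
    }
  }
  # logits gradient of the node loss
  tape <- pottsfold:::ad_tape()
  lgv <- matrix(rnorm(n * 20), n, 20)
  lref <- pottsfold:::ad_leaf(tape, lgv)
  loss <- pottsfold:::tape_loss_node(lref, s, mask)
  gl <- pottsfold:::ad_backward(loss)(lref)
  eps <- 1e-5
  for (t in 1:6) {
    i <- sample(length(lgv), 1)
    lp <- lgv; lp[i] <- lp[i] + eps
    lm <- lgv; lm[i] <- lm[i] - eps
    fd <- (loss_node(lp, s, mask) - loss_node(lm, s, mask)) / (2 * eps)
    expect_equal(gl[i], fd, tolerance = 1e-4)
  }
})

test_that("the full-variant total is exactly L_V + L_E with equal weights", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(10, "helix", 2)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 6)
  ord <- decoding_order(10, 0, g$id)
  lb <- loss_msa(p, cfg, g, ord, int_to_aa(random_seq(10, 2)))
  expect_identical(lb$L_total, lb$L_V + lb$L_E)
  expect_gt(lb$L_V, 0); expect_gt(lb$L_E, 0)
})

test_that("MSA loss degenerates correctly and handles all-gap rows", {
  cfg <- tiny_cfg()
  bb <- make_synthetic_backbone(9, "strand", 3)
  g <- build_knn_graph(bb, k = cfg$k, n_rbf = cfg$n_rbf,
                       relpos_clip = cfg$relpos_clip)
  p <- init_model_params(cfg, seed = 9)
  ord <- decoding_order(9, 0, g$id)
  nat <- int_to_aa(random_seq(9, 11))
  single <- loss_msa(p, cfg, g, ord, nat)
  copies <- loss_msa(p, cfg, g, ord, rep(nat, 4))
  expect_equal(copies$L_total, single$L_total, tolerance = 1e-12)
  allgap <- loss_msa(p, cfg, g, ord, c(nat, strrep("-", 9)))
  expect_equal(allgap$L_total, single$L_total, tolerance = 1e-12)
  expect_equal(allgap$all_gap_rows, 1L)
  expect_error(loss_msa(p, cfg, g, ord, substr(nat, 1, 5)), "unaligned")
})
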