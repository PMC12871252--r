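test_that("potts energy matches direct sums and the brute-force oracle", {
  # hand-built 2-site model: h1(A)=1, h2(C)=-0.5, J12(A,C)=0.25
  h <- matrix(0, 2, 20)
  h[1, aa_to_int("A")] <- 1
  h[2, aa_to_int("C")] <- -0.5
  J <- matrix(0, 1, 400)
  J[1, (aa_to_int("A") - 1) * 20 + aa_to_int("C")] <- 0.25
  pm <- potts_model(h, matrix(c(1L, 2L), 1), J)
  expect_equal(potts_energy(pm, "AC"), 0.75)

  z <- potts_model(matrix(0, 4, 20), t(combn(4, 2)), matrix(0, 6, 400))
  expect_equal(potts_energy(z, "ACDE"), 0)

  pm8 <- make_random_potts(8, seed = 21)
  for (rep in 1:5) {
    s <- random_seq(8, 30 + rep)
    expect_equal(potts_energy(pm8, int_to_aa(s)), brute_energy(pm8, s),
                 tolerance = 1e-12)
  }
  expect_error(potts_energy(pm8, "ACD"), "length")
  expect_error(potts_energy(pm8, "ACDEFGH!"), "unknown")
})

test_that("pair and site conditionals equal full-sequence enumeration", {
  for (trial in 1:5) {
    n <- sample(4:9, 1)
    pm <- make_random_potts(n, seed = 100 + trial)
    s <- random_seq(n, 200 + trial)
    i <- sample(n, 1); j <- sample(setdiff(seq_len(n), i), 1)
    expect_lt(max(abs(pair_conditional(pm, int_to_aa(s), i, j) -
                        brute_pair_conditional(pm, s, i, j))), 1e-9)
    expect_lt(max(abs(site_conditional(pm, int_to_aa(s), i) -
                        brute_site_conditional(pm, s, i))), 1e-9)
    expect_equal(sum(pair_conditional(pm, int_to_aa(s), i, j)), 1,
                 tolerance = 1e-9)
  }
  # zero model: uniform conditionals
  z <- potts_model(matrix(0, 3, 20), t(combn(3, 2)), matrix(0, 3, 400))
  expect_equal(unname(pair_conditional(z, "ACD", 1, 2)),
               matrix(1 / 400, 20, 20))
  expect_equal(unname(site_conditional(z, "ACD", 2)), rep(1 / 20, 20))
  expect_error(pair_conditional(make_random_potts(5, edges = matrix(c(1L, 2L), 1),
                                                  seed = 1), "ACDEF", 1, 3),
               "not an edge")
})

test_that("J storage is exactly symmetric under (i,j,a,b) <-> (j,i,b,a)", {
  pm <- make_random_potts(6, seed = 9)
  for (t in 1:20) {
    i <- sample(6, 1); j <- sample(setdiff(1:6, i), 1)
    a <- sample(20, 1); b <- sample(20, 1)
    expect_identical(potts_pair_energy(pm, i, j, a, b),
                     potts_pair_energy(pm, j, i, b, a))
  }
})

test_that("incremental ddG equals the two-path full-energy difference", {
  pm <- make_random_potts(10, seed = 55)
  s <- random_seq(10, 77)
  for (t in 1:50) {
    i <- sample(10, 1)
    mut <- sample(setdiff(1:20, s[i]), 1)
    mr <- mutation_record(AA20[s[i]], i, AA20[mut])
    s2 <- s; s2[i] <- mut
    expect_equal(ddg_potts(pm, int_to_aa(s), mr),
                 potts_energy(pm, int_to_aa(s2)) - potts_energy(pm, int_to_aa(s)),
                 tolerance = 1e-9)
  }
  # identity mutation and zero model give exactly 0
  expect_equal(ddg_potts(pm, int_to_aa(s),
                         mutation_record(AA20[s[3]], 3, AA20[s[3]])), 0)
  z <- potts_model(matrix(0, 10, 20), pm$edges, pm$J * 0)
  expect_equal(ddg_potts(z, int_to_aa(s),
                         mutation_record(AA20[s[4]], 4, "W")), 0)
  # wild-type mismatch is a flagged error
  bad <- mutation_record(AA20[(s[2] %% 20) + 1], 2, "A")
  expect_error(ddg_potts(pm, int_to_aa(s), bad), class = "pf_wt_mismatch")
})

test_that("gauge shifts of h leave every ddG unchanged", {
  pm <- make_random_potts(7, seed = 13)
  pm2 <- pm
  pm2$h[3, ] <- pm2$h[3, ] + 1.7   # constant shift at one site
  s <- random_seq(7, 4)
  expect_equal(potts_energy(pm2, int_to_aa(s)),
               potts_energy(pm, int_to_aa(s)) + 1.7, tolerance = 1e-9)
  for (t in 1:20) {
    i <- sample(7, 1); mut <- sample(setdiff(1:20, s[i]), 1)
    mr <- mutation_record(AA20[s[i]], i, AA20[mut])
    expect_equal(ddg_potts(pm, int_to_aa(s), mr),
                 ddg_potts(pm2, int_to_aa(s), mr), tolerance = 1e-9)
  }
})

test_that("neighbour ablation keeps per-site nearest/furthest sets", {
  bb <- make_synthetic_backbone(12, "hairpin", 3)
  pm <- make_random_potts(12, seed = 31)
  s <- int_to_aa(random_seq(12, 8))

  full <- ablate_neighbors(pm, bb, m = 11, mode = "nearest")
  expect_equal(potts_energy(full, s), potts_energy(pm, s))
  none <- ablate_neighbors(pm, bb, m = 0, mode = "nearest")
  expect_equal(nrow(none$edges), 0L)
  expect_equal(potts_energy(none, s), sum(pm$h[cbind(1:12, aa_to_int(s))]))
  expect_error(ablate_neighbors(pm, bb, m = 20), "m must lie")

  # per-site nearest-m and furthest-(k-m) retained sets are complementary:
  # under "either" the union covers every edge; under "both" the
  # intersection is empty
  key <- function(x) paste(x$edges[, 1], x$edges[, 2])
  for (m in c(3, 6)) {
    near_e <- ablate_neighbors(pm, bb, m, "nearest", orphan = "either")
    far_e <- ablate_neighbors(pm, bb, 11 - m, "furthest", orphan = "either")
    expect_setequal(union(key(near_e), key(far_e)), key(pm))
    near_b <- ablate_neighbors(pm, bb, m, "nearest", orphan = "both")
    far_b <- ablate_neighbors(pm, bb, 11 - m, "furthest", orphan = "both")
    expect_length(intersect(key(near_b), key(far_b)), 0)
  }
  # "either" keeps a superset of "both"
  e1 <- ablate_neighbors(pm, bb, 4, "nearest", orphan = "either")
  e2 <- ablate_neighbors(pm, bb, 4, "nearest", orphan = "both")
  expect_gte(nrow(e1$edges), nrow(e2$edges))
})

test_that("serialization round-trips bit-exactly and rejects bad files", {
  pm <- make_random_potts(9, seed = 77)
  tf <- tempfile(fileext = ".potts")
  save_potts(pm, tf)
  pm2 <- load_potts(tf)
  for (t in 1:100) {
    s <- int_to_aa(random_seq(9, 1000 + t))
    expect_identical(potts_energy(pm, s), potts_energy(pm2, s))
  }
  # truncated file -> format error, not a garbage model
  raw <- readBin(tf, "raw", file.info(tf)$size)
  tf2 <- tempfile()
  writeBin(raw[1:20], tf2)
  expect_error(load_potts(tf2), "not a readable")
  # foreign RDS -> format error
  tf3 <- tempfile(); saveRDS(list(a = 1), tf3)
  expect_error(load_potts(tf3), "format error")
  # alphabet mismatch -> explicit error
  obj <- readRDS(tf); obj$alphabet <- paste(rev(aa_alphabet()), collapse = "")
  tf4 <- tempfile(); saveRDS(obj, tf4)
  expect_error(load_potts(tf4), "alphabet")
})

test_that("mutation strings parse and reject malformed input", {
  mr <- parse_mutation("A123G")
  expect_equal(mr$wt_aa, "A"); expect_equal(mr$position, 123L)
  expect_equal(mr$mut_aa, "G")
  expect_error(parse_mutation("A12"), "cannot parse")
  expect_error(parse_mutation("Z12G"), "cannot parse")  # Z not an amino acid
})
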