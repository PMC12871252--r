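#' Construct a Potts model over the 20-letter amino-acid alphabet
#'
#' A Potts model scores a sequence `s` of length `n` as
#' `H(s) = sum_i h_i(s[i]) + sum_(i,j) J_ij(s[i], s[j])`, the pair sum
#' running once over each unordered edge. The convention throughout this
#' package is that `H` is a log-compatibility score: higher is more
#' favourable, and `softmax(H)` over sequences is a probability. Users who
#' want a physical energy should negate.
#'
#' Pair tables are stored once per unordered edge `(i < j)` as a flattened
#' 20 x 20 table with index `(a - 1) * 20 + b`, `a` the residue at the
#' lower site. Querying `(i, j, a, b)` and `(j, i, b, a)` therefore returns
#' the identical stored value.
#'
#' @param h `n x 20` matrix of self-energies.
#' @param edges `E x 2` integer matrix of site pairs (any order; stored
#'   with the lower site first; self-pairs and duplicates are errors).
#' @param J `E x 400` matrix of flattened pair tables, row order matching
#'   `edges`.
#' @param ca_dist Optional numeric vector of CA distances per edge
#'   (Angstrom), used by [ablate_neighbors()].
#' @return An object of class `potts_model`.
#' @export
potts_model <- function(h, edges, J, ca_dist = NULL) {
  h <- as.matrix(h)
  n <- nrow(h)
  stopifnot(ncol(h) == 20L)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
    J <- matrix(numeric(0), 0L, 400L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  J <- as.matrix(J)
  stopifnot(nrow(J) == nrow(edges), ncol(J) == 400L || nrow(J) == 0L)
  if (any(edges[, 1] == edges[, 2])) stop("self-pairs are not allowed in edges")
  if (any(edges < 1L) || any(edges > n)) stop("edge site index out of range")
  flip <- edges[, 1] > edges[, 2]
  if (any(flip)) {
    edges[flip, ] <- edges[flip, 2:1]
    # transposing a flattened a-major 20x20 table = index permutation
    J[flip, ] <- J[flip, .j_transpose_perm(), drop = FALSE]
  }
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  if (!all(is.finite(h)) || (nrow(J) > 0L && !all(is.finite(J))))
    stop("all energies must be finite")
  structure(list(n_sites = n, alphabet = .AA, h = h, edges = edges, J = J,
                 ca_dist = ca_dist),
            class = "potts_model")
}

.j_transpose_perm <- function(q = 20L) {
  # perm such that Jt[idx(a,b)] = J[idx(b,a)]
  ab <- expand.grid(b = seq_len(q), a = seq_len(q))   # column-fast b
  (ab$b - 1L) * q + ab$a
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("<potts_model: %d sites, %d undirected edges>\n",
              x$n_sites, nrow(x$edges)))
  invisible(x)
}

#' Pair-energy accessor
#'
#' Returns `J_ij(a, b)` with the symmetry guarantee
#' `J_ij(a, b) == J_ji(b, a)` exactly. Non-edges return 0.
#'
#' @param pm A [potts_model()].
#' @param i,j Site indices.
#' @param a,b 1-based alphabet indices (residue at `i`, residue at `j`).
#' @export
potts_pair_energy <- function(pm, i, j, a, b) {
  if (i > j) { tmp <- i; i <- j; j <- tmp; tmp <- a; a <- b; b <- tmp }
  e <- which(pm$edges[, 1] == i & pm$edges[, 2] == j)
  if (length(e) == 0L) return(0)
  pm$J[e, (a - 1L) * 20L + b]
}

seq_to_int <- function(pm, sequence) {
  s <- aa_to_int(sequence)
  if (length(s) != pm$n_sites)
    stop("sequence length ", length(s), " != n_sites ", pm$n_sites)
  s
}

#' Potts score of a full sequence
#'
#' `H(s) = sum_i h_i(s[i]) + sum_(i,j in edges) J_ij(s[i], s[j])`, each
#' unordered pair counted once. Higher = more favourable.
#'
#' @param pm A [potts_model()].
#' @param sequence Amino-acid string of length `n_sites`.
#' @return Scalar score.
#' @export
potts_energy <- function(pm, sequence) {
  s <- seq_to_int(pm, sequence)
  hsum <- sum(pm$h[cbind(seq_len(pm$n_sites), s)])
  if (nrow(pm$edges) == 0L) return(hsum)
  si <- s[pm$edges[, 1]]; sj <- s[pm$edges[, 2]]
  hsum + sum(pm$J[cbind(seq_len(nrow(pm$edges)), (si - 1L) * 20L + sj)])
}

# Per-site interaction fields: Phi[i, a] = sum_{j in N(i)} w[j] * J_ij(a, s[j]).
# `weights` (default all 1) down-weights conditioning residues, e.g. for gap
# masking where a gapped neighbour contributes nothing.
potts_fields <- function(pm, s, weights = NULL) {
  n <- pm$n_sites
  Phi <- matrix(0, n, 20L)
  E <- nrow(pm$edges)
  if (E == 0L) return(Phi)
  if (is.null(weights)) weights <- rep(1, n)
  i <- pm$edges[, 1]; j <- pm$edges[, 2]
  eidx <- seq_len(E)
  Ji <- vapply(seq_len(20L), function(a) pm$J[cbind(eidx, (a - 1L) * 20L + s[j])],
               numeric(E))                       # E x 20, contribution to site i
  Jj <- vapply(seq_len(20L), function(b) pm$J[cbind(eidx, (s[i] - 1L) * 20L + b)],
               numeric(E))                       # E x 20, contribution to site j
  Ji <- Ji * weights[j]
  Jj <- Jj * weights[i]
  acc_i <- rowsum(Ji, group = i, reorder = FALSE)
  Phi[as.integer(rownames(acc_i)), ] <- Phi[as.integer(rownames(acc_i)), ] + acc_i
  acc_j <- rowsum(Jj, group = j, reorder = FALSE)
  Phi[as.integer(rownames(acc_j)), ] <- Phi[as.integer(rownames(acc_j)), ] + acc_j
  Phi
}

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Single-site conditional distribution
#'
#' Probability over the 20 residues at site `i` given the rest of the
#' sequence: `softmax_a( h_i(a) + sum_{j in N(i)} J_ij(a, s[j]) )`. The
#' identity at site `i` itself never enters the conditioning.
#'
#' @param pm A [potts_model()].
#' @param sequence Context sequence (length `n_sites`).
#' @param i Site index.
#' @return Named numeric vector of 20 probabilities summing to 1.
#' @export
site_conditional <- function(pm, sequence, i) {
  s <- seq_to_int(pm, sequence)
  if (i < 1L || i > pm$n_sites) stop("site index out of range")
  Phi <- potts_fields(pm, s)
  p <- softmax_vec(pm$h[i, ] + Phi[i, ])
  names(p) <- .AA
  p
}

#' Pair conditional distribution over an edge
#'
#' Joint probability over all 400 residue pairs at edge `(i, j)` given the
#' native residues at all other sites:
#' `softmax_(a,b)( h_i(a) + h_j(b) + J_ij(a,b) + sum_{k in N(i), k != j}
#' J_ik(a, s[k]) + sum_{k in N(j), k != i} J_jk(b, s[k]) )`.
#'
#' @param pm A [potts_model()].
#' @param sequence Context sequence.
#' @param i,j Sites joined by an edge (error otherwise).
#' @return `20 x 20` matrix, rows = residue at `i`, cols = residue at `j`,
#'   summing to 1.
#' @export
pair_conditional <- function(pm, sequence, i, j) {
  s <- seq_to_int(pm, sequence)
  lo <- min(i, j); hi <- max(i, j)
  e <- which(pm$edges[, 1] == lo & pm$edges[, 2] == hi)
  if (length(e) == 0L) stop("(", i, ",", j, ") is not an edge of the model")
  Phi <- potts_fields(pm, s)
  Jtab <- matrix(pm$J[e, ], 20L, 20L, byrow = TRUE)  # [a_lo, b_hi]
  u_lo <- pm$h[lo, ] + Phi[lo, ] - Jtab[, s[hi]]
  u_hi <- pm$h[hi, ] + Phi[hi, ] - Jtab[s[lo], ]
  En <- outer(u_lo, u_hi, "+") + Jtab
  p <- exp(En - max(En)); p <- p / sum(p)
  if (i > j) p <- t(p)
  dimnames(p) <- list(.AA, .AA)
  p
}

#' Mutation record
#'
#' @param wt_aa Wild-type one-letter residue.
#' @param position 1-based position (sequence index, or author numbering
#'   when resolved through a structure; see [score_mutations()]).
#' @param mut_aa Mutant one-letter residue.
#' @param ddG_expt Experimental ddG (optional; any consistent unit).
#' @param protein_id Optional identifier.
#' @return Object of class `mutation_record`.
#' @export
mutation_record <- function(wt_aa, position, mut_aa, ddG_expt = NA_real_,
                            protein_id = NA_character_) {
  structure(list(wt_aa = wt_aa, position = as.integer(position),
                 mut_aa = mut_aa, ddG_expt = ddG_expt,
                 protein_id = protein_id),
            class = "mutation_record")
}

#' Parse a mutation string like "A123G"
#'
#' @param x Character scalar: wild-type residue, position, mutant residue.
#' @param protein_id Optional identifier carried into the record.
#' @return A [mutation_record()].
#' @export
parse_mutation <- function(x, protein_id = NA_character_) {
  m <- regmatches(x, regexec("^([A-Y])([0-9]+)([A-Y])$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse mutation string: '", x, "'")
  mutation_record(m[2], as.integer(m[3]), m[4], protein_id = protein_id)
}

#' Incremental Potts ddG of a point mutation
#'
#' `H(s_mut) - H(s_wt)` computed incrementally:
#' `h_i(mut) - h_i(wt) + sum_{j in N(i)} (J_ij(mut, s[j]) - J_ij(wt, s[j]))`.
#' Positive values mean the mutation is predicted more favourable
#' (stabilizing) under the score convention of [potts_model()].
#'
#' @param pm A [potts_model()].
#' @param wt_sequence Wild-type sequence.
#' @param mutation A [mutation_record()] (position = 1-based sequence index).
#' @param fields Optional precomputed [potts_fields()] for `wt_sequence`
#'   (batch scoring reuses one field computation across mutations).
#' @return Scalar ddG (score units).
#' @export
ddg_potts <- function(pm, wt_sequence, mutation, fields = NULL) {
  s <- seq_to_int(pm, wt_sequence)
  i <- mutation$position
  if (i < 1L || i > pm$n_sites) stop("mutation position out of range")
  wt <- aa_to_int(mutation$wt_aa); mut <- aa_to_int(mutation$mut_aa)
  if (s[i] != wt)
    stop(structure(class = c("pf_wt_mismatch", "error", "condition"),
                   list(message = sprintf(
                     "wild-type mismatch at position %d: sequence has %s, record says %s",
                     i, .AA[s[i]], mutation$wt_aa), call = NULL)))
  if (is.null(fields)) fields <- potts_fields(pm, s)
  (pm$h[i, mut] + fields[i, mut]) - (pm$h[i, wt] + fields[i, wt])
}

#' Restrict pair terms to each site's m nearest (or furthest) neighbours
#'
#' Inference-time ablation: for each site, rank its Potts partners by CA
#' distance and keep only pair tables to the `m` nearest (`mode =
#' "nearest"`) or `m` furthest (`mode = "furthest"`). By default an
#' unordered pair survives if *either* endpoint retains it, so "each
#' residue keeps information about its m nearest neighbours" holds
#' literally; `orphan = "both"` drops pairs unless both endpoints retain
#' them.
#'
#' @param pm A [potts_model()] with per-edge `ca_dist` (as produced by
#'   [extract_potts()]), or pass `bb` to recompute distances.
#' @param bb Optional [backbone()] supplying CA coordinates.
#' @param m Number of neighbours to retain per site, `0 <= m <= k`.
#' @param mode `"nearest"` or `"furthest"`.
#' @param orphan `"either"` (default) or `"both"`.
#' @return A new [potts_model()] with the reduced edge set.
#' @export
ablate_neighbors <- function(pm, bb = NULL, m, mode = c("nearest", "furthest"),
                             orphan = c("either", "both")) {
  mode <- match.arg(mode)
  orphan <- match.arg(orphan)
  E <- nrow(pm$edges)
  deg <- tabulate(c(pm$edges[, 1], pm$edges[, 2]), nbins = pm$n_sites)
  k <- max(deg, 0L)
  if (!is.numeric(m) || m < 0 || m > k)
    stop("m must lie in [0, ", k, "] for this model")
  if (E == 0L || m == k) {
    if (m == k) return(pm)
  }
  dist <- pm$ca_dist
  if (!is.null(bb)) {
    ca <- bb$coords[, "CA", ]; dim(ca) <- c(bb$n, 3)
    dist <- sqrt(rowSums((ca[pm$edges[, 1], , drop = FALSE] -
                            ca[pm$edges[, 2], , drop = FALSE])^2))
  }
  if (is.null(dist)) stop("no CA distances available: supply `bb`")
  keep_site <- matrix(FALSE, pm$n_sites, E)
  for (i in seq_len(pm$n_sites)) {
    eids <- which(pm$edges[, 1] == i | pm$edges[, 2] == i)
    if (length(eids) == 0L) next
    ord <- order(dist[eids], eids)               # ascending, stable
    if (mode == "furthest") ord <- rev(ord)
    take <- eids[ord][seq_len(min(m, length(eids)))]
    keep_site[i, take] <- TRUE
  }
  kept_i <- keep_site[cbind(pm$edges[, 1], seq_len(E))]
  kept_j <- keep_site[cbind(pm$edges[, 2], seq_len(E))]
  keep <- if (orphan == "either") kept_i | kept_j else kept_i & kept_j
  potts_model(pm$h, pm$edges[keep, , drop = FALSE], pm$J[keep, , drop = FALSE],
              ca_dist = dist[keep])
}

#' Save / load a Potts model
#'
#' Single-file container (RDS) holding the named arrays `h`, `edges`, `J`,
#' the alphabet string and `n_sites`. `load_potts(save_potts(m))`
#' reproduces every energy bit-exactly. A truncated or foreign file raises
#' a format error; an alphabet-order mismatch is an explicit error.
#'
#' @param pm A [potts_model()].
#' @param path File path.
#' @return `save_potts`: `path` invisibly. `load_potts`: a [potts_model()].
#' @export
save_potts <- function(pm, path) {
  stopifnot(inherits(pm, "potts_model"))
  saveRDS(list(format = "pottsfold_potts", version = 1L,
               alphabet = paste(pm$alphabet, collapse = ""),
               n_sites = pm$n_sites, h = pm$h, edges = pm$edges, J = pm$J,
               ca_dist = pm$ca_dist),
          path)
  invisible(path)
}

#' @rdname save_potts
#' @export
load_potts <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable Potts container: ", conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "pottsfold_potts"))
    stop("format error: '", path, "' is not a pottsfold Potts container")
  need <- c("alphabet", "n_sites", "h", "edges", "J")
  if (!all(need %in% names(obj)))
    stop("format error: missing fields ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  if (!identical(obj$alphabet, paste(.AA, collapse = "")))
    stop("alphabet-order mismatch: file declares '", obj$alphabet, "'")
  potts_model(obj$h, obj$edges, obj$J, ca_dist = obj$ca_dist)
}

#' Random Potts model fixture
#'
#' Gaussian self- and pair-energies over a given edge set (default: all
#' pairs). Intended for oracle tests and demonstrations.
#'
#' @param n_sites Number of sites.
#' @param edges Optional `E x 2` matrix; default fully connected.
#' @param h_sd,J_sd Standard deviations of the energy entries.
#' @param seed Integer seed.
#' @return A [potts_model()].
#' @export
make_random_potts <- function(n_sites, edges = NULL, h_sd = 1, J_sd = 0.5,
                              seed = 1L) {
  if (is.null(edges)) edges <- t(utils::combn(n_sites, 2L))
  with_seed(seed, {
    h <- matrix(stats::rnorm(n_sites * 20L, 0, h_sd), n_sites, 20L)
    J <- matrix(stats::rnorm(nrow(edges) * 400L, 0, J_sd), nrow(edges), 400L)
    potts_model(h, edges, J)
  })
}
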