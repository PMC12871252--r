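#' Radial basis expansion of a distance
#'
#' `activation_m = exp(-((d - center_m) / width)^2)`. Values lie in (0, 1],
#' peaking at 1 exactly when `d` equals a center.
#'
#' @param d Numeric vector of distances (Angstrom).
#' @param centers Numeric vector of RBF centers (Angstrom).
#' @param width Positive width (Angstrom).
#' @return Matrix `length(d) x length(centers)`.
#' @export
rbf_expand <- function(d, centers, width) {
  if (!is.numeric(width) || width <= 0) stop("width must be > 0")
  z <- outer(d, centers, function(x, m) exp(-((x - m) / width)^2))
  z
}

default_rbf_centers <- function(n_rbf = 16L, d_min = 2, d_max = 22) {
  seq(d_min, d_max, length.out = n_rbf)
}

#' Build the k-nearest-neighbour residue graph with input features
#'
#' Nodes are residues; each valid node is connected to its `k_effective =
#' min(k, n_valid - 1)` nearest valid neighbours by CA distance (ascending,
#' ties broken by lower residue index). Every directed edge carries RBF
#' expansions of all 25 ordered interatomic distances among
#' \{N, CA, C, O, virtual C-beta\}, a clipped signed sequence-offset one-hot,
#' and a same-chain indicator. A self-edge (i -> i) is kept per node; its
#' embedding later supplies the Potts self-energy table. Node features are
#' initialized to null vectors by the network, so the graph stores only
#' edge features.
#'
#' @param bb A [backbone()] object.
#' @param k Neighbours per node (default 48).
#' @param n_rbf Number of Gaussian centers (default 16, evenly spaced on
#'   2--22 Angstrom; width = spacing).
#' @param relpos_clip Sequence-offset clip (default 32).
#' @return An object of class `residue_graph` with fields `n`, `k_eff`,
#'   `neighbors` (`n x k_eff`, NA-padded for invalid nodes), `edge_feat`
#'   (`(n * k_eff) x D`, row `(i-1)*k_eff + s` = edge i -> neighbors[i, s]),
#'   `self_feat` (`n x D`), `edge_mask`, `ca_nbr_dist`, `valid`, `chain`.
#' @export
build_knn_graph <- function(bb, k = 48L, n_rbf = 16L, relpos_clip = 32L) {
  stopifnot(inherits(bb, "backbone"))
  n <- bb$n
  valid <- bb$valid
  n_valid <- sum(valid)
  if (n_valid < 2L) stop("need at least 2 valid residues to build a graph")
  k_eff <- min(as.integer(k), n_valid - 1L)

  cb <- place_virtual_cbeta(bb)
  atoms <- list(N = bb$coords[, "N", ], CA = bb$coords[, "CA", ],
                C = bb$coords[, "C", ], O = bb$coords[, "O", ], CB = cb)
  for (nm in names(atoms)) dim(atoms[[nm]]) <- c(n, 3)

  ca <- atoms$CA
  D <- as.matrix(stats::dist(ca))
  D[, !valid] <- Inf
  diag(D) <- Inf

  neighbors <- matrix(NA_integer_, n, k_eff)
  ca_nbr_dist <- matrix(NA_real_, n, k_eff)
  for (i in which(valid)) {
    # ascending distance, tie-break by lower node id (order() is stable on
    # the secondary index)
    ord <- order(D[i, ], seq_len(n))[seq_len(k_eff)]
    neighbors[i, ] <- ord
    ca_nbr_dist[i, ] <- D[i, ord]
  }

  centers <- default_rbf_centers(n_rbf)
  width <- centers[2] - centers[1]
  n_edge <- n * k_eff
  src <- rep(seq_len(n), each = k_eff)
  dst <- as.integer(t(neighbors))
  edge_ok <- !is.na(dst)
  dst_safe <- ifelse(edge_ok, dst, src)

  edge_feat <- edge_feature_block(atoms, src, dst_safe, centers, width,
                                  bb$chain, relpos_clip)
  edge_feat[!edge_ok, ] <- 0
  self_feat <- edge_feature_block(atoms, seq_len(n), seq_len(n), centers, width,
                                  bb$chain, relpos_clip)
  self_feat[!valid, ] <- 0

  structure(list(n = n, k_eff = k_eff, neighbors = neighbors,
                 edge_feat = edge_feat, self_feat = self_feat,
                 edge_mask = as.numeric(edge_ok), ca_nbr_dist = ca_nbr_dist,
                 valid = valid, chain = bb$chain, id = bb$id,
                 n_rbf = n_rbf, relpos_clip = as.integer(relpos_clip)),
            class = "residue_graph")
}

# 25 ordered atom-pair RBF blocks + relative-position one-hot + same-chain bit
edge_feature_block <- function(atoms, src, dst, centers, width, chain, clip) {
  nm <- c("N", "CA", "C", "O", "CB")
  n_edge <- length(src)
  blocks <- vector("list", 25L)
  bi <- 0L
  for (a1 in nm) for (a2 in nm) {
    bi <- bi + 1L
    dd <- sqrt(rowSums((atoms[[a1]][src, , drop = FALSE] -
                          atoms[[a2]][dst, , drop = FALSE])^2))
    dd[!is.finite(dd)] <- 0
    blocks[[bi]] <- rbf_expand(dd, centers, width)
  }
  off <- pmax(pmin(dst - src, clip), -clip)
  rel <- matrix(0, n_edge, 2L * clip + 1L)
  rel[cbind(seq_len(n_edge), off + clip + 1L)] <- 1
  same_chain <- as.numeric(chain[src] == chain[dst])
  # different-chain edges get the center (offset 0) bucket zeroed out:
  # sequence separation is meaningless across chains
  cross <- same_chain == 0
  if (any(cross)) {
    rel[cross, ] <- 0
  }
  cbind(do.call(cbind, blocks), rel, same_chain)
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph '%s': %d nodes, k_eff=%d, %d edge features>\n",
              x$id, x$n, x$k_eff, ncol(x$edge_feat)))
  invisible(x)
}

# dimension of the edge feature vector for a given config
edge_feature_dim <- function(n_rbf = 16L, relpos_clip = 32L) {
  25L * as.integer(n_rbf) + (2L * as.integer(relpos_clip) + 1L) + 1L
}
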