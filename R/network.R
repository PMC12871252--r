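#' Model configuration
#'
#' Hyperparameters of the graph network. The defaults are the published
#' recipe: hidden dimensionality 128, three encoder and three decoder
#' message-passing layers, k = 48 neighbours, dropout 10%.
#'
#' @param hidden_dim Embedding width.
#' @param encoder_layers,decoder_layers Number of MPNN layers.
#' @param k Neighbours per node in the residue graph.
#' @param dropout Dropout rate used in training mode.
#' @param variant One of `"full"` (node + edge losses, decoder + Potts
#'   head), `"potts_only"` (Potts head only, edge loss), `"potts_single"`
#'   (Potts head only, single-site conditional loss), `"node_only"`
#'   (decoder only, no Potts head).
#' @param n_rbf,rbf_min,rbf_max Radial-basis layout (16 Gaussians evenly
#'   spaced on 2--22 Angstrom, width = spacing).
#' @param relpos_clip Signed sequence-offset clip for the relative position
#'   one-hot.
#' @param ff_mult Width multiplier of the position-wise feed-forward blocks.
#' @param activation `"gelu"` (default) or `"relu"` for the MLP blocks.
#' @param potts_head_bias Whether the Potts head linear layer has a bias.
#' @return A list of class `pf_config`.
#' @export
model_config <- function(hidden_dim = 128L, encoder_layers = 3L,
                         decoder_layers = 3L, k = 48L, dropout = 0.10,
                         variant = c("full", "potts_only", "potts_single",
                                     "node_only"),
                         n_rbf = 16L, rbf_min = 2, rbf_max = 22,
                         relpos_clip = 32L, ff_mult = 4L,
                         activation = c("gelu", "relu"),
                         potts_head_bias = TRUE) {
  variant <- match.arg(variant)
  activation <- match.arg(activation)
  stopifnot(hidden_dim > 0, encoder_layers > 0, decoder_layers > 0, k > 0,
            dropout >= 0, dropout < 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 encoder_layers = as.integer(encoder_layers),
                 decoder_layers = as.integer(decoder_layers),
                 k = as.integer(k), dropout = dropout, alphabet_size = 20L,
                 variant = variant, n_rbf = as.integer(n_rbf),
                 rbf_min = rbf_min, rbf_max = rbf_max,
                 relpos_clip = as.integer(relpos_clip),
                 ff_mult = as.integer(ff_mult), activation = activation,
                 potts_head_bias = potts_head_bias),
            class = "pf_config")
}

has_decoder <- function(cfg) cfg$variant %in% c("full", "node_only")
has_potts_head <- function(cfg) cfg$variant != "node_only"

xavier <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(2 / (fi + fo))), fi, fo)

mlp3_params <- function(din, d) list(
  W1 = xavier(din, d), b1 = numeric(d),
  W2 = xavier(d, d),   b2 = numeric(d),
  W3 = xavier(d, d),   b3 = numeric(d))

ff_params <- function(d, mult) list(
  W1 = xavier(d, d * mult), b1 = numeric(d * mult),
  W2 = xavier(d * mult, d), b2 = numeric(d))

ln_params <- function(d) list(g = rep(1, d), b = numeric(d))

#' Initialize network parameters
#'
#' Xavier-initialized weights for the configured variant. Variants without
#' a decoder (`potts_only`, `potts_single`) carry no decoder parameters at
#' all (so no optimizer state for them); `node_only` carries no Potts head.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return Nested named list of parameter matrices.
#' @export
init_model_params <- function(cfg, seed = 0L) {
  d <- cfg$hidden_dim
  D <- edge_feature_dim(cfg$n_rbf, cfg$relpos_clip)
  with_seed(derive_seed(seed, "init"), {
    p <- list(embed = list(W = xavier(D, d), b = numeric(d), ln = ln_params(d)),
              enc = lapply(seq_len(cfg$encoder_layers), function(l) list(
                msg = mlp3_params(3L * d, d), ln1 = ln_params(d),
                ff = ff_params(d, cfg$ff_mult), ln2 = ln_params(d),
                emsg = mlp3_params(3L * d, d), ln3 = ln_params(d))))
    if (has_potts_head(cfg))
      p$potts_head <- list(W = xavier(d, 400L),
                           b = if (cfg$potts_head_bias) numeric(400L) else NULL)
    if (has_decoder(cfg)) {
      p$seq_embed <- list(W = xavier(20L, d))
      p$dec <- lapply(seq_len(cfg$decoder_layers), function(l) list(
        msg = mlp3_params(4L * d, d), ln1 = ln_params(d),
        ff = ff_params(d, cfg$ff_mult), ln2 = ln_params(d)))
      p$out <- list(W = xavier(d, 20L), b = numeric(20L))
    }
    p
  })
}

# flatten the per-node edge arrays of a residue_graph into the layout the
# network consumes: per node, one self edge followed by its k_eff neighbours
graph_arrays <- function(graph) {
  n <- graph$n; k <- graph$k_eff
  kk <- k + 1L
  src <- rep(seq_len(n), each = kk)
  dstm <- cbind(seq_len(n), graph$neighbors)
  dst <- as.integer(t(dstm))
  mask <- c(t(cbind(as.numeric(graph$valid),
                    matrix(graph$edge_mask, n, k, byrow = TRUE))))
  dst[is.na(dst)] <- src[is.na(dst)]
  feat <- matrix(0, n * kk, ncol(graph$edge_feat))
  self_rows <- (seq_len(n) - 1L) * kk + 1L
  nbr_rows <- setdiff(seq_len(n * kk), self_rows)
  feat[self_rows, ] <- graph$self_feat
  feat[nbr_rows, ] <- graph$edge_feat
  cnt <- rowsum(mask, group = src, reorder = FALSE)[, 1]
  cnt <- pmax(cnt, 1)
  list(n = n, kk = kk, src = src, dst = dst, mask = mask, feat = feat,
       self_rows = self_rows, nbr_rows = nbr_rows, inv_cnt = 1 / cnt)
}

cfg_act <- function(cfg) if (identical(cfg$activation, "relu")) ad_relu else ad_gelu

run_mlp3 <- function(p, x, act = ad_gelu) {
  h <- act(ad_linear(x, p$W1, p$b1))
  h <- act(ad_linear(h, p$W2, p$b2))
  ad_linear(h, p$W3, p$b3)
}

run_ff <- function(p, x, act = ad_gelu) {
  h <- act(ad_linear(x, p$W1, p$b1))
  ad_linear(h, p$W2, p$b2)
}

check_finite <- function(x, where) {
  v <- vof(x)
  if (!all(is.finite(v)))
    stop("non-finite values produced in ", where, call. = FALSE)
  x
}

#' Run the message-passing encoder
#'
#' Nodes start as null vectors; edges start from their geometric features.
#' Each of the three layers updates nodes from masked mean-aggregated
#' messages, applies a position-wise feed-forward block, and then updates
#' the edge embeddings (self-edges included). Deterministic in eval mode.
#'
#' @param graph A [build_knn_graph()] result.
#' @param params From [init_model_params()] (or a tape registration of it).
#' @param cfg The matching [model_config()].
#' @param train Logical; enables dropout.
#' @param tape Internal: autodiff tape for training.
#' @return List with `h` (`n x d` node embeddings), `e` (all-edge
#'   embeddings, self rows first per node), and the flattened graph arrays.
#' @export
encode <- function(graph, params, cfg, train = FALSE, tape = NULL) {
  ga <- graph$.arrays %||% graph_arrays(graph)
  p <- if (!is.null(tape)) ad_params(tape, params) else params
  d <- cfg$hidden_dim
  if (is.null(ga$maskm) || ncol(ga$maskm) != d) {
    ga$maskm <- matrix(ga$mask, length(ga$mask), d)
    ga$invcm <- matrix(ga$inv_cnt, ga$n, d)
  }
  maskm <- ga$maskm
  invc <- ga$invcm

  act <- cfg_act(cfg)
  e <- ad_layernorm(ad_linear(ga$feat, p$embed$W, p$embed$b),
                    p$embed$ln$g, p$embed$ln$b)
  h <- matrix(0, ga$n, d)
  for (l in seq_len(cfg$encoder_layers)) {
    lp <- p$enc[[l]]
    hi <- ad_gather_rows(h, ga$src)
    hj <- ad_gather_rows(h, ga$dst)
    m <- run_mlp3(lp$msg, ad_concat_cols(list(hi, hj, e)), act)
    m <- ad_mul_const(m, maskm)
    agg <- ad_mul_const(ad_scatter_rows(m, ga$src, ga$n), invc)
    h <- ad_layernorm(ad_add(h, ad_dropout(agg, cfg$dropout, train)),
                      lp$ln1$g, lp$ln1$b)
    h <- ad_layernorm(ad_add(h, ad_dropout(run_ff(lp$ff, h, act), cfg$dropout,
                                           train)),
                      lp$ln2$g, lp$ln2$b)
    em <- run_mlp3(lp$emsg, ad_concat_cols(list(ad_gather_rows(h, ga$src),
                                                ad_gather_rows(h, ga$dst), e)),
                   act)
    e <- ad_layernorm(ad_add(e, ad_dropout(em, cfg$dropout, train)),
                      lp$ln3$g, lp$ln3$b)
    check_finite(h, paste0("encoder layer ", l, " (nodes)"))
    check_finite(e, paste0("encoder layer ", l, " (edges)"))
  }
  list(h = h, e = e, ga = ga, params = p, graph = graph)
}

#' Fixed per-protein decoding order
#'
#' A seeded random permutation keyed by (global seed, protein identifier),
#' so every model variant and replicate sees the same order for the same
#' protein.
#'
#' @param n Number of sites.
#' @param seed Global integer seed.
#' @param protein_id Identifier string.
#' @return Integer permutation of `1:n` with attribute `provenance`.
#' @export
decoding_order <- function(n, seed = 0L, protein_id = "structure") {
  ord <- with_seed(derive_seed(seed, "order", protein_id), sample.int(n))
  attr(ord, "provenance") <- list(seed = seed, protein_id = protein_id)
  ord
}

#' Autoregressive decoder logits
#'
#' Computes per-site 20-way logits with the causal structure of the
#' decoding order: the logits at site `i` depend on the structure and only
#' on residues at sites strictly preceding `i` in `order` (and, in
#' generation mode, only those already committed). Neighbour context for a
#' not-yet-decoded site uses its encoder embedding with a zeroed sequence
#' embedding; for a decoded site it uses the current decoder-layer
#' embedding plus its sequence embedding.
#'
#' @param enc Result of [encode()].
#' @param cfg The [model_config()] (must have a decoder).
#' @param order Permutation from [decoding_order()].
#' @param sequence Integer vector (1-based alphabet indices) or amino-acid
#'   string; `NA` at positions whose residue is not yet known.
#' @param train Logical; enables dropout.
#' @return `n x 20` logits matrix (or tape ref in training mode).
#' @export
decode_logits <- function(enc, cfg, order, sequence, train = FALSE) {
  if (!has_decoder(cfg))
    stop("variant '", cfg$variant, "' has no autoregressive decoder")
  ga <- enc$ga; p <- enc$params
  n <- ga$n; d <- cfg$hidden_dim
  if (is.character(sequence)) sequence <- aa_to_int(sequence)
  if (length(sequence) != n) stop("sequence/context length mismatch: ",
                                  length(sequence), " vs ", n)
  if (length(order) != n || !identical(sort(as.integer(order)), seq_len(n)))
    stop("order must be a permutation of 1:n")
  rank <- integer(n); rank[order] <- seq_len(n)
  known <- !is.na(sequence)
  onehot <- matrix(0, n, 20L)
  onehot[cbind(which(known), sequence[known])] <- 1
  s_emb <- ad_matmul(onehot, p$seq_embed$W)
  mask_bw <- as.numeric(rank[ga$dst] < rank[ga$src] & known[ga$dst])
  mbm <- matrix(mask_bw, length(mask_bw), d)
  maskm <- if (!is.null(ga$maskm) && ncol(ga$maskm) == d) ga$maskm else
    matrix(ga$mask, length(ga$mask), d)
  invc <- if (!is.null(ga$invcm) && ncol(ga$invcm) == d) ga$invcm else
    matrix(ga$inv_cnt, n, d)

  act <- cfg_act(cfg)
  e <- enc$e
  h_enc_j <- ad_gather_rows(enc$h, ga$dst)
  s_j <- ad_mul_const(ad_gather_rows(s_emb, ga$dst), mbm)
  h <- enc$h
  for (l in seq_len(cfg$decoder_layers)) {
    lp <- p$dec[[l]]
    hj <- ad_add(ad_mul_const(ad_gather_rows(h, ga$dst), mbm),
                 ad_mul_const(h_enc_j, 1 - mbm))
    m <- run_mlp3(lp$msg, ad_concat_cols(list(ad_gather_rows(h, ga$src),
                                              e, s_j, hj)), act)
    m <- ad_mul_const(m, maskm)
    agg <- ad_mul_const(ad_scatter_rows(m, ga$src, n), invc)
    h <- ad_layernorm(ad_add(h, ad_dropout(agg, cfg$dropout, train)),
                      lp$ln1$g, lp$ln1$b)
    h <- ad_layernorm(ad_add(h, ad_dropout(run_ff(lp$ff, h, act), cfg$dropout,
                                           train)),
                      lp$ln2$g, lp$ln2$b)
    check_finite(h, paste0("decoder layer ", l))
  }
  ad_linear(h, p$out$W, p$out$b)
}

# column-permutation sending flattened-table index (a-1)*20+b to (b-1)*20+a
.diag_cols <- function() (seq_len(20L) - 1L) * 20L + seq_len(20L)

#' Extract the Potts model from final edge embeddings
#'
#' One shared linear layer maps every final edge embedding to a flattened
#' 20 x 20 table. The two directed tables of an unordered pair are averaged
#' (one transposed) into the symmetric pair energy `J_ij`; when the k-NN
#' graph holds only one direction of a pair, that table (symmetrized the
#' same way) is used alone. The self-edge table's diagonal supplies the 20
#' self-energies `h_i`.
#'
#' @param enc Result of [encode()].
#' @param cfg The [model_config()] (must have a Potts head).
#' @return A [potts_model()] in eval mode; in tape mode a list with tape
#'   refs `h`, `J` plus the `edges` and `ca_dist` bookkeeping.
#' @export
extract_potts <- function(enc, cfg) {
  if (!has_potts_head(cfg))
    stop("variant 'node_only' has no Potts head")
  graph <- enc$graph; ga <- enc$ga; p <- enc$params
  Tall <- ad_matmul(enc$e, p$potts_head$W)
  if (!is.null(p$potts_head$b) && !is.null(vof(p$potts_head$b)))
    Tall <- ad_add_bias(Tall, p$potts_head$b)

  # self-energies: diagonal of each self-edge table
  Tself <- ad_gather_rows(Tall, ga$self_rows)
  h <- ad_rowgather(Tself, matrix(.diag_cols(), ga$n, 20L, byrow = TRUE))

  # undirected edge set from the directed neighbour lists
  nbr_rows <- ga$nbr_rows
  src <- ga$src[nbr_rows]; dst <- ga$dst[nbr_rows]
  ok <- ga$mask[nbr_rows] > 0
  lo <- pmin(src, dst); hi <- pmax(src, dst)
  key <- paste(lo, hi)
  ukey <- unique(key[ok])
  E <- length(ukey)
  dir_lo <- rep(NA_integer_, E)   # directed row with src == lo
  dir_hi <- rep(NA_integer_, E)   # directed row with src == hi
  idx <- match(key, ukey)
  for (r in which(ok)) {
    e_id <- idx[r]
    if (src[r] <= dst[r]) dir_lo[e_id] <- nbr_rows[r] else dir_hi[e_id] <- nbr_rows[r]
  }
  perm <- .j_transpose_perm()
  Tt <- ad_permute_cols(Tall, perm)
  both <- ad_concat_rows(list(Tall, Tt))
  off <- nrow(vof(Tall))
  ia <- ifelse(is.na(dir_lo), off + dir_hi, dir_lo)
  ib <- ifelse(is.na(dir_hi), dir_lo, off + dir_hi)
  J <- ad_scale(ad_add(ad_gather_rows(both, ia), ad_gather_rows(both, ib)), 0.5)

  edges <- matrix(c(as.integer(sub(" .*", "", ukey)),
                    as.integer(sub(".* ", "", ukey))), ncol = 2L)
  # CA distance of each unordered pair, for neighbour ablation
  slot <- function(rows) {
    i <- ga$src[rows]
    s <- rows - (i - 1L) * ga$kk - 1L
    graph$ca_nbr_dist[cbind(i, s)]
  }
  ca_dist <- ifelse(is.na(dir_lo), slot(dir_hi), slot(dir_lo))

  if (is_ad(J) || is_ad(h))
    return(list(h = h, J = J, edges = edges, ca_dist = ca_dist))
  potts_model(h, edges, J, ca_dist = ca_dist)
}

#' Save / load a model checkpoint
#'
#' Single-file container holding the parameter arrays with the
#' [model_config()] echoed in the header, plus optional metadata (epoch,
#' validation loss, optimizer state for resumable checkpoints).
#'
#' @param params Parameter list.
#' @param cfg The [model_config()].
#' @param path File path.
#' @param extra Optional named list stored alongside.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: list
#'   with `params`, `cfg`, `extra`.
#' @export
save_checkpoint <- function(params, cfg, path, extra = list()) {
  saveRDS(list(format = "pottsfold_checkpoint", version = 1L,
               cfg = unclass(cfg), params = params, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable checkpoint: ", conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "pottsfold_checkpoint"))
    stop("format error: '", path, "' is not a pottsfold checkpoint")
  cfg <- do.call(model_config, obj$cfg[setdiff(names(obj$cfg), "alphabet_size")])
  list(params = obj$params, cfg = cfg, extra = obj$extra)
}
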