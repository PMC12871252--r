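#' Node negative log-likelihood loss
#'
#' `-(1/2000) * sum over unmasked sites of log P_V(s[i] | ...)` from
#' teacher-forced decoder logits. The 1/2000 constant is part of the
#' published objective (it makes the node loss scale with protein length
#' while the edge loss does not).
#'
#' @param logits `n x 20` teacher-forced logits.
#' @param target_sequence Amino-acid string or integer vector, length `n`.
#' @param mask Logical length-`n` gap mask, TRUE = position participates
#'   (default all).
#' @return Scalar loss.
#' @export
loss_node <- function(logits, target_sequence, mask = NULL) {
  logits <- vof(logits)
  if (is.character(target_sequence)) target_sequence <- aa_to_int(target_sequence)
  n <- nrow(logits)
  if (length(target_sequence) != n) stop("logits/sequence shape mismatch")
  if (is.null(mask)) mask <- rep(TRUE, n)
  mx <- apply(logits, 1, max)
  lp <- logits - mx - log(rowSums(exp(logits - mx)))
  picked <- lp[cbind(seq_len(n), target_sequence)]
  -(1 / 2000) * sum(picked[mask])
}

# count of edges with both endpoints unmasked
unmasked_edges <- function(pm, mask) {
  if (nrow(pm$edges) == 0L) return(0L)
  sum(mask[pm$edges[, 1]] & mask[pm$edges[, 2]])
}

#' Edge composite pseudo-likelihood loss
#'
#' `-(1/n_edges) * sum over unmasked undirected edges of the log
#' probability of the native residue pair` under the 400-way pair
#' conditional, conditioned on the native residues at all other (unmasked)
#' sites. A masked position removes itself from the conditioning and every
#' edge incident to it from the sum.
#'
#' @param pm A [potts_model()].
#' @param target_sequence Sequence of length `n_sites`.
#' @param mask Logical gap mask (TRUE = participates).
#' @param normalize `"unmasked"` (default: divide by the number of edges
#'   actually summed) or `"structural"` (divide by the full structural edge
#'   count).
#' @return Scalar loss; 0 (with a warning) when no edge survives masking.
#' @export
loss_edge <- function(pm, target_sequence, mask = NULL,
                      normalize = c("unmasked", "structural")) {
  normalize <- match.arg(normalize)
  s <- seq_to_int(pm, target_sequence)
  n <- pm$n_sites
  if (is.null(mask)) mask <- rep(TRUE, n)
  E <- nrow(pm$edges)
  n_um <- unmasked_edges(pm, mask)
  if (n_um == 0L) {
    warning("no unmasked edges; edge loss defined as 0")
    return(0)
  }
  w <- as.numeric(mask)
  Phi <- potts_fields(pm, s, weights = w)
  lo <- pm$edges[, 1]; hi <- pm$edges[, 2]
  total <- 0
  for (e in seq_len(E)) {
    if (!mask[lo[e]] || !mask[hi[e]]) next
    Jtab <- matrix(pm$J[e, ], 20L, 20L, byrow = TRUE)
    u_lo <- pm$h[lo[e], ] + Phi[lo[e], ] - w[hi[e]] * Jtab[, s[hi[e]]]
    u_hi <- pm$h[hi[e], ] + Phi[hi[e], ] - w[lo[e]] * Jtab[s[lo[e]], ]
    En <- outer(u_lo, u_hi, "+") + Jtab
    mx <- max(En)
    total <- total + (En[s[lo[e]], s[hi[e]]] - mx - log(sum(exp(En - mx))))
  }
  denom <- if (normalize == "unmasked") n_um else E
  -total / denom
}

#' Single-site Potts-conditional negative log-likelihood
#'
#' `-(1/2000) * sum over unmasked sites of log P_ss(s[i] | ...)` where the
#' single-site conditional at site `i` sums the self-energy and all pair
#' energies to (unmasked) native neighbours, never conditioning on site `i`
#' itself.
#'
#' @inheritParams loss_edge
#' @return Scalar loss.
#' @export
loss_single_site <- function(pm, target_sequence, mask = NULL) {
  s <- seq_to_int(pm, target_sequence)
  n <- pm$n_sites
  if (is.null(mask)) mask <- rep(TRUE, n)
  Phi <- potts_fields(pm, s, weights = as.numeric(mask))
  logits <- pm$h + Phi
  mx <- apply(logits, 1, max)
  lp <- logits - mx - log(rowSums(exp(logits - mx)))
  -(1 / 2000) * sum(lp[cbind(seq_len(n), s)][mask])
}

# fixed 20 x 400 broadcast matrices: row energies u_i spread over the
# a-major flattened pair table (A: residue at the lower site; B: higher)
.bcast_A <- function() {
  A <- matrix(0, 20L, 400L)
  for (a in seq_len(20L)) A[a, (a - 1L) * 20L + seq_len(20L)] <- 1
  A
}
.bcast_B <- function() {
  B <- matrix(0, 20L, 400L)
  for (b in seq_len(20L)) B[b, (seq_len(20L) - 1L) * 20L + b] <- 1
  B
}

# ---- tape-mode losses used by the training loop ---------------------------
# hJ: list(h = n x 20 ref, J = E x 400 ref, edges) from extract_potts()

tape_fields <- function(hJ, s, w) {
  edges <- hJ$edges
  n <- nrow(vof(hJ$h))
  E <- nrow(edges)
  if (E == 0L) return(matrix(0, n, 20L))
  lo <- edges[, 1]; hi <- edges[, 2]
  cols_i <- outer(rep(1, E), (seq_len(20L) - 1L) * 20L) + s[hi]   # E x 20
  cols_j <- matrix((s[lo] - 1L) * 20L, E, 20L) +
    matrix(seq_len(20L), E, 20L, byrow = TRUE)
  Ji <- ad_mul_const(ad_rowgather(hJ$J, cols_i), matrix(w[hi], E, 20L))
  Jj <- ad_mul_const(ad_rowgather(hJ$J, cols_j), matrix(w[lo], E, 20L))
  ad_add(ad_scatter_rows(Ji, lo, n), ad_scatter_rows(Jj, hi, n))
}

tape_loss_edge <- function(hJ, s, mask, normalize = "unmasked") {
  edges <- hJ$edges
  E <- nrow(edges)
  w <- as.numeric(mask)
  lo <- edges[, 1]; hi <- edges[, 2]
  w_e <- w[lo] * w[hi]
  n_um <- sum(w_e)
  if (n_um == 0) return(list(loss = NULL, n_um = 0L))
  Phi <- tape_fields(hJ, s, w)
  cols_i <- outer(rep(1, E), (seq_len(20L) - 1L) * 20L) + s[hi]
  cols_j <- matrix((s[lo] - 1L) * 20L, E, 20L) +
    matrix(seq_len(20L), E, 20L, byrow = TRUE)
  Ji <- ad_mul_const(ad_rowgather(hJ$J, cols_i), matrix(w[hi], E, 20L))
  Jj <- ad_mul_const(ad_rowgather(hJ$J, cols_j), matrix(w[lo], E, 20L))
  u_lo <- ad_add(ad_add(ad_gather_rows(hJ$h, lo), ad_gather_rows(Phi, lo)),
                 ad_scale(Ji, -1))
  u_hi <- ad_add(ad_add(ad_gather_rows(hJ$h, hi), ad_gather_rows(Phi, hi)),
                 ad_scale(Jj, -1))
  En <- ad_add(ad_add(ad_matmul(u_lo, .bcast_A()), ad_matmul(u_hi, .bcast_B())),
               hJ$J)
  lp <- ad_logsoftmax(En)
  native <- matrix((s[lo] - 1L) * 20L + s[hi], E, 1L)
  picked <- ad_rowgather(lp, native)
  picked <- ad_mul_const(picked, matrix(w_e, E, 1L))
  denom <- if (normalize == "unmasked") n_um else E
  list(loss = ad_scale(ad_sum(picked), -1 / denom), n_um = n_um)
}

tape_loss_single_site <- function(hJ, s, mask) {
  w <- as.numeric(mask)
  n <- length(s)
  Phi <- tape_fields(hJ, s, w)
  lp <- ad_logsoftmax(ad_add(hJ$h, Phi))
  picked <- ad_rowgather(lp, matrix(s, n, 1L))
  picked <- ad_mul_const(picked, matrix(w, n, 1L))
  ad_scale(ad_sum(picked), -1 / 2000)
}

tape_loss_node <- function(logits, s, mask) {
  n <- length(s)
  lp <- ad_logsoftmax(logits)
  picked <- ad_rowgather(lp, matrix(s, n, 1L))
  picked <- ad_mul_const(picked, matrix(as.numeric(mask), n, 1L))
  ad_scale(ad_sum(picked), -1 / 2000)
}

#' MSA-averaged loss
#'
#' Mean over the batch's sequences of the variant's loss components, each
#' sequence teacher-forced with itself and gap-masked: `full` averages
#' `L_V + L_E`, `potts_only` the edge loss only, `potts_single` the
#' single-site Potts loss only, `node_only` the node loss only. A batch of
#' size 1 with the native sequence reproduces the plain (non-MSA) loss.
#'
#' @param params Model parameters.
#' @param cfg [model_config()].
#' @param graph [build_knn_graph()] result.
#' @param order [decoding_order()] permutation.
#' @param sequences List (or character vector) of aligned sequences, gaps
#'   as `"-"`; each must match the structure length.
#' @param masks Optional list of logical gap masks; by default derived from
#'   the gap characters.
#' @return A loss breakdown: list with `L_V`, `L_E`, `L_total`,
#'   `masked_site_count`, `masked_edge_count`, `all_gap_rows`.
#' @export
loss_msa <- function(params, cfg, graph, order, sequences, masks = NULL) {
  if (is.character(sequences)) sequences <- as.list(sequences)
  M <- length(sequences)
  stopifnot(M >= 1L)
  parsed <- lapply(seq_along(sequences), function(m) {
    sq <- sequences[[m]]
    ch <- if (is.character(sq) && length(sq) == 1L) strsplit(sq, "")[[1]] else sq
    if (length(ch) != graph$n)
      stop("unaligned sequence ", m, ": length ", length(ch),
           " != structure length ", graph$n)
    gap <- ch == "-"
    s <- rep(1L, graph$n)
    s[!gap] <- aa_to_int(ch[!gap])
    mask <- if (!is.null(masks)) masks[[m]] else !gap
    list(s = s, mask = mask & !gap)
  })
  enc <- encode(graph, params, cfg, train = FALSE)
  hJ <- if (has_potts_head(cfg)) extract_potts(enc, cfg) else NULL
  LV <- 0; LE <- 0
  msites <- 0L; medges <- 0L; all_gap <- 0L
  for (pr in parsed) {
    if (!any(pr$mask)) { all_gap <- all_gap + 1L; next }
    msites <- msites + sum(!pr$mask)
    if (has_decoder(cfg)) {
      lg <- decode_logits(enc, cfg, order, pr$s, train = FALSE)
      LV <- LV + loss_node(lg, pr$s, pr$mask)
    }
    if (!is.null(hJ)) {
      medges <- medges + (nrow(hJ$edges) - unmasked_edges(hJ, pr$mask))
      if (cfg$variant == "potts_single") {
        LE <- LE + loss_single_site(hJ, int_to_aa(pr$s), pr$mask)
      } else if (cfg$variant != "node_only") {
        LE <- LE + loss_edge(hJ, int_to_aa(pr$s), pr$mask)
      }
    }
  }
  M_eff <- M - all_gap
  if (M_eff > 0L) { LV <- LV / M_eff; LE <- LE / M_eff }
  list(L_V = LV, L_E = LE, L_total = LV + LE,
       masked_site_count = msites, masked_edge_count = medges,
       all_gap_rows = all_gap)
}
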