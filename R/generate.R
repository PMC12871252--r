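#' Sample a sequence autoregressively
#'
#' Residues are drawn site-by-site in the fixed per-protein decoding order
#' from `softmax(logits / temperature)`; the zero-temperature limit is the
#' argmax. Each step re-evaluates the decoder with the residues committed
#' so far (positions not yet decoded carry no sequence information by
#' construction, so the final teacher-forced replay reproduces the
#' generation-time logits exactly).
#'
#' @param params Model parameters (a variant with a decoder).
#' @param cfg [model_config()].
#' @param graph [build_knn_graph()] result.
#' @param temperature Sampling temperature `>= 0` (default 0.1).
#' @param seed Global seed; also keys the decoding order via the protein
#'   identifier.
#' @param order Optional explicit [decoding_order()]; by default derived
#'   from `(seed, graph$id)`.
#' @return A `design_result`: `sequence`, `order`, `per_site_logprob`
#'   (log-probability of the sampled residue at each site, generation
#'   time), `temperature`, plus empty optimization fields.
#' @export
sample_sequence <- function(params, cfg, graph, temperature = 0.1, seed = 0L,
                            order = NULL) {
  if (!is.numeric(temperature) || temperature < 0)
    stop("temperature must be >= 0")
  if (is.null(order)) order <- decoding_order(graph$n, seed, graph$id)
  enc <- encode(graph, params, cfg, train = FALSE)
  n <- graph$n
  s <- rep(NA_integer_, n)
  logp <- numeric(n)
  rng_seed <- derive_seed(seed, "sample", graph$id)
  for (t in seq_len(n)) {
    site <- order[t]
    logits <- decode_logits(enc, cfg, order, s, train = FALSE)[site, ]
    if (temperature <= 1e-6) {
      pick <- which.max(logits)
    } else {
      p <- softmax_vec(logits / temperature)
      pick <- with_seed(derive_seed(rng_seed, t),
                        sample.int(20L, 1L, prob = p))
    }
    lp_all <- logits - max(logits) - log(sum(exp(logits - max(logits))))
    s[site] <- pick
    logp[site] <- lp_all[pick]
  }
  structure(list(sequence = int_to_aa(s), order = order,
                 per_site_logprob = logp, temperature = temperature,
                 trace = data.frame(pass = integer(0), site = integer(0),
                                    old = character(0), new = character(0),
                                    delta = numeric(0)),
                 potts_score_initial = NA_real_,
                 potts_score_final = NA_real_,
                 id = graph$id),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design '%s': %d residues, T=%g, %d accepted moves>\n",
              x$id, nchar(x$sequence), x$temperature, nrow(x$trace)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Potts-guided local optimization of a designed sequence
#'
#' Visits sites in the decoding order used for generation. At each site all
#' 20 candidates are scored by the single-site Potts conditional (the
#' incumbent's own terms are excluded from the conditioning by
#' construction) and the best-scoring residue is installed before moving
#' on, so later sites see the updated context. Ties keep the incumbent;
#' among non-incumbent ties the alphabetically first residue wins, which
#' together with the strict-improvement rule guarantees termination.
#' `mode = "single_pass"` stops after one sweep; `"to_convergence"` sweeps
#' until a full sweep makes no change. `scorer = "single_site"` instead
#' scores candidates by the decoder's summed log-probabilities
#' (teacher-forced re-evaluation per candidate; the expensive variant).
#'
#' @param pm A [potts_model()] (for `scorer = "potts"`).
#' @param start A `design_result` from [sample_sequence()], or a list with
#'   `sequence` and `order`.
#' @param mode `"single_pass"` or `"to_convergence"`.
#' @param scorer `"potts"` or `"single_site"`.
#' @param node_model For `scorer = "single_site"`: list with `params`,
#'   `cfg`, `graph` (a decoder-bearing checkpoint); an error otherwise.
#' @param max_sweeps Safety bound for convergence mode (default 50).
#' @return An updated `design_result` with the move trace; each trace row
#'   records (pass, site, old, new, delta) with `delta >= 0` under the
#'   Potts scorer, and `potts_score_final = potts_score_initial +
#'   sum(delta)`.
#' @export
local_optimize <- function(pm, start, mode = c("single_pass", "to_convergence"),
                           scorer = c("potts", "single_site"),
                           node_model = NULL, max_sweeps = 50L) {
  mode <- match.arg(mode)
  scorer <- match.arg(scorer)
  s <- aa_to_int(start$sequence)
  order <- start$order
  if (scorer == "potts") {
    if (is.null(pm) || !inherits(pm, "potts_model"))
      stop("scorer 'potts' requires a potts_model (node-only checkpoints cannot score this way)")
    if (length(s) != pm$n_sites) stop("start sequence length mismatch")
  } else {
    if (is.null(node_model) || is.null(node_model$params$dec))
      stop("scorer 'single_site' requires a decoder-bearing model")
    enc <- encode(node_model$graph, node_model$params, node_model$cfg,
                  train = FALSE)
    seq_logprob <- function(sv) {
      lg <- decode_logits(enc, node_model$cfg, order, sv, train = FALSE)
      mx <- apply(lg, 1, max)
      lp <- lg - mx - log(rowSums(exp(lg - mx)))
      sum(lp[cbind(seq_along(sv), sv)])
    }
  }
  trace <- list()
  pass <- 0L
  score0 <- if (scorer == "potts") potts_energy(pm, int_to_aa(s)) else NA_real_
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    for (site in order) {
      if (scorer == "potts") {
        Phi <- potts_fields(pm, s)
        cand <- pm$h[site, ] + Phi[site, ]
      } else {
        cand <- vapply(seq_len(20L), function(a) {
          sv <- s; sv[site] <- a; seq_logprob(sv)
        }, numeric(1))
      }
      inc <- s[site]
      best <- which.max(cand)                      # ties: lowest alphabet index
      if (cand[best] <= cand[inc]) best <- inc     # ties keep the incumbent
      if (best != inc) {
        delta <- cand[best] - cand[inc]
        trace[[length(trace) + 1L]] <- data.frame(
          pass = pass, site = site, old = .AA[inc], new = .AA[best],
          delta = delta)
        s[site] <- best
        changed <- TRUE
      }
    }
    if (mode == "single_pass" || !changed || pass >= max_sweeps) break
  }
  out <- start
  out$sequence <- int_to_aa(s)
  out$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(pass = integer(0), site = integer(0), old = character(0),
               new = character(0), delta = numeric(0))
  out$sweeps <- pass
  if (scorer == "potts") {
    out$potts_score_initial <- score0
    out$potts_score_final <- potts_energy(pm, out$sequence)
  }
  out
}

#' Native sequence recovery
#'
#' Fraction of unmasked positions where the designed sequence matches the
#' native one.
#'
#' @param designed,native Equal-length amino-acid strings.
#' @param valid_mask Optional logical mask of scorable positions.
#' @return Fraction in `[0, 1]`.
#' @export
native_sequence_recovery <- function(designed, native, valid_mask = NULL) {
  d <- strsplit(designed, "")[[1]]
  n <- strsplit(native, "")[[1]]
  if (length(d) != length(n))
    stop("length mismatch: designed ", length(d), ", native ", length(n))
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(d))
  if (!any(valid_mask)) stop("no unmasked positions: NSR is undefined")
  sum(d[valid_mask] == n[valid_mask]) / sum(valid_mask)
}
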