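#' Pearson correlation with explicit guards
#'
#' Standard product-moment correlation; errors (rather than returning NA)
#' on fewer than 3 pairs or zero variance, naming the offending side.
#'
#' @param x,y Equal-length numeric vectors, `length >= 3`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3L) stop("need at least 3 pairs for a correlation")
  if (stats::sd(x) == 0) stop("undefined correlation: zero variance in x (predictions)")
  if (stats::sd(y) == 0) stop("undefined correlation: zero variance in y (observations)")
  stats::cor(x, y)
}

#' Score a mutation table and evaluate ddG prediction
#'
#' For every mutation row, predicts the stability change and (when
#' experimental values are present) reports the Pearson correlation per
#' protein and pooled. The `"potts"` scorer uses the incremental Potts
#' energy difference ([ddg_potts()]). The `"node"` scorer compares summed
#' decoder log-probabilities of the mutant and wild-type sequences under
#' the same fixed decoding order (full teacher-forced re-evaluation of the
#' mutant). Predicted scores are positive-stabilizing; set
#' `flip_expt_sign = TRUE` for datasets whose experimental column uses the
#' opposite convention, which flips the experimental values before the
#' correlation.
#'
#' @param model For `scorer = "potts"`: a [potts_model()]; for `"node"`: a
#'   list with `params`, `cfg`, `graph`.
#' @param wt_sequence Wild-type sequence matching the structure.
#' @param mutations List of [mutation_record()]s (or character vector of
#'   strings like `"A123G"`).
#' @param scorer `"potts"` or `"node"`.
#' @param structure Optional [backbone()]: when given, mutation positions
#'   are interpreted in author numbering and resolved through its
#'   `resno`/`chain` map; otherwise they are 1-based sequence indices.
#' @param flip_expt_sign Flip the sign of `ddG_expt` before correlating.
#' @param seed Seed for the fixed decoding order of the node scorer.
#' @return A `ddg_report`: `predictions` data frame (one row per scored
#'   mutation), `per_protein` (Pearson r and n for proteins with >= 3
#'   scored rows), `pooled_r`, `mean_per_protein_r`, `scorer`, `skipped`
#'   (rows with reasons).
#' @export
score_mutations <- function(model, wt_sequence, mutations,
                            scorer = c("potts", "node"), structure = NULL,
                            flip_expt_sign = FALSE, seed = 0L) {
  scorer <- match.arg(scorer)
  if (is.character(mutations)) mutations <- lapply(mutations, parse_mutation)
  if (length(mutations) && inherits(mutations, "mutation_record"))
    mutations <- list(mutations)
  wt_int <- aa_to_int(wt_sequence)
  n <- length(wt_int)

  resolve_pos <- function(mr) {
    if (is.null(structure)) return(mr$position)
    hit <- which(structure$resno == mr$position)
    if (length(hit) == 0L) return(NA_integer_)
    hit[1]
  }

  if (scorer == "potts") {
    stopifnot(inherits(model, "potts_model"))
    fields <- potts_fields(model, wt_int)
  } else {
    if (is.null(model$params$dec))
      stop("node scorer requires a decoder-bearing model")
    order <- decoding_order(model$graph$n, seed, model$graph$id)
    enc <- encode(model$graph, model$params, model$cfg, train = FALSE)
    logprob <- function(s_int) {
      lg <- decode_logits(enc, model$cfg, order, s_int, train = FALSE)
      mx <- apply(lg, 1, max)
      lp <- lg - mx - log(rowSums(exp(lg - mx)))
      sum(lp[cbind(seq_along(s_int), s_int)])
    }
    wt_lp <- logprob(wt_int)
  }

  preds <- list(); skipped <- list()
  for (mr in mutations) {
    pos <- resolve_pos(mr)
    reason <- NULL
    if (is.na(pos) || pos < 1L || pos > n) {
      reason <- "position unresolvable"
    } else if (.AA[wt_int[pos]] != mr$wt_aa) {
      reason <- sprintf("wild-type mismatch (sequence has %s)", .AA[wt_int[pos]])
    }
    if (!is.null(reason)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        protein_id = mr$protein_id, mutation = paste0(mr$wt_aa, mr$position, mr$mut_aa),
        reason = reason)
      next
    }
    pred <- if (mr$wt_aa == mr$mut_aa) 0 else if (scorer == "potts") {
      ddg_potts(model, wt_sequence,
                mutation_record(mr$wt_aa, pos, mr$mut_aa), fields = fields)
    } else {
      s2 <- wt_int; s2[pos] <- aa_to_int(mr$mut_aa)
      logprob(s2) - wt_lp
    }
    preds[[length(preds) + 1L]] <- data.frame(
      protein_id = mr$protein_id,
      mutation = paste0(mr$wt_aa, mr$position, mr$mut_aa),
      position = mr$position, predicted = pred,
      ddG_expt = if (flip_expt_sign) -mr$ddG_expt else mr$ddG_expt)
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    data.frame(protein_id = character(0), mutation = character(0),
               position = integer(0), predicted = numeric(0),
               ddG_expt = numeric(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(protein_id = character(0), mutation = character(0),
               reason = character(0))

  scored <- predictions[!is.na(predictions$ddG_expt), , drop = FALSE]
  per_protein <- NULL
  pooled_r <- NA_real_
  if (nrow(scored) >= 3L) pooled_r <- pearson(scored$predicted, scored$ddG_expt)
  if (nrow(scored)) {
    sp <- split(scored, scored$protein_id)
    pp <- lapply(sp, function(d)
      data.frame(protein_id = d$protein_id[1], n = nrow(d),
                 r = if (nrow(d) >= 3L && stats::sd(d$predicted) > 0 &&
                         stats::sd(d$ddG_expt) > 0)
                   pearson(d$predicted, d$ddG_expt) else NA_real_))
    per_protein <- do.call(rbind, pp)
  }
  structure(list(predictions = predictions, per_protein = per_protein,
                 pooled_r = pooled_r,
                 mean_per_protein_r = if (!is.null(per_protein))
                   mean(per_protein$r, na.rm = TRUE) else NA_real_,
                 scorer = scorer, flip_expt_sign = flip_expt_sign,
                 skipped = skipped),
            class = "ddg_report")
}

#' @export
print.ddg_report <- function(x, ...) {
  cat(sprintf("<ddg_report [%s]: %d scored, %d skipped, pooled r = %s>\n",
              x$scorer, nrow(x$predictions), nrow(x$skipped),
              format(x$pooled_r, digits = 3)))
  invisible(x)
}

#' Export designed sequences as FASTA
#'
#' Headers carry the design metadata (`id`, `seed`, `temperature`,
#' optimization mode, initial/final Potts scores) as `key=value` pairs
#' parseable by [parse_design_header()].
#'
#' @param results List of `design_result`s (possibly empty).
#' @param path Output path.
#' @param seed,optimize Metadata recorded in the headers.
#' @return `path`, invisibly.
#' @export
export_designs <- function(results, path, seed = NA, optimize = "none") {
  if (length(results) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- vapply(results, `[[`, "", "sequence")
  headers <- vapply(results, function(r)
    paste0(r$id,
           "|seed=", seed,
           "|temperature=", r$temperature,
           "|optimize=", optimize,
           "|potts_initial=", r$potts_score_initial,
           "|potts_final=", r$potts_score_final),
    "")
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Parse a design FASTA header written by [export_designs()]
#'
#' @param header Header string (without the leading `>`).
#' @return Named list: `id` plus the key=value fields.
#' @export
parse_design_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  out <- list(id = parts[1])
  for (p in parts[-1]) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    val <- kv[2]
    num <- suppressWarnings(as.numeric(val))
    out[[kv[1]]] <- if (is.na(num) && !identical(val, "NA")) val else num
  }
  out
}
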