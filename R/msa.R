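#' Parse an A3M / aligned-FASTA alignment
#'
#' The first record is the query. Lowercase letters are insertions relative
#' to the query frame: they are counted per row (for the insertion
#' statistic) and then removed, so every returned row has exactly the query
#' length, with gaps as `"-"`. A row whose uppercase+gap column count
#' differs from the query length is a format error naming the row.
#'
#' @param path Path to an `.a3m` or aligned-FASTA file.
#' @return List of class `raw_msa`: `query` (string), `rows` (character
#'   vector, row 1 = query), `names`, `n_insertions` (per row, pre-removal
#'   count), `row_length_pre` (length before insertion removal).
#' @export
parse_a3m <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty alignment file: ", path)
  seqs <- as.character(recs)
  q_len <- nchar(gsub("[a-z]", "", seqs[1]))
  rows <- character(length(seqs))
  n_ins <- integer(length(seqs))
  pre_len <- integer(length(seqs))
  for (r in seq_along(seqs)) {
    kept <- gsub("[a-z]", "", seqs[r])
    n_ins[r] <- nchar(seqs[r]) - nchar(kept)
    pre_len[r] <- nchar(seqs[r])
    if (nchar(kept) != q_len)
      stop("format error in row ", r, " ('", names(recs)[r],
           "'): ", nchar(kept), " match columns, query has ", q_len)
    rows[r] <- kept
  }
  structure(list(query = rows[1], rows = rows, names = names(recs),
                 n_insertions = n_ins, row_length_pre = pre_len),
            class = "raw_msa")
}

#' MSA filter parameters
#'
#' Defaults are the empirically best thresholds of the training recipe:
#' 50% minimum identity to the query, at most 20% insertions, at most 20%
#' gaps ("deletions" in the query frame).
#'
#' @param min_identity,max_gap,max_insertion Fractions in `[0, 1]`.
#' @return List of class `filter_params`.
#' @export
filter_params <- function(min_identity = 0.50, max_gap = 0.20,
                          max_insertion = 0.20) {
  stopifnot(min_identity >= 0, min_identity <= 1, max_gap >= 0, max_gap <= 1,
            max_insertion >= 0, max_insertion <= 1)
  structure(list(min_identity = min_identity, max_gap = max_gap,
                 max_insertion = max_insertion), class = "filter_params")
}

msa_row_stats <- function(msa) {
  q <- strsplit(msa$query, "")[[1]]
  L <- length(q)
  t(vapply(seq_along(msa$rows), function(r) {
    ch <- strsplit(msa$rows[r], "")[[1]]
    gaps <- sum(ch == "-")
    # identity denominator = query length; a gap counts as a mismatch
    ident <- sum(ch == q & ch != "-") / L
    insf <- if (msa$row_length_pre[r] > 0)
      msa$n_insertions[r] / msa$row_length_pre[r] else 0
    c(identity = ident, gap_fraction = gaps / L, insertion_fraction = insf)
  }, numeric(3)))
}

#' Filter an MSA by identity / gap / insertion thresholds
#'
#' Rows failing any threshold are removed; the query (row 1) is always
#' retained. Identity is computed in the query frame after insertion
#' removal, with query length as the denominator and gaps counting as
#' mismatches. The insertion fraction uses the row length before insertion
#' removal as its denominator.
#'
#' @param msa A [parse_a3m()] result or `filtered_msa` (filtering is
#'   idempotent).
#' @param params A [filter_params()].
#' @return List of class `filtered_msa`: `query`, `rows`, `names`, `stats`
#'   (per retained row), `gap_masks` (list of logical vectors, TRUE at
#'   non-gap columns), `filter_params`.
#' @export
filter_msa <- function(msa, params = filter_params()) {
  if (inherits(msa, "filtered_msa"))
    msa <- structure(list(query = msa$query, rows = msa$rows, names = msa$names,
                          n_insertions = rep(0L, length(msa$rows)),
                          row_length_pre = nchar(msa$rows)),
                     class = "raw_msa")
  stopifnot(inherits(msa, "raw_msa"), inherits(params, "filter_params"))
  st <- msa_row_stats(msa)
  keep <- st[, "identity"] >= params$min_identity &
    st[, "gap_fraction"] <= params$max_gap &
    st[, "insertion_fraction"] <= params$max_insertion
  keep[1] <- TRUE
  rows <- msa$rows[keep]
  structure(list(query = msa$query, rows = rows, names = msa$names[keep],
                 stats = st[keep, , drop = FALSE],
                 gap_masks = lapply(rows, function(x)
                   strsplit(x, "")[[1]] != "-"),
                 filter_params = params),
            class = "filtered_msa")
}

#' @export
print.filtered_msa <- function(x, ...) {
  cat(sprintf("<filtered_msa: %d rows x %d columns>\n",
              length(x$rows), nchar(x$query)))
  invisible(x)
}

#' Subsample MSA rows to a token budget
#'
#' Uniform random subset without replacement of at most
#' `floor(token_budget / query_length)` rows; an MSA smaller than the cap
#' is returned whole. Deterministic per seed.
#'
#' @param msa A [filter_msa()] result.
#' @param token_budget Total residue budget (default 10000).
#' @param seed Integer seed.
#' @return Character vector of aligned rows.
#' @export
subsample_msa <- function(msa, token_budget = 10000L, seed = 0L) {
  L <- nchar(msa$query)
  if (token_budget < L)
    stop("token budget ", token_budget, " is smaller than the query length ", L)
  cap <- token_budget %/% L
  if (length(msa$rows) <= cap) return(msa$rows)
  pick <- with_seed(derive_seed(seed, "subsample"),
                    sort(sample.int(length(msa$rows), cap)))
  msa$rows[pick]
}

#' Generate a toy A3M alignment
#'
#' Rows are derived from a random query: each query column becomes a gap
#' with probability `gap_rate`, otherwise matches the query with
#' probability `identity_target / (1 - gap_rate)` (so the expected identity
#' equals the target) or mutates to a random different residue; lowercase
#' insertions are added after columns with probability `insertion_rate`.
#' Byte-identical output per seed.
#'
#' @param query_length,n_rows Dimensions.
#' @param identity_target Expected identity to the query, with
#'   `identity_target + gap_rate <= 1`.
#' @param gap_rate,insertion_rate Per-column rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return A3M text (single string ending in newline).
#' @export
make_toy_msa <- function(query_length, n_rows, identity_target, gap_rate = 0,
                         insertion_rate = 0, seed = 0L) {
  stopifnot(gap_rate >= 0, gap_rate <= 1, insertion_rate >= 0,
            insertion_rate <= 1, identity_target >= 0, identity_target <= 1)
  if (identity_target + gap_rate > 1)
    stop("impossible parameters: identity_target + gap_rate > 1")
  p_match <- if (gap_rate < 1) identity_target / (1 - gap_rate) else 0
  with_seed(derive_seed(seed, "toymsa"), {
    q <- sample(.AA, query_length, replace = TRUE)
    out <- character(2L * n_rows + 2L)
    out[1] <- ">query"
    out[2] <- paste(q, collapse = "")
    for (r in seq_len(n_rows)) {
      u <- stats::runif(query_length)
      ch <- q
      gap <- u < gap_rate
      mut <- !gap & (stats::runif(query_length) > p_match)
      ch[gap] <- "-"
      ch[mut] <- vapply(which(mut), function(i)
        sample(setdiff(.AA, q[i]), 1L), character(1))
      ins <- stats::runif(query_length) < insertion_rate
      ch[ins] <- paste0(ch[ins], tolower(sample(.AA, sum(ins), replace = TRUE)))
      out[2L * r + 1L] <- paste0(">row", r)
      out[2L * r + 2L] <- paste(ch, collapse = "")
    }
    paste0(paste(out, collapse = "\n"), "\n")
  })
}

#' Write an MSA (or raw A3M text) to file
#'
#' @param x A3M text string, `raw_msa`, or `filtered_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_a3m <- function(x, path) {
  if (is.character(x) && length(x) == 1L && !inherits(x, "raw_msa")) {
    writeLines(sub("\n$", "", x), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    nm <- x$names %||% c(">query", paste0(">row", seq_along(x$rows)[-1] - 1L))
    nm <- sub("^>?", ">", nm)
    writeLines(as.vector(rbind(nm, x$rows)), con)
  }
  invisible(path)
}
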