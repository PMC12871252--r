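# internal environment: instrumentation counters (e.g. noise-call tripwire)
.pf_env <- new.env(parent = emptyenv())
.pf_env$noise_calls <- 0L

.BB_ATOMS <- c("N", "CA", "C", "O")

#' Construct a backbone structure object
#'
#' A `backbone` holds per-residue heavy-atom coordinates for N, CA, C, O
#' (Angstrom), chain labels, author residue numbers, and a validity mask
#' (TRUE where all four atoms are present and finite). Residues are ordered
#' chain-grouped, sequential within a chain.
#'
#' @param coords Numeric array `n x 4 x 3`; second dimension ordered
#'   N, CA, C, O. Missing atoms as NA.
#' @param chain Character vector of per-residue chain labels.
#' @param resno Integer vector of author residue numbers (may be
#'   non-contiguous).
#' @param id Identifier string.
#' @return An object of class `backbone`.
#' @export
backbone <- function(coords, chain = NULL, resno = NULL, id = "structure") {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 4L, dim(coords)[3] == 3L)
  n <- dim(coords)[1]
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(resno)) resno <- seq_len(n)
  stopifnot(length(chain) == n, length(resno) == n)
  valid <- apply(coords, 1, function(m) all(is.finite(m)))
  dimnames(coords) <- list(NULL, .BB_ATOMS, c("x", "y", "z"))
  structure(list(n = n, coords = coords, chain = as.character(chain),
                 resno = as.integer(resno), valid = valid, id = id),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone '%s': %d residues, %d chain(s), %d valid>\n",
              x$id, x$n, length(unique(x$chain)), sum(x$valid)))
  invisible(x)
}

#' Read a protein backbone from a PDB or mmCIF file
#'
#' Parses the file with bio3d, resolves alternate locations to the highest
#' occupancy (first on a tie), and returns one entry per residue that has at
#' least one backbone atom. Residues missing any of N/CA/C/O get
#' `valid = FALSE` but keep their slot so author numbering is preserved.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chains Optional character vector of chain IDs to keep.
#' @return A [backbone()] object; the native sequence (one-letter code,
#'   `X` for nonstandard residues) is attached as `$sequence`.
#' @export
read_backbone <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("no such structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    suppressWarnings(
      if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
      else bio3d::read.pdb(path)),
    error = function(e) stop("failed to parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$elety %in% .BB_ATOMS, , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no backbone atoms after chain selection")

  # altloc: highest occupancy wins, first record on tie
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  # residue order: file order of (chain, resno, insert) as bio3d read them
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  at <- at[order(match(rkey, unique(rkey))), , drop = FALSE]
  ukeys <- unique(paste(at$chain, at$resno, at$insert, sep = "|"))
  n <- length(ukeys)
  if (n == 0L) stop("empty structure: zero residues after selection")
  coords <- array(NA_real_, dim = c(n, 4L, 3L))
  chain <- character(n); resno <- integer(n); resid <- character(n)
  ridx <- match(paste(at$chain, at$resno, at$insert, sep = "|"), ukeys)
  aidx <- match(at$elety, .BB_ATOMS)
  for (r in seq_len(nrow(at))) {
    coords[ridx[r], aidx[r], ] <- c(at$x[r], at$y[r], at$z[r])
    chain[ridx[r]] <- at$chain[r]
    resno[ridx[r]] <- at$resno[r]
    resid[ridx[r]] <- at$resid[r]
  }
  bb <- backbone(coords, chain = chain, resno = resno,
                 id = sub("\\.[^.]*$", "", basename(path)))
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one) | !(one %in% .AA)] <- "X"
  bb$sequence <- paste(one, collapse = "")
  bb
}

#' Write a backbone to a minimal PDB file
#'
#' Emits ATOM records for the four backbone atoms of every valid residue
#' (glycine-agnostic; residue name fixed to ALA so the file round-trips
#' through standard readers).
#'
#' @param bb A [backbone()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(bb, path) {
  stopifnot(inherits(bb, "backbone"))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_len(bb$n)) {
    if (!bb$valid[i]) next
    for (a in seq_along(.BB_ATOMS)) {
      serial <- serial + 1L
      xyz <- bb$coords[i, a, ]
      writeLines(sprintf(
        "ATOM  %5d %-4s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, paste0(" ", .BB_ATOMS[a]), substr(bb$chain[i], 1, 1),
        bb$resno[i], xyz[1], xyz[2], xyz[3],
        substr(.BB_ATOMS[a], 1, 1)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a backbone to a minimal mmCIF file
#'
#' Same content as [write_backbone_pdb()] in mmCIF `atom_site` records, so
#' the two renderings of one structure parse back to identical coordinates.
#'
#' @param bb A [backbone()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_backbone_cif <- function(bb, path) {
  stopifnot(inherits(bb, "backbone"))
  hdr <- c("data_backbone", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- character(0)
  serial <- 0L
  for (i in seq_len(bb$n)) {
    if (!bb$valid[i]) next
    for (a in seq_along(.BB_ATOMS)) {
      serial <- serial + 1L
      xyz <- bb$coords[i, a, ]
      rows <- c(rows, sprintf(
        "ATOM %d %s %s . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA %s %s 1",
        serial, substr(.BB_ATOMS[a], 1, 1), .BB_ATOMS[a], bb$chain[i], i,
        xyz[1], xyz[2], xyz[3], bb$resno[i], bb$chain[i], .BB_ATOMS[a]))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Place virtual C-beta atoms
#'
#' Computes an idealized C-beta position for every residue from the backbone
#' N, CA, C atoms only (sequence-independent; glycine receives one too):
#' `Cb = a * (b x c) + bw * b + cw * c + CA` with `b = CA - N`,
#' `c = C - CA`, using fixed ideal-tetrahedral constants.
#'
#' @param bb A [backbone()] object.
#' @param constants Named numeric vector `c(a=, b=, c=)`; the defaults are
#'   the ideal-geometry values used by prior inverse-folding work.
#' @return `n x 3` matrix of C-beta coordinates; rows for invalid residues
#'   are NA (never NaN-propagated downstream). Attribute `valid` marks rows
#'   with all of N/CA/C present.
#' @export
place_virtual_cbeta <- function(bb,
                                constants = c(a = -0.58273431,
                                              b = 0.56802827,
                                              c = -0.54067466)) {
  stopifnot(inherits(bb, "backbone"))
  N <- bb$coords[, "N", , drop = FALSE]; dim(N) <- c(bb$n, 3)
  CA <- bb$coords[, "CA", , drop = FALSE]; dim(CA) <- c(bb$n, 3)
  C <- bb$coords[, "C", , drop = FALSE]; dim(C) <- c(bb$n, 3)
  ok <- apply(cbind(N, CA, C), 1, function(v) all(is.finite(v)))
  b <- CA - N
  cc <- C - CA
  # row-wise cross product b x c
  a <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
             b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
             b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  cb <- constants[["a"]] * a + constants[["b"]] * b + constants[["c"]] * cc + CA
  cb[!ok, ] <- NA_real_
  attr(cb, "valid") <- ok
  cb
}

#' Add Gaussian coordinate noise (training-time augmentation)
#'
#' Displaces every backbone atom by an independent draw from
#' `Normal(0, sigma^2)` in each of x, y, z. A fresh draw is taken per call;
#' the input structure is not modified. Virtual C-beta atoms must be placed
#' *after* noising (the featurizer does this).
#'
#' @param bb A [backbone()] object.
#' @param sigma Standard deviation in Angstrom, `>= 0`.
#' @param seed Optional integer; when given the draw is reproducible.
#' @return A new [backbone()] object with displaced coordinates.
#' @export
add_noise <- function(bb, sigma, seed = NULL) {
  stopifnot(inherits(bb, "backbone"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single number >= 0")
  .pf_env$noise_calls <- .pf_env$noise_calls + 1L
  if (sigma == 0) return(bb)
  draw <- function() array(stats::rnorm(bb$n * 4L * 3L, 0, sigma),
                           dim = c(bb$n, 4L, 3L))
  eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- bb
  out$coords <- bb$coords + eps
  dimnames(out$coords) <- dimnames(bb$coords)
  out
}

# ideal backbone internal coordinates (Engh-Huber-like)
.GEO <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
             a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
             omega = 180)

# place atom D given A-B-C, bond length |CD|, angle B-C-D (deg), dihedral
# A-B-C-D (deg); standard natural-extension-of-reference-frame construction
nerf_place <- function(a, b, c, len, ang, dih) {
  th <- ang * pi / 180
  ch <- dih * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-len * cos(th), len * sin(th) * cos(ch), len * sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Generate a synthetic ideal-geometry backbone
#'
#' Builds an idealized poly-alanine backbone chain from internal coordinates
#' (standard bond lengths/angles, trans peptide bonds) with the phi/psi
#' dihedrals of the requested topology. The seed adds a small deterministic
#' phi/psi jitter (sd 8 degrees) so that fixtures with different seeds are
#' structurally distinct while consecutive CA-CA distances stay at
#' 3.8 +/- 0.1 Angstrom (fixed by the trans peptide geometry).
#'
#' @param n_res Number of residues, `>= 2`.
#' @param topology One of `"helix"`, `"strand"`, `"hairpin"`.
#' @param seed Integer seed; `seed = 0` gives the unjittered ideal chain.
#' @return A [backbone()] object.
#' @export
make_synthetic_backbone <- function(n_res, topology = c("helix", "strand", "hairpin"),
                                    seed = 0L) {
  topology <- match.arg(topology)
  if (!is.numeric(n_res) || n_res < 2) stop("n_res must be >= 2")
  n_res <- as.integer(n_res)
  phi <- numeric(n_res); psi <- numeric(n_res)
  if (topology == "helix") {
    phi[] <- -57; psi[] <- -47
  } else if (topology == "strand") {
    phi[] <- -139; psi[] <- 135
  } else {
    # two antiparallel strands joined by a two-residue turn whose dihedrals
    # were chosen so the strands pair at ~5 A CA-CA without steric overlap
    half <- n_res %/% 2L
    turn <- c(half, half + 1L)
    phi[] <- -139; psi[] <- 135
    phi[turn[1]] <- -41.9; psi[turn[1]] <- -63.4
    phi[turn[2]] <- -73.1; psi[turn[2]] <- -47.9
  }
  if (seed != 0L) {
    jit <- with_seed(derive_seed(seed, "bbjitter"),
                     matrix(stats::rnorm(2L * n_res, 0, 8), ncol = 2))
    keep <- if (topology == "hairpin") -(c(n_res %/% 2L, n_res %/% 2L + 1L)) else TRUE
    phi[keep] <- phi[keep] + jit[keep, 1]
    psi[keep] <- psi[keep] + jit[keep, 2]
  }

  g <- .GEO
  coords <- array(NA_real_, dim = c(n_res, 4L, 3L))
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C <- CA + c(-g$b_ca_c * cos(th), g$b_ca_c * sin(th), 0)
  coords[1, 1, ] <- N; coords[1, 2, ] <- CA; coords[1, 3, ] <- C
  for (i in seq_len(n_res - 1L)) {
    Np <- nerf_place(coords[i, 1, ], coords[i, 2, ], coords[i, 3, ],
                     g$b_c_n, g$a_ca_c_n, psi[i])
    CAp <- nerf_place(coords[i, 2, ], coords[i, 3, ], Np,
                      g$b_n_ca, g$a_c_n_ca, g$omega)
    Cp <- nerf_place(coords[i, 3, ], Np, CAp,
                     g$b_ca_c, g$a_n_ca_c, phi[i + 1L])
    coords[i + 1L, 1, ] <- Np; coords[i + 1L, 2, ] <- CAp; coords[i + 1L, 3, ] <- Cp
  }
  # carbonyl O: sp2 carbon, direction opposite the CA/N(next) bisector
  for (i in seq_len(n_res)) {
    Nn <- if (i < n_res) coords[i + 1L, 1, ] else
      nerf_place(coords[i, 1, ], coords[i, 2, ], coords[i, 3, ],
                 g$b_c_n, g$a_ca_c_n, psi[i])
    dir <- unit3(-(unit3(coords[i, 2, ] - coords[i, 3, ]) +
                     unit3(Nn - coords[i, 3, ])))
    coords[i, 4, ] <- coords[i, 3, ] + g$b_c_o * dir
  }
  backbone(coords, id = sprintf("synthetic_%s_n%d_seed%d", topology, n_res, seed))
}

# internal: counter used by the no-noise-at-inference tripwire test
noise_call_count <- function() .pf_env$noise_calls
reset_noise_counter <- function() { .pf_env$noise_calls <- 0L; invisible(NULL) }
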