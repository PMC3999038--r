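# Pairwise global alignment, percent identity, anchor-position mapping,
# progressive multiple alignment and best-reference assignment.
#
# Pairwise alignment is delegated to Biostrings::pairwiseAlignment
# (affine-gap Needleman-Wunsch); defaults BLOSUM62 / gap open 10 /
# gap extend 0.5 follow common practice for protein alignment.

.blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Default alignment parameters
#'
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param submat Substitution matrix; default BLOSUM62.
#' @return List used by the alignment functions.
#' @export
align_params <- function(gap_open = 10, gap_extend = 0.5, submat = NULL) {
  if (is.null(submat)) submat <- .blosum62()
  list(gap_open = gap_open, gap_extend = gap_extend, submat = submat)
}

#' Optimal global pairwise protein alignment
#'
#' Affine-gap global (Needleman-Wunsch) alignment. Characters must be in
#' the substitution matrix alphabet (the 20 amino acids plus B, Z, J, X
#' and `*` for BLOSUM62).
#'
#' @param a,b Protein strings.
#' @param params See [align_params()].
#' @return Object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings) and `score`.
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = params$submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  structure(list(
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", format(x$score), "\n  ",
      x$aligned_a, "\n  ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x identical columns / columns where neither row has a gap. Columns
#' inside terminal gap runs have a gap in one row and are therefore never
#' counted: identity is computed over the aligned overlap only, which is
#' the right convention for partial amplicons against full references.
#'
#' @param aln A `pairwise_alignment` (or list with `aligned_a`/`aligned_b`).
#' @return Percentage in \\[0, 100\\].
#' @export
percent_identity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  comp <- ca != "-" & cb != "-"
  if (!any(comp)) stop("no comparable columns: sequences do not overlap")
  100 * sum(ca[comp] == cb[comp]) / sum(comp)
}

#' Define catalytic anchor positions on a reference protein
#'
#' Anchors are kept in 1-based reference-sequence numbering (e.g. the
#' class II catalytic tryptophan homologous to Trp-171 of P. chrysosporium
#' LiPH8), never in alignment-column numbering, which is an artifact of
#' one particular multiple alignment.
#'
#' @param ref_id Reference identifier.
#' @param family "CLASS_II", "UPO" or "DYP".
#' @param anchors `data.frame` with columns `position` (1-based integer),
#'   `residue` (expected single letter), `role` (label, e.g. "trp171").
#' @param numbering_source Free-text note on the numbering scheme.
#' @return Object of class `anchor_spec`.
#' @export
anchor_spec <- function(ref_id, family, anchors, numbering_source = "") {
  family <- match.arg(family, .FAMILIES)
  stopifnot(is.data.frame(anchors),
            all(c("position", "residue", "role") %in% names(anchors)))
  anchors$position <- as.integer(anchors$position)
  anchors$residue <- toupper(anchors$residue)
  if (any(nchar(anchors$residue) != 1L)) {
    stop("expected residues must be single amino-acid letters")
  }
  structure(list(ref_id = ref_id, family = family, anchors = anchors,
                 numbering_source = numbering_source),
            class = "anchor_spec")
}

#' Read anchor specifications from YAML
#'
#' Format: a top-level `anchors` list of entries with `ref_id`, `family`,
#' `numbering_source` and a `positions` mapping of 1-based position ->
#' `{residue, role}`.
#'
#' @param path YAML path.
#' @return Named (by `ref_id`) list of `anchor_spec` objects.
#' @export
read_anchors_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$anchors)) stop("anchor YAML lacks an 'anchors' section")
  out <- lapply(cfg$anchors, function(a) {
    pos <- names(a$positions)
    anchor_spec(a$ref_id, a$family,
                data.frame(position = as.integer(pos),
                           residue = vapply(a$positions, `[[`, "", "residue"),
                           role = vapply(a$positions, `[[`, "", "role")),
                numbering_source = a$numbering_source %||% "")
  })
  names(out) <- vapply(out, `[[`, "", "ref_id")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map reference anchor positions onto a query protein
#'
#' Globally aligns the query to the reference and reports, for each anchor
#' position, the query residue occupying the reference's column: the
#' residue letter, "GAP" when the query has a gap in that column, or
#' "ABSENT" when the anchor column lies outside the aligned span of a
#' partial query (inside a terminal gap run of the query row).
#'
#' @param query Query protein string.
#' @param spec An `anchor_spec`.
#' @param reference Reference protein string (its length must cover the
#'   anchor positions).
#' @param params Alignment parameters, see [align_params()].
#' @return `data.frame` with columns `role`, `position`, `expected`,
#'   `query_residue`, `matches_expected`, `query_index` (NA when the
#'   residue is GAP/ABSENT).
#' @export
map_anchors <- function(query, spec, reference, params = align_params()) {
  stopifnot(inherits(spec, "anchor_spec"))
  if (max(spec$anchors$position) > nchar(reference)) {
    stop("anchor position ", max(spec$anchors$position),
         " beyond reference length ", nchar(reference))
  }
  aln <- global_align(query, reference, params)
  qc <- strsplit(aln$aligned_a, "")[[1]]
  rc <- strsplit(aln$aligned_b, "")[[1]]
  ref_pos <- cumsum(rc != "-")          # reference coordinate per column
  q_nongap <- which(qc != "-")
  q_span <- range(q_nongap)             # query's aligned span (columns)
  q_index <- cumsum(qc != "-")

  out <- spec$anchors
  out$expected <- out$residue
  out$residue <- NULL
  out$query_residue <- NA_character_
  out$matches_expected <- FALSE
  out$query_index <- NA_integer_
  for (k in seq_len(nrow(out))) {
    col <- which(ref_pos == out$position[k] & rc != "-")
    if (length(col) != 1L) stop("anchor column not found (internal error)")
    if (col < q_span[1] || col > q_span[2]) {
      out$query_residue[k] <- "ABSENT"
    } else if (qc[col] == "-") {
      out$query_residue[k] <- "GAP"
    } else {
      out$query_residue[k] <- qc[col]
      out$matches_expected[k] <- qc[col] == out$expected[k]
      out$query_index[k] <- q_index[col]
    }
  }
  out[, c("role", "position", "expected", "query_residue",
          "matches_expected", "query_index")]
}

#' Assign the best-matching reference to a query
#'
#' Maximizes percent identity over the aligned overlap against each panel
#' member; ties are broken by lexicographic reference id. Identity is
#' reported to one decimal.
#'
#' @param query Query protein string.
#' @param panel Named character vector of reference proteins.
#' @param params Alignment parameters.
#' @return List with `ref_id` and `identity`.
#' @export
assign_best_reference <- function(query, panel, params = align_params()) {
  if (length(panel) == 0L) stop("reference panel is empty")
  if (is.null(names(panel))) stop("panel must be named by reference id")
  ids <- sort(names(panel))
  pid <- vapply(ids, function(id) {
    percent_identity(global_align(query, panel[[id]], params))
  }, numeric(1))
  best <- ids[which.max(pid)]           # first max = lexicographically least
  list(ref_id = best, identity = round(max(pid), 1))
}

# ---- progressive multiple alignment ---------------------------------------

# profile = character matrix, rows = sequences, cols = alignment columns

# average BLOSUM62 score between two profile columns (gaps contribute 0)
.profile_col_scores <- function(A, B, submat) {
  # returns matrix score[i, j] for column i of A vs column j of B
  alpha <- rownames(submat)
  enc <- function(M) {
    # counts of each alphabet letter per column
    t(vapply(seq_len(ncol(M)), function(j) {
      tabulate(match(M[, j], alpha), nbins = length(alpha))
    }, integer(length(alpha))))
  }
  ca <- enc(A)
  cb <- enc(B)
  (ca %*% submat %*% t(cb)) / (nrow(A) * nrow(B))
}

# affine-gap global profile-profile alignment; returns merged matrix
.align_profiles <- function(A, B, params) {
  go <- params$gap_open
  ge <- params$gap_extend
  S <- .profile_col_scores(A, B, params$submat)
  la <- ncol(A)
  lb <- ncol(B)
  NEG <- -1e18
  # M: A-col with B-col; X: A-col vs gap; Y: gap vs B-col
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)
  Y <- matrix(NEG, la + 1L, lb + 1L)
  M[1, 1] <- 0
  X[2:(la + 1L), 1] <- -go - ge * (0:(la - 1L))
  Y[1, 2:(lb + 1L)] <- -go - ge * (0:(lb - 1L))
  tbM <- matrix(0L, la + 1L, lb + 1L)
  tbX <- matrix(0L, la + 1L, lb + 1L)
  tbY <- matrix(0L, la + 1L, lb + 1L)
  for (i in 2:(la + 1L)) {
    # vectorized over j is awkward with the X/Y recurrences; plain loops
    # are fine at amplicon scale (columns of order 150)
    for (j in 2:(lb + 1L)) {
      cand <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which.max(cand)              # ties: prefer M, then X, then Y
      M[i, j] <- cand[k] + S[i - 1L, j - 1L]
      tbM[i, j] <- k
      cand <- c(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge)
      k <- which.max(cand)
      X[i, j] <- cand[k]
      tbX[i, j] <- k
      cand <- c(M[i, j - 1L] - go - ge, X[i, j - 1L] - go - ge,
                Y[i, j - 1L] - ge)
      k <- which.max(cand)
      Y[i, j] <- cand[k]
      tbY[i, j] <- k
    }
  }
  # traceback
  i <- la + 1L
  j <- lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  takeA <- logical(0)
  takeB <- logical(0)
  while (i > 1L || j > 1L) {
    if (i == 1L) state <- 3L
    if (j == 1L) state <- 2L
    if (state == 1L) {
      takeA <- c(TRUE, takeA)
      takeB <- c(TRUE, takeB)
      state <- tbM[i, j]
      i <- i - 1L
      j <- j - 1L
    } else if (state == 2L) {
      takeA <- c(TRUE, takeA)
      takeB <- c(FALSE, takeB)
      s <- tbX[i, j]
      i <- i - 1L
      state <- if (i == 1L && j == 1L) 1L else c(1L, 2L)[max(s, 1L)]
    } else {
      takeA <- c(FALSE, takeA)
      takeB <- c(TRUE, takeB)
      s <- tbY[i, j]
      j <- j - 1L
      state <- if (i == 1L && j == 1L) 1L else c(1L, 2L, 3L)[max(s, 1L)]
    }
  }
  ncols <- length(takeA)
  out <- matrix("-", nrow(A) + nrow(B), ncols)
  out[seq_len(nrow(A)), takeA] <- A
  out[nrow(A) + seq_len(nrow(B)), takeB] <- B
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

.msa_to_strings <- function(M) {
  setNames(apply(M, 1L, paste, collapse = ""), rownames(M))
}

#' Progressive multiple protein alignment
#'
#' Minimal progressive aligner: a neighbor-joining guide tree is built
#' from pairwise p-distances (computed on pairwise global alignments),
#' then profiles are merged following the guide tree's agglomeration
#' order using affine-gap profile-profile alignment (average-of-pairs
#' BLOSUM62 column scores). All output rows have equal length and
#' removing gaps recovers the inputs.
#'
#' @param records Named character vector of >= 2 protein sequences.
#' @param params Alignment parameters, see [align_params()].
#' @return Named character vector of equal-length gapped rows
#'   (class `msa`).
#' @export
progressive_msa <- function(records, params = align_params()) {
  n <- length(records)
  if (n < 2L) stop("need at least two sequences to align")
  if (is.null(names(records))) names(records) <- paste0("seq", seq_len(n))
  if (n == 2L) {
    aln <- global_align(records[[1]], records[[2]], params)
    out <- setNames(c(aln$aligned_a, aln$aligned_b), names(records))
    class(out) <- "msa"
    return(out)
  }
  # pairwise p-distances for the guide tree
  D <- matrix(0, n, n, dimnames = list(names(records), names(records)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- global_align(records[[i]], records[[j]], params)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    comp <- ca != "-" & cb != "-"
    D[i, j] <- D[j, i] <- if (any(comp)) mean(ca[comp] != cb[comp]) else 1
  }
  joins <- .nj_joins(D)$joins           # agglomeration order from NJ
  profiles <- lapply(seq_len(n), function(i) {
    matrix(strsplit(records[[i]], "")[[1]], nrow = 1L,
           dimnames = list(names(records)[i], NULL))
  })
  # node k (> n) is the profile created by join k - n
  merge_two <- function(a, b) .align_profiles(profiles[[a]], profiles[[b]], params)
  for (k in seq_along(joins)) {
    jn <- joins[[k]]
    profiles[[n + k]] <- merge_two(jn$a, jn$b)
  }
  last <- joins[[length(joins)]]
  final <- profiles[[n + length(joins)]]
  if (!is.null(last$c)) {               # trailing trifurcation
    final <- .align_profiles(final, profiles[[last$c]], params)
  }
  out <- .msa_to_strings(final)[names(records)]
  class(out) <- "msa"
  out
}
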