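#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# IUPAC nucleotide ambiguity sets, extended with inosine (I).
# Inosine base-pairs promiscuously and is treated as a universal match
# (same base set as N) in hybridization contexts.
.IUPAC_NT <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG",
  N = "ACGT", I = "ACGT"
)

.NT_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D",
  N = "N", I = "I"
)

# 4-bit base masks: A=1, C=2, G=4, T=8; an IUPAC code's mask is the union
# of its base set. Two codes are compatible iff their masks intersect.
.NT_MASK <- vapply(.IUPAC_NT, function(set) {
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  sum(bits[strsplit(set, "")[[1]]])
}, integer(1))

.AA_LETTERS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Normalize and validate a nucleotide sequence
#'
#' Upper-cases, converts U to T (templates are cDNA), and checks every
#' character against the IUPAC ambiguity alphabet extended with inosine.
#'
#' @param seq A single nucleotide string.
#' @param what Label used in error messages.
#' @return The normalized sequence string.
#' @export
normalize_nt <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string")
  }
  s <- chartr("u", "U", toupper(seq))
  s <- gsub("U", "T", s, fixed = TRUE)
  if (nchar(s) == 0L) stop(what, " is empty")
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), names(.IUPAC_NT))
  if (length(bad) > 0L) {
    stop(what, " contains characters outside the IUPAC nucleotide alphabet: ",
         paste(bad, collapse = ", "))
  }
  s
}

#' Construct a degenerate primer
#'
#' A primer written 5'->3' in IUPAC ambiguity codes, optionally carrying
#' inosine (I) at fully degenerate positions and an expected protein motif
#' encoded by the primer region.
#'
#' @param name Primer name.
#' @param seq Primer sequence (IUPAC codes plus I), length >= 10.
#' @param motif Optional expected protein motif (length <= ceiling(len/3)).
#' @return An object of class `degenerate_primer`.
#' @examples
#' degenerate_primer("DyP360F", "TGYCCITTYGCIGCNCAYAT", motif = "CPFAAHI")
#' @export
degenerate_primer <- function(name, seq, motif = NULL) {
  seq <- normalize_nt(gsub("[ '′-]", "", seq), paste0("primer ", name))
  if (nchar(seq) < 10L) stop("primer ", name, " is shorter than 10 nt")
  if (!is.null(motif)) {
    motif <- toupper(motif)
    if (nchar(motif) > ceiling(nchar(seq) / 3)) {
      stop("motif longer than the primer can encode")
    }
  }
  structure(list(name = name, seq = seq, motif = motif),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat("<degenerate_primer>", x$name, " 5'-", x$seq, "-3'",
      if (!is.null(x$motif)) paste0("  motif: ", x$motif), "\n", sep = "")
  invisible(x)
}

#' Expand a degenerate primer into concrete sequences
#'
#' Substitutes every IUPAC ambiguity code by each member of its base set.
#' Inosine positions stay symbolic and are emitted as the wildcard N, so
#' they do not multiply the expansion count.
#'
#' @param primer A `degenerate_primer` or a raw IUPAC string.
#' @param max_expansions Guard against combinatorial blow-up; an error is
#'   raised when the product of code cardinalities exceeds it.
#' @return Character vector of concrete sequences (N at inosine positions).
#' @examples
#' expand_degenerate("GGY")  # "GGC" "GGT"
#' @export
expand_degenerate <- function(primer, max_expansions = 10000L) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$seq
         else normalize_nt(primer, "primer")
  chars <- strsplit(seq, "")[[1]]
  sets <- lapply(chars, function(ch) {
    if (ch == "I") "N" else strsplit(.IUPAC_NT[[ch]], "")[[1]]
  })
  card <- prod(vapply(sets, length, integer(1)))
  if (card > max_expansions) {
    stop("expansion overflow: ", card, " concrete sequences exceed limit ",
         max_expansions)
  }
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}

#' Number of concrete expansions of a degenerate sequence
#'
#' @inheritParams expand_degenerate
#' @return Integer product of per-position cardinalities (inosine counts 1).
#' @export
degeneracy <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$seq
         else normalize_nt(primer, "primer")
  chars <- strsplit(seq, "")[[1]]
  prod(vapply(chars, function(ch) {
    if (ch == "I") 1L else nchar(.IUPAC_NT[[ch]])
  }, integer(1)))
}

#' IUPAC-aware reverse complement
#'
#' Complements ambiguity codes (R<->Y, K<->M, B<->V, D<->H; S, W, N, I map
#' to themselves) and reverses. An involution: applying it twice restores
#' the input.
#'
#' @param seq IUPAC nucleotide string.
#' @return The reverse complement string.
#' @examples
#' reverse_complement("AAYGC")  # "GCRTT"
#' @export
reverse_complement <- function(seq) {
  s <- normalize_nt(seq)
  chars <- strsplit(s, "")[[1]]
  paste(rev(.NT_COMPLEMENT[chars]), collapse = "")
}

# genetic code table from Biostrings, cached
.genetic_code <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    gc
  }
})

.translate_codon <- function(codon) {
  gc <- .genetic_code()
  aa <- gc[codon]
  if (!is.na(aa)) return(unname(aa))
  # ambiguous codon: translate every expansion; X unless all agree
  sets <- lapply(strsplit(codon, "")[[1]], function(ch) {
    strsplit(.IUPAC_NT[[ch]], "")[[1]]
  })
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  aas <- unique(gc[apply(combos, 1L, paste, collapse = "")])
  if (length(aas) == 1L) unname(aas) else "X"
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; the trailing incomplete codon is dropped. Codons
#' containing ambiguity codes (including N and inosine) translate to a
#' specific amino acid only when every concrete expansion agrees, else X.
#'
#' @param seq Nucleotide string (IUPAC alphabet).
#' @param frame 0, 1 or 2: bases skipped before the first codon.
#' @param strand "+" or "-": on "-" the reverse complement is translated.
#' @return Single amino-acid string ("*" marks stop codons).
#' @examples
#' translate_dna("ATGGAA")  # "ME"
#' @export
translate_dna <- function(seq, frame = 0L, strand = "+") {
  s <- normalize_nt(seq)
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") s <- reverse_complement(s)
  if (nchar(s) - frame < 3L) {
    stop("nothing left to translate in frame ", frame)
  }
  s <- substr(s, frame + 1L, nchar(s))
  n_codon <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  paste(vapply(codons, .translate_codon, character(1)), collapse = "")
}

#' Read a FASTA file as a named character vector
#'
#' Record ids are taken up to the first whitespace in the header; sequences
#' are upper-cased with U normalized to T when `alphabet = "nt"`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet "nt" (validate as IUPAC nucleotide) or "aa" (as-is).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "[[:space:]]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  if (length(seqs) > 0L && alphabet == "nt") {
    seqs <- vapply(seqs, normalize_nt, character(1))
    names(seqs) <- ids
  }
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) stop("no sequences to write")
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
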