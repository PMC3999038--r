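# In-silico PCR: locate degenerate primer binding sites on both strands
# and extract convergent products within the expected size window.

.FAMILIES <- c("CLASS_II", "UPO", "DYP")

#' Construct a primer pair
#'
#' A degenerate forward/reverse primer set with its target peroxidase
#' family and an expected product size window (primer-inclusive, matching
#' gel-estimated sizes).
#'
#' @param forward,reverse `degenerate_primer` objects.
#' @param family One of "CLASS_II", "UPO", "DYP".
#' @param size_window Integer `c(min_bp, max_bp)`; `min_bp` must be at
#'   least the two primer lengths combined.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, family, size_window) {
  stopifnot(inherits(forward, "degenerate_primer"),
            inherits(reverse, "degenerate_primer"))
  family <- match.arg(family, .FAMILIES)
  size_window <- as.integer(size_window)
  if (length(size_window) != 2L || any(is.na(size_window))) {
    stop("size_window must be c(min_bp, max_bp)")
  }
  if (size_window[1] < nchar(forward$seq) + nchar(reverse$seq)) {
    stop("size_window minimum smaller than the combined primer lengths")
  }
  if (size_window[2] <= size_window[1]) {
    stop("size_window maximum must exceed the minimum")
  }
  structure(list(forward = forward, reverse = reverse, family = family,
                 size_window = size_window),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair> ", x$family, ": ", x$forward$name, " / ",
      x$reverse$name, ", window ", x$size_window[1], "-",
      x$size_window[2], " bp\n", sep = "")
  invisible(x)
}

#' The three peroxidase primer pairs
#'
#' The degenerate primer sets used to amplify partial class II peroxidase
#' (peroxiF2/peroxiR2, ~400 bp), unspecific peroxygenase (APO_65F/APO_130R,
#' ~210 bp) and dye-decolorizing peroxidase (DyP360F/DyP485R, ~400 bp)
#' transcripts from forest-litter cDNA. The "~" sizes are realized as
#' windows: 300-500 bp for CLASS_II and DYP, 150-280 bp for UPO.
#'
#' @return Named list of `primer_pair` objects (CLASS_II, UPO, DYP).
#' @export
peroxidase_primers <- function() {
  list(
    CLASS_II = primer_pair(
      degenerate_primer("peroxiF2", "GGYGGIGGIGCBGAYGGYTC"),
      degenerate_primer("peroxiR2", "GGIGTIGARTCGAABGG"),
      family = "CLASS_II", size_window = c(300L, 500L)),
    UPO = primer_pair(
      degenerate_primer("APO_65F", "AAYGCIATGGCNAAYCAYGG"),
      degenerate_primer("APO_130R", "GCRTCRTGYTCIATNCC"),
      family = "UPO", size_window = c(150L, 280L)),
    DYP = primer_pair(
      degenerate_primer("DyP360F", "TGYCCITTYGCIGCNCAYAT", motif = "CPFAAHI"),
      degenerate_primer("DyP485R", "RAARAARTAYTCICCNCC", motif = "GGEYFF"),
      family = "DYP", size_window = c(300L, 500L))
  )
}

#' Read primer pairs from a YAML file
#'
#' Expects a top-level `pairs` list with entries carrying `family`,
#' `forward: {name, seq, motif}`, `reverse: {...}` and `size_window`.
#' A file with the shipped pairs is at
#' `system.file("extdata", "primers.yaml", package = "peroxscan")`.
#'
#' @param path Path to the YAML file.
#' @return Named list of `primer_pair` objects.
#' @export
read_primers_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pairs)) stop("primers YAML lacks a 'pairs' section")
  out <- lapply(cfg$pairs, function(p) {
    primer_pair(
      degenerate_primer(p$forward$name, p$forward$seq, p$forward$motif),
      degenerate_primer(p$reverse$name, p$reverse$seq, p$reverse$motif),
      family = p$family,
      size_window = unlist(p$size_window))
  })
  names(out) <- vapply(out, function(p) p$family, character(1))
  out
}

# mismatch profile of a primer mask against every offset of a template
# mask vector; returns integer vector over offsets 1..(n-m+1)
.scan_mismatches <- function(tmask, pmask) {
  n <- length(tmask)
  m <- length(pmask)
  n_off <- n - m + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (j in seq_len(m)) {
    mm <- mm + as.integer(bitwAnd(tmask[j:(j + n_off - 1L)], pmask[j]) == 0L)
  }
  mm
}

.seq_mask <- function(seq) unname(.NT_MASK[strsplit(seq, "")[[1]]])

#' Find degenerate primer binding sites on a template
#'
#' Ungapped scan of both strands. A position matches when at most
#' `max_mismatch` template/primer positions have disjoint IUPAC base sets;
#' inosine and N never count as mismatches. Regardless of `max_mismatch`,
#' the two 3'-terminal primer positions must match exactly (PCR extension
#' requires a paired 3' end).
#'
#' @param template Nucleotide string or a single named element of one.
#' @param primer A `degenerate_primer`.
#' @param max_mismatch Non-negative integer mismatch tolerance.
#' @return `data.frame` with columns `start`, `end` (1-based, inclusive,
#'   plus-strand coordinates of the footprint), `strand` ("+": primer
#'   matches the plus strand as written; "-": its reverse complement
#'   does), `mismatches`.
#' @export
find_sites <- function(template, primer, max_mismatch = 0L) {
  stopifnot(inherits(primer, "degenerate_primer"), max_mismatch >= 0L)
  s <- normalize_nt(template, "template")
  tmask <- .seq_mask(s)
  p <- primer$seq
  m <- nchar(p)
  res <- list()

  # plus strand: primer as written; 3' end is the footprint's right end
  pmask <- .seq_mask(p)
  mm <- .scan_mismatches(tmask, pmask)
  if (length(mm) > 0L) {
    tail2 <- .scan_mismatches(tmask, pmask[(m - 1L):m])
    # mismatches within the last two primer positions, per offset
    end3 <- tail2[seq_along(mm) + (m - 2L)]
    ok <- which(mm <= max_mismatch & end3 == 0L)
    if (length(ok) > 0L) {
      res[["+"]] <- data.frame(start = ok, end = ok + m - 1L, strand = "+",
                               mismatches = mm[ok])
    }
  }

  # minus strand: reverse complement of the primer on the plus strand;
  # the primer's 3' terminus maps to the footprint's left end
  rc <- reverse_complement(p)
  pmask <- .seq_mask(rc)
  mm <- .scan_mismatches(tmask, pmask)
  if (length(mm) > 0L) {
    head2 <- .scan_mismatches(tmask, pmask[1:2])
    end3 <- head2[seq_along(mm)]
    ok <- which(mm <= max_mismatch & end3 == 0L)
    if (length(ok) > 0L) {
      res[["-"]] <- data.frame(start = ok, end = ok + m - 1L, strand = "-",
                               mismatches = mm[ok])
    }
  }

  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Extract amplicons for a primer pair from one template
#'
#' Emits every forward-site/reverse-site combination in convergent
#' orientation whose primer-inclusive product length falls inside the
#' pair's size window. The amplicon sequence is reported on the strand
#' defined by the forward primer, so it always begins with a
#' forward-primer-compatible footprint and ends with the reverse
#' complement of a reverse-primer-compatible one. Overlapping and nested
#' products are all reported.
#'
#' @param template Nucleotide string.
#' @param pair A `primer_pair`.
#' @param max_mismatch Mismatch tolerance passed to [find_sites()].
#' @param template_id Identifier recorded in the output.
#' @return `data.frame` with columns `template_id`, `start`, `end`
#'   (1-based inclusive plus-strand span), `strand`, `length`, `family`,
#'   `fwd_mismatches`, `rev_mismatches`, `seq`.
#' @export
amplify <- function(template, pair, max_mismatch = 0L,
                    template_id = "template") {
  stopifnot(inherits(pair, "primer_pair"))
  s <- normalize_nt(template, "template")
  fsites <- find_sites(s, pair$forward, max_mismatch)
  rsites <- find_sites(s, pair$reverse, max_mismatch)
  lo <- pair$size_window[1]
  hi <- pair$size_window[2]
  out <- list()

  # product sense = plus strand: forward(+) upstream of reverse(-)
  f <- fsites[fsites$strand == "+", , drop = FALSE]
  r <- rsites[rsites$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    len <- r$end[j] - f$start[i] + 1L
    if (r$start[j] > f$end[i] && len >= lo && len <= hi) {
      out[[length(out) + 1L]] <- data.frame(
        template_id = template_id, start = f$start[i], end = r$end[j],
        strand = "+", length = len, family = pair$family,
        fwd_mismatches = f$mismatches[i], rev_mismatches = r$mismatches[j],
        seq = substr(s, f$start[i], r$end[j]))
    }
  }

  # product sense = minus strand: reverse(+) upstream of forward(-)
  f <- fsites[fsites$strand == "-", , drop = FALSE]
  r <- rsites[rsites$strand == "+", , drop = FALSE]
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    len <- f$end[i] - r$start[j] + 1L
    if (f$start[i] > r$end[j] && len >= lo && len <= hi) {
      out[[length(out) + 1L]] <- data.frame(
        template_id = template_id, start = r$start[j], end = f$end[i],
        strand = "-", length = len, family = pair$family,
        fwd_mismatches = f$mismatches[i], rev_mismatches = r$mismatches[j],
        seq = reverse_complement(substr(s, r$start[j], f$end[i])))
    }
  }

  if (length(out) == 0L) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), family = character(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      seq = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

#' Run in-silico PCR over a pool of templates
#'
#' @param templates Named character vector of nucleotide sequences.
#' @param pair A `primer_pair`.
#' @param max_mismatch Mismatch tolerance.
#' @return Row-bound [amplify()] output; amplicon ids are
#'   `<template_id>` when a template yields one product and
#'   `<template_id>.amp<k>` when several, in column `amplicon_id`.
#' @export
amplify_pool <- function(templates, pair, max_mismatch = 0L) {
  stopifnot(length(templates) > 0L, !is.null(names(templates)))
  res <- lapply(names(templates), function(id) {
    amplify(templates[[id]], pair, max_mismatch, template_id = id)
  })
  res <- do.call(rbind, res)
  if (nrow(res) == 0L) {
    res$amplicon_id <- character(0)
    return(res)
  }
  n_per <- table(res$template_id)
  res$amplicon_id <- ifelse(
    n_per[res$template_id] == 1L, res$template_id,
    paste0(res$template_id, ".amp",
           ave(seq_len(nrow(res)), res$template_id, FUN = seq_along)))
  rownames(res) <- NULL
  res
}
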